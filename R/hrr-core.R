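#' The identity vector for circular convolution
#'
#' Returns \eqn{e_0 = (1, 0, \dots, 0)}, the unit impulse: binding any vector
#' with `hrr_identity(d)` returns it unchanged.
#'
#' @param dim dimensionality (at least 2).
#' @return a numeric vector of length `dim`.
#' @examples
#' hrr_bind(hrr_identity(8), hrr_random(8, seed = 1))
#' @export
hrr_identity <- function(dim) {
  if (dim < 2) vs_error("vsbind_param_error", "dim must be >= 2")
  c(1, numeric(dim - 1))
}

#' Generate a seeded random symbol vector
#'
#' Atomic symbols are random unit vectors; in high dimension independent draws
#' are quasi-orthogonal, which is what lets superposed bindings be told apart.
#' Three constructions are available:
#'
#' * `"gaussian"`: i.i.d. normal entries, then normalized to unit Euclidean
#'   norm (the distribution Plate's capacity theory assumes);
#' * `"sparse"`: exactly `round(sparsity * dim)` nonzero entries at seeded
#'   random indices, i.i.d. normal values, normalized — a sparse distributed
#'   code;
#' * `"unitary"`: all Fourier magnitudes equal to 1 with seeded random phases
#'   (conjugate-symmetric, so the vector is real). Unitary vectors are exactly
#'   invertible under [hrr_inverse()], which makes them the right choice for
#'   positional tags.
#'
#' The same `(dim, seed, mode, sparsity)` always reproduces the same vector
#' bit-for-bit.
#'
#' @param dim dimensionality (>= 2).
#' @param seed integer seed for this draw.
#' @param mode one of `"gaussian"`, `"sparse"`, `"unitary"`.
#' @param sparsity fraction in (0, 1] of nonzero entries (sparse mode only).
#' @return a unit-norm numeric vector of length `dim`.
#' @examples
#' a <- hrr_random(256, seed = 1)
#' b <- hrr_random(256, seed = 2)
#' hrr_similarity(a, b)  # near 0
#' @export
hrr_random <- function(dim, seed, mode = c("gaussian", "sparse", "unitary"),
                       sparsity = 0.05) {
  mode <- match.arg(mode)
  if (dim < 2) vs_error("vsbind_param_error", "dim must be >= 2")
  if (sparsity <= 0 || sparsity > 1) {
    vs_error("vsbind_param_error", "sparsity must be in (0, 1]")
  }
  set.seed(seed)
  v <- switch(mode,
    gaussian = stats::rnorm(dim, sd = 1 / sqrt(dim)),
    sparse = {
      k <- max(1L, as.integer(round(sparsity * dim)))
      idx <- sample.int(dim, k)
      out <- numeric(dim)
      out[idx] <- stats::rnorm(k)
      out
    },
    unitary = unitary_vector(dim)
  )
  v / sqrt(sum(v^2))
}

# Real vector whose DFT has unit magnitude everywhere: random phases on the
# free bins, conjugate symmetry on the rest, +1 on the self-conjugate bins.
unitary_vector <- function(dim) {
  half <- floor((dim - 1) / 2)
  spec <- complex(real = rep(1, dim))
  if (half >= 1) {
    theta <- stats::runif(half, 0, 2 * pi)
    spec[2:(half + 1)] <- complex(modulus = 1, argument = theta)
    spec[dim:(dim - half + 1)] <- Conj(spec[2:(half + 1)])
  }
  Re(stats::fft(spec, inverse = TRUE)) / dim
}

#' Superpose (bundle) vectors
#'
#' Element-wise addition. The result is correlated with every constituent and
#' is deliberately not renormalized: accumulation of net activation across
#' superpositions is itself a model-level prediction, so the raw sum is kept
#' (use [hrr_normalize()] when a unit vector is needed).
#'
#' @param vs a list of equal-dimensional numeric vectors, or a single vector.
#' @param ... further vectors, appended to `vs`.
#' @return the element-wise sum.
#' @examples
#' a <- hrr_random(64, 1); b <- hrr_random(64, 2)
#' s <- hrr_superpose(a, b)
#' hrr_similarity(s, a) > 0 && hrr_similarity(s, b) > 0
#' @export
hrr_superpose <- function(vs, ...) {
  if (!is.list(vs)) vs <- c(list(vs), list(...)) else vs <- c(vs, list(...))
  if (length(vs) == 0) vs_error("vsbind_param_error", "nothing to superpose")
  out <- vs[[1]]
  for (v in vs[-1]) {
    vs_check_dim(out, v)
    out <- out + v
  }
  out
}

#' Bind two vectors by circular convolution
#'
#' The conjunctive operator of the HRR algebra:
#' \deqn{(a \otimes b)[k] = \sum_j a[j]\, b[(k - j) \bmod d].}
#' The output has the same dimensionality as the inputs (a *reduced
#' representation*) and is approximately orthogonal to both. Computed via the
#' FFT identity; it agrees with the direct \eqn{O(d^2)} sum to 1e-9.
#'
#' @param a,b numeric vectors of equal length.
#' @return their circular convolution.
#' @examples
#' hrr_bind(c(1, 2, 0, 0), c(0, 1, 0, 0))  # unit shift: 0 1 2 0
#' @export
hrr_bind <- function(a, b) {
  vs_check_dim(a, b)
  Re(stats::fft(stats::fft(a) * stats::fft(b), inverse = TRUE)) / length(a)
}

#' Approximate inverse (involution)
#'
#' Plate's involution: entry 0 is fixed and the remaining entries are
#' reversed (`a[j] -> a[d - j]`, indices mod d). Applying it twice returns
#' the input exactly. For unitary vectors the involution is the exact
#' convolutional inverse: `hrr_bind(u, hrr_inverse(u))` is the identity
#' impulse; for generic vectors it is approximate, which is why unbinding
#' yields the stored symbol plus noise.
#'
#' @param a a numeric vector.
#' @return the involuted vector, written `!a` in the algebra.
#' @examples
#' hrr_inverse(c(10, 1, 2, 3))  # 10 3 2 1
#' @export
hrr_inverse <- function(a) {
  d <- length(a)
  if (d < 2) vs_error("vsbind_param_error", "dim must be >= 2")
  a[c(1L, d:2L)]
}

#' Unbind (release) a constituent from a binding
#'
#' Binds the trace with the involution of the key:
#' `hrr_unbind(hrr_bind(a, k), k)` recovers a noisy copy of `a` whose
#' similarity to `a` is well above its similarity to `k` or to unrelated
#' symbols; [cleanup()] then snaps it back to the vocabulary.
#'
#' @param trace the bound (possibly superposed) vector.
#' @param key the cue that was bound with the sought constituent.
#' @return a noisy reconstruction of the constituent.
#' @examples
#' a <- hrr_random(256, 1); b <- hrr_random(256, 2)
#' noisy <- hrr_unbind(hrr_bind(a, b), b)
#' hrr_similarity(noisy, a) > hrr_similarity(noisy, b)
#' @export
hrr_unbind <- function(trace, key) {
  vs_check_dim(trace, key)
  hrr_bind(trace, hrr_inverse(key))
}

#' Compare two vectors
#'
#' Cosine similarity (default; scale-invariant, in \[-1, 1\]) or the raw dot
#' product.
#'
#' @param a,b numeric vectors of equal length.
#' @param metric `"cosine"` or `"dot"`.
#' @return a scalar similarity.
#' @export
hrr_similarity <- function(a, b, metric = c("cosine", "dot")) {
  metric <- match.arg(metric)
  vs_check_dim(a, b)
  d <- sum(a * b)
  if (metric == "dot") return(d)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    vs_error("vsbind_param_error", "cosine similarity undefined for zero-norm input")
  }
  d / (na * nb)
}

#' Normalize to unit Euclidean norm
#'
#' @param v a numeric vector with nonzero norm.
#' @return `v / ||v||`.
#' @export
hrr_normalize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) vs_error("vsbind_param_error", "cannot normalize a zero vector")
  v / n
}

#' Build a vocabulary of named atomic symbols
#'
#' A vocabulary maps symbol names to seeded random unit vectors of a common
#' dimensionality and doubles as the cleanup (autoassociative) memory: noisy
#' vectors produced by unbinding are identified by nearest-neighbour cosine
#' against its entries. Each entry's seed is derived from the vocabulary seed,
#' the entry name and its position, so the same `(names, dim, seed, mode)`
#' regenerates identical vectors bit-for-bit.
#'
#' @param names unique, non-empty symbol names (order matters for storage,
#'   not for generation).
#' @param dim dimensionality of all entries.
#' @param seed integer vocabulary seed.
#' @param mode,sparsity passed to [hrr_random()].
#' @return an object of class `hrr_vocabulary` with fields `vectors`
#'   (a `dim x n` matrix, one column per name), `names`, `dim`, `seed`,
#'   `mode`, `sparsity`.
#' @examples
#' v <- hrr_vocabulary(c("A", "B", "X"), dim = 256, seed = 7)
#' cleanup(v$vectors[, "A"], v)
#' @export
hrr_vocabulary <- function(names, dim, seed,
                           mode = c("gaussian", "sparse", "unitary"),
                           sparsity = 0.05) {
  mode <- match.arg(mode)
  names <- as.character(names)
  if (length(names) == 0 || anyDuplicated(names) || any(!nzchar(names))) {
    vs_error("vsbind_param_error", "names must be unique and non-empty")
  }
  vecs <- vapply(seq_along(names), function(i) {
    hrr_random(dim, child_seed(seed, paste0("vocab:", names[i]), i),
               mode = mode, sparsity = sparsity)
  }, numeric(dim))
  colnames(vecs) <- names
  structure(list(vectors = vecs, names = names, dim = dim, seed = seed,
                 mode = mode, sparsity = sparsity),
            class = "hrr_vocabulary")
}

#' @export
print.hrr_vocabulary <- function(x, ...) {
  cat(sprintf("<hrr_vocabulary> %d symbols, dim %d, mode %s, seed %d\n",
              length(x$names), x$dim, x$mode, x$seed))
  cat("  ", paste(utils::head(x$names, 12), collapse = " "),
      if (length(x$names) > 12) "..." else "", "\n")
  invisible(x)
}

#' @export
`[[.hrr_vocabulary` <- function(x, name) {
  if (!name %in% x$names) {
    vs_error("vsbind_vocab_miss", sprintf("unknown symbol '%s'", name))
  }
  x$vectors[, name]
}

#' Clean up a noisy vector against a vocabulary
#'
#' Nearest-neighbour (single-shot autoassociative) readout: returns the
#' vocabulary entry with the highest cosine similarity together with that
#' score and the runner-up score. When the best score falls below `threshold`
#' the result is a *no-match* — a distinguishable outcome, not an error —
#' with `matched = FALSE` and `name = NA`. Exact ties are broken towards the
#' lexicographically smaller name, and the tie shows up as
#' `runner_up_score == score`.
#'
#' @param v the noisy vector to identify.
#' @param vocab an [hrr_vocabulary()].
#' @param threshold minimum best cosine for a match (default 0.1).
#' @return an object of class `cleanup_result`: `name`, `score`,
#'   `runner_up_score`, `matched`.
#' @export
cleanup <- function(v, vocab, threshold = 0.1) {
  stopifnot(inherits(vocab, "hrr_vocabulary"))
  if (length(vocab$names) == 0) vs_error("vsbind_param_error", "empty vocabulary")
  vs_check_dim(v, vocab$vectors[, 1])
  nv <- sqrt(sum(v^2))
  if (nv == 0) {
    scores <- rep(0, length(vocab$names))
  } else {
    scores <- unname(as.numeric(crossprod(vocab$vectors, v)) /
                       (nv * sqrt(colSums(vocab$vectors^2))))
  }
  ord <- order(-scores, vocab$names)  # lexicographic tie-break
  best <- ord[1]
  runner <- if (length(ord) > 1) scores[ord[2]] else -1
  matched <- scores[best] >= threshold
  structure(list(name = if (matched) vocab$names[best] else NA_character_,
                 score = scores[best], runner_up_score = runner,
                 matched = matched),
            class = "cleanup_result")
}

#' @export
print.cleanup_result <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("<cleanup> %s (score %.3f, runner-up %.3f)\n",
                x$name, x$score, x$runner_up_score))
  } else {
    cat(sprintf("<cleanup> no match (best %.3f)\n", x$score))
  }
  invisible(x)
}
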
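#' Generate artificial-grammar sequences
#'
#' Seeded generators for the stimulus families used in artificial-grammar
#' learning paradigms:
#'
#' * `"adjacent"`: a matched pair `A<i> B<i>` with spec chunk (1, 2);
#' * `"axb"`: a non-adjacent pair `A<i> X.. X B<i>` with `n_intervening`
#'   irrelevant X tokens; *ungrammatical* variants pair A and B from
#'   mismatched families (`A<i> ... B<j>`, the standard violation), not
#'   random tokens;
#' * `"nested"`: `A1..Ak Bk..B1` with chunks `(i, 2k+1-i)` — centre-embedded
#'   pairings;
#' * `"crossed"`: `A1..Ak B1..Bk` with chunks `(i, k+i)` — cross-serial
#'   pairings.
#'
#' Family indices (and for axb, grammaticality) are drawn from child seeds of
#' `seed`, so output is bit-reproducible.
#'
#' @param kind grammar kind (above).
#' @param n number of sequences (>= 1).
#' @param seed integer seed.
#' @param n_families number of A/B families available (vocabulary size
#'   driver); must be >= 2 for ungrammatical axb pairings.
#' @param n_intervening number of X tokens (axb only; 0 degenerates to an
#'   adjacent pair).
#' @param n_pairs number of dependency pairs k (nested/crossed only).
#' @param p_grammatical probability an axb draw is grammatical (axb only).
#' @return a list of `n` elements, each with `tokens` (character),
#'   `spec` ([structure_spec()]), `grammatical` (logical), and
#'   `salient` (the non-X token names, for [filter_salient()]).
#' @examples
#' gen_grammar_sequences("nested", n = 1, seed = 1, n_pairs = 2)[[1]]
#' @export
gen_grammar_sequences <- function(kind = c("adjacent", "axb", "nested", "crossed"),
                                  n, seed, n_families = 8, n_intervening = 2,
                                  n_pairs = 2, p_grammatical = 0.5) {
  kind <- match.arg(kind)
  if (n < 1) vs_error("vsbind_param_error", "n must be >= 1")
  if (n_families < 2) {
    vs_error("vsbind_param_error", "need at least 2 A/B families")
  }
  lapply(seq_len(n), function(i) {
    set.seed(child_seed(seed, paste0("grammar:", kind), i))
    switch(kind,
      adjacent = {
        fam <- sample.int(n_families, 1)
        list(tokens = c(paste0("A", fam), paste0("B", fam)),
             spec = structure_spec(list(c(1L, 2L)), "adjacent"),
             grammatical = TRUE,
             salient = c(paste0("A", fam), paste0("B", fam)))
      },
      axb = {
        fam <- sample.int(n_families, 1)
        gram <- stats::runif(1) < p_grammatical
        bfam <- if (gram) fam else sample(setdiff(seq_len(n_families), fam), 1)
        xs <- if (n_intervening > 0) {
          paste0("X", sample.int(n_families, n_intervening, replace = TRUE))
        } else character(0)
        toks <- c(paste0("A", fam), xs, paste0("B", bfam))
        list(tokens = toks,
             spec = structure_spec(list(c(1L, length(toks))), "nonadjacent"),
             grammatical = gram,
             salient = c(toks[1], toks[length(toks)]))
      },
      nested = {
        k <- n_pairs
        toks <- c(paste0("A", 1:k), paste0("B", k:1))
        list(tokens = toks,
             spec = structure_spec(lapply(1:k, function(j) c(j, 2L * k + 1L - j)),
                                   "nested"),
             grammatical = TRUE, salient = toks)
      },
      crossed = {
        k <- n_pairs
        toks <- c(paste0("A", 1:k), paste0("B", 1:k))
        list(tokens = toks,
             spec = structure_spec(lapply(1:k, function(j) c(j, k + j)),
                                   "crossed"),
             grammatical = TRUE, salient = toks)
      })
  })
}

#' Vocabulary covering a grammar's token space
#'
#' Convenience constructor for the `A<i>`, `B<i>`, `X<i>` names a grammar
#' generator can emit.
#'
#' @param n_families number of families.
#' @param dim,seed,mode,sparsity as in [hrr_vocabulary()].
#' @return an [hrr_vocabulary()].
#' @export
grammar_vocabulary <- function(n_families, dim, seed, mode = "gaussian",
                               sparsity = 0.05) {
  hrr_vocabulary(c(paste0("A", seq_len(n_families)),
                   paste0("B", seq_len(n_families)),
                   paste0("X", seq_len(n_families))),
                 dim = dim, seed = seed, mode = mode, sparsity = sparsity)
}

#' Monte-Carlo serial-recall capacity benchmark
#'
#' For each (dimensionality, load) pair, encodes `n_trials` random token
#' lists and scores the fraction recalled perfectly by [serial_recall()],
#' exercising the HRR capacity trade-off: repeated superposition degrades
#' the trace, so accuracy falls with load and rises with dimensionality.
#'
#' @param dims dimensionalities to test.
#' @param loads list lengths to test.
#' @param vocab_size vocabulary size per trial.
#' @param n_trials trials per cell.
#' @param seed integer seed; trial t of each cell uses a child seed.
#' @param gamma,rho buffer weighting (defaults: no decay).
#' @return a data frame with one row per (dim, load): `dim`, `load`,
#'   `accuracy` (exact-recall fraction), `mean_top_score`, `n_trials`,
#'   `seed`.
#' @export
benchmark_recall <- function(dims, loads, vocab_size = 32, n_trials = 100,
                             seed = 1, gamma = 1, rho = 0) {
  grid <- expand.grid(dim = dims, load = loads)
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    d <- grid$dim[g]; L <- grid$load[g]
    correct <- 0; score_sum <- 0
    for (t in seq_len(n_trials)) {
      s <- child_seed(seed, sprintf("bench:%d:%d", d, L), t)
      voc <- hrr_vocabulary(sprintf("t%02d", seq_len(vocab_size)), d, s)
      tg <- make_tagset("item", d, L, child_seed(s, "tags"))
      set.seed(child_seed(s, "tokens"))
      toks <- sample(voc$names, L, replace = TRUE)
      tr <- encode_sequence(toks, voc, tg, gamma, rho)
      scores <- vapply(seq_len(L), function(k) {
        r <- recall_item(tr, k, voc, tg, threshold = -1)
        score_ok <- identical(r$name, toks[k])
        c(r$score, score_ok)
      }, numeric(2))
      if (all(scores[2, ] == 1)) correct <- correct + 1
      score_sum <- score_sum + mean(scores[1, ])
    }
    data.frame(dim = d, load = L, accuracy = correct / n_trials,
               mean_top_score = score_sum / n_trials,
               n_trials = n_trials, seed = seed)
  })
  do.call(rbind, rows)
}

#' Activation trace of an accumulating buffer
#'
#' Tracks the squared Euclidean norm of the buffer and the count of entries
#' materially above background (|entry| > `2/sqrt(d)`, a scale-aware
#' reporting convention) after each encoding step. Superposition of
#' quasi-orthogonal unit bindings makes the squared norm grow roughly
#' linearly with the number of superposed terms — net activation rises as a
#' structure accumulates — while a buffer reset (re-sparsification at a
#' chunk boundary) drops it to zero before growth resumes.
#'
#' @param tokens vocabulary names to encode, in order.
#' @param vocab,tags vocabulary and item tag set.
#' @param gamma,rho buffer weighting (defaults: unweighted).
#' @param resets integer steps *after which* the buffer is zeroed (e.g. a
#'   chunk close); positions restart from 1 after each reset.
#' @return a data frame with one row per encoding step (`step`, `token`,
#'   `order`, `sq_norm`, `active_count`, `reset = FALSE`) plus one marker row
#'   per reset (`reset = TRUE`, `sq_norm = 0`).
#' @export
activation_report <- function(tokens, vocab, tags, gamma = 1, rho = 0,
                              resets = integer(0)) {
  tokens <- as.character(tokens)
  if (length(tokens) == 0) vs_error("vsbind_param_error", "no encoding steps")
  check_buffer_params(gamma, rho)
  d <- tags$dim
  thr <- 2 / sqrt(d)
  # Two accumulators keep the running buffer equal to the closed-form trace
  # after every step: the recency part decays by gamma on each append, the
  # primacy part persists undecayed.
  rec <- numeric(d)
  prim <- numeric(d)
  order_k <- 0L
  out <- list()
  for (i in seq_along(tokens)) {
    order_k <- order_k + 1L
    binding <- hrr_bind(tagset_get(tags, order_k), vocab[[tokens[i]]])
    rec <- gamma * rec + binding
    if (rho > 0) prim <- prim + rho^(order_k - 1) * binding
    buf <- rec + prim
    out[[length(out) + 1]] <-
      data.frame(step = i, token = tokens[i], order = order_k,
                 sq_norm = sum(buf^2), active_count = sum(abs(buf) > thr),
                 reset = FALSE)
    if (i %in% resets) {
      rec <- numeric(d)
      prim <- numeric(d)
      order_k <- 0L
      # explicit marker row: the re-sparsified buffer's activity drops to zero
      out[[length(out) + 1]] <-
        data.frame(step = i, token = NA_character_, order = 0L,
                   sq_norm = 0, active_count = 0L, reset = TRUE)
    }
  }
  do.call(rbind, out)
}

#' Orthogonalization-by-binding report
#'
#' Summarizes |cosine| between bound vectors and their constituents. Binding
#' re-codes its inputs into a vector approximately orthogonal to both, so
#' the mean |cosine| is small and shrinks as dimensionality grows. Pairs can
#' be supplied explicitly (a list of `list(bound =, constituents = list())`)
#' or generated from seeded random pairs.
#'
#' @param pairs optional explicit pairs; if `NULL`, `n_pairs` random
#'   gaussian pairs at `dim` are generated and bound.
#' @param n_pairs,dim,seed generation parameters (used when `pairs` is NULL).
#' @return a list: `per_pair` data frame (`pair`, `constituent`, `abs_cos`),
#'   `mean_abs_cos`, `max_abs_cos`, `n`.
#' @export
orthogonality_report <- function(pairs = NULL, n_pairs = 100, dim = 256,
                                 seed = 1) {
  if (is.null(pairs)) {
    pairs <- lapply(seq_len(n_pairs), function(i) {
      a <- hrr_random(dim, child_seed(seed, "ortho:a", i))
      b <- hrr_random(dim, child_seed(seed, "ortho:b", i))
      list(bound = hrr_bind(a, b), constituents = list(a, b))
    })
  }
  if (length(pairs) == 0) vs_error("vsbind_param_error", "no pairs")
  rows <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    data.frame(pair = i,
               constituent = seq_along(p$constituents),
               abs_cos = vapply(p$constituents, function(cst)
                 abs(hrr_similarity(p$bound, cst)), numeric(1)))
  }))
  list(per_pair = rows, mean_abs_cos = mean(rows$abs_cos),
       max_abs_cos = max(rows$abs_cos), n = length(pairs))
}
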
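#' Encode a token sequence into a decaying serial-order buffer
#'
#' Implements the positional-tagging account of serial working memory: each
#' token is bound to the positional tag for its boundary-relative ordinal
#' position and the bindings are superposed,
#' \deqn{Sequence = w_1\, 1\degree \otimes Item_1 + w_2\, 2\degree \otimes Item_2 + \dots}
#' The buffer decays, so late items are encoded more strongly than middle
#' ones (recency), while a primacy component re-weights early items
#' (rehearsal-like input gain):
#' \deqn{w_i = \gamma^{L-i} + \rho^{\,i-1}.}
#' With `gamma = 1, rho = 0` the weights are identically 1 and the trace is
#' the plain unweighted superposition (the primacy component vanishes
#' entirely at `rho = 0`). The defaults `gamma = 0.82, rho = 0.35` produce the
#' classic U-shaped serial-position curve at list length 7.
#'
#' Encoding is incremental in spirit: appending a token to the trace of its
#' prefix, after re-scaling the previous contributions by `gamma`, gives the
#' same closed form.
#'
#' @param tokens character vector of vocabulary names (may be empty).
#' @param vocab an [hrr_vocabulary()].
#' @param tags an [make_tagset()] whose `max_order` is at least
#'   `length(tokens)`.
#' @param gamma recency decay in (0, 1]; 1 means no decay.
#' @param rho primacy weight in \[0, 1); 0 disables the primacy component.
#' @return an object of class `sequence_trace`: `vector`, `length`, `dim`,
#'   `level` (the tag family used), `gamma`, `rho`, and `log` (the input
#'   tokens, kept for inspection only — no decoding path reads it).
#' @examples
#' voc <- hrr_vocabulary(LETTERS[1:8], 1024, seed = 3)
#' tg  <- make_tagset("item", 1024, 8, seed = 3)
#' tr  <- encode_sequence(c("A", "B", "C"), voc, tg, gamma = 1, rho = 0)
#' serial_recall(tr, voc, tg)
#' @export
encode_sequence <- function(tokens, vocab, tags, gamma = 0.82, rho = 0.35) {
  check_buffer_params(gamma, rho)
  tokens <- as.character(tokens)
  L <- length(tokens)
  if (L > tags$max_order) {
    vs_error("vsbind_capacity_error",
             sprintf("sequence of %d exceeds tag capacity %d", L, tags$max_order))
  }
  vec <- encode_weighted(tokens, seq_len(L), decay_weights(L, gamma, rho),
                         vocab, tags)
  structure(list(vector = vec, length = L, dim = tags$dim, level = tags$level,
                 gamma = gamma, rho = rho, log = tokens),
            class = "sequence_trace")
}

check_buffer_params <- function(gamma, rho) {
  if (gamma <= 0 || gamma > 1) {
    vs_error("vsbind_param_error", "gamma must be in (0, 1]")
  }
  if (rho < 0 || rho >= 1) {
    vs_error("vsbind_param_error", "rho must be in [0, 1)")
  }
}

# w_i = gamma^(L-i) + rho^(i-1); the primacy term is identically zero when
# rho = 0, so the gamma = 1, rho = 0 buffer is the unweighted superposition.
decay_weights <- function(L, gamma, rho) {
  if (L == 0) return(numeric(0))
  i <- seq_len(L)
  gamma^(L - i) + if (rho > 0) rho^(i - 1) else 0
}

# Shared accumulation core: the oscillator-gated encoder calls this too, so
# dynamic and static encodings are bitwise identical by construction.
encode_weighted <- function(tokens, orders, weights, vocab, tags) {
  vec <- numeric(tags$dim)
  for (i in seq_along(tokens)) {
    item <- vocab[[tokens[i]]]
    vec <- vec + weights[i] * hrr_bind(tagset_get(tags, orders[i]), item)
  }
  vec
}

#' @export
print.sequence_trace <- function(x, ...) {
  cat(sprintf("<sequence_trace> L = %d, dim %d, gamma %.2f, rho %.2f\n",
              x$length, x$dim, x$gamma, x$rho))
  invisible(x)
}

#' Recall the item at one serial position
#'
#' Retrieval is positional unbinding followed by cleanup:
#' `Item ~ Sequence (x) !Position`, identified against the vocabulary.
#'
#' @param trace a [encode_sequence()] result.
#' @param order serial position, 1-based, at most `trace$length`.
#' @param vocab,tags the vocabulary and tag set used at encoding.
#' @param threshold cleanup no-match threshold.
#' @return a `cleanup_result`.
#' @export
recall_item <- function(trace, order, vocab, tags, threshold = 0.1) {
  stopifnot(inherits(trace, "sequence_trace"))
  if (order < 1 || order > trace$length) {
    vs_error("vsbind_param_error",
             sprintf("position %d outside 1..%d", order, trace$length))
  }
  cleanup(hrr_unbind(trace$vector, tagset_get(tags, order)), vocab, threshold)
}

#' Recall a whole sequence in serial order
#'
#' Applies [recall_item()] at every position 1..L. Positions whose cleanup
#' falls below threshold are reported as the blank token so the output always
#' has length L.
#'
#' @inheritParams recall_item
#' @param blank token standing in for a no-match (default `"∅"`).
#' @return a character vector of length `trace$length`.
#' @export
serial_recall <- function(trace, vocab, tags, threshold = 0.1,
                          blank = "\u2205") {
  if (trace$length == 0) return(character(0))
  vapply(seq_len(trace$length), function(k) {
    r <- recall_item(trace, k, vocab, tags, threshold)
    if (r$matched) r$name else blank
  }, character(1))
}
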
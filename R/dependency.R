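#' Salience-filter a token sequence
#'
#' Dependency encoding operates on the salient constituents only: irrelevant
#' intervening items (the X's of an A-X^n-B sequence) are suppressed before
#' anything reaches the dependency buffer. Filtering keeps the salient tokens
#' in order and re-indexes their positions from 1, so the downstream encoding
#' is boundary-relative: an A-X^n-B sequence filters to exactly the same
#' token list as A-B, for every n, and hence to bit-identical codes.
#'
#' @param tokens non-empty character vector.
#' @param salient either a character vector of salient token names or an
#'   integer vector of salient serial positions (1-based).
#' @return the salient subsequence, in order.
#' @examples
#' filter_salient(c("A", "X", "X", "B"), c("A", "B"))  # "A" "B"
#' @export
filter_salient <- function(tokens, salient) {
  if (length(tokens) == 0) vs_error("vsbind_param_error", "empty token list")
  keep <- if (is.numeric(salient)) {
    seq_along(tokens) %in% as.integer(salient)
  } else {
    tokens %in% as.character(salient)
  }
  out <- tokens[keep]
  if (length(out) == 0) {
    vs_error("vsbind_spec_error", "salience mask removed every token")
  }
  out
}

#' Encode a chunk (dependency) of tokens
#'
#' A chunk is the unweighted superposition of position (x) item bindings over
#' its constituents: \eqn{\sum_k k\degree_I \otimes item_k}. Unlike the
#' serial-order buffer the dependency buffer applies no decay — its
#' constituents are saliently maintained — which is what makes the
#' non-adjacent and adjacent encodings of the same salient pair bit-identical.
#'
#' @param tokens 1 to `item_tags$max_order` vocabulary names.
#' @param vocab an [hrr_vocabulary()].
#' @param item_tags the item-level [make_tagset()].
#' @return a numeric vector of dimension `item_tags$dim`.
#' @examples
#' voc <- hrr_vocabulary(c("A", "B"), 512, seed = 1)
#' tg  <- make_tagset("item", 512, 2, seed = 1)
#' ch  <- encode_chunk(c("A", "B"), voc, tg)
#' cleanup(hrr_unbind(ch, tg$tags[, 2]), voc)  # "B"
#' @export
encode_chunk <- function(tokens, vocab, item_tags) {
  L <- length(tokens)
  if (L < 1) vs_error("vsbind_param_error", "empty chunk")
  if (L > item_tags$max_order) {
    vs_error("vsbind_capacity_error",
             sprintf("chunk of %d exceeds tag capacity %d", L, item_tags$max_order))
  }
  encode_weighted(as.character(tokens), seq_len(L), rep(1, L), vocab, item_tags)
}

#' Encode a dependency with context-keyed positional tags
#'
#' Positional tags can vary by context as well as by position: the tag base
#' is selected by a context label, here keyed to the dependency's governing
#' (first) element. This matters for grammaticality memory: an additive
#' memory of plain position-item chunks records which items occurred at
#' which positions but nothing about their pairings, so matched and
#' mismatched A-B pairs score alike. With context-keyed tags the non-initial
#' items are bound to tags specific to the governing element, so the memory
#' trace carries the co-occurrence structure and family-mismatched probes
#' score reliably lower familiarity.
#'
#' The tag family is regenerated deterministically from `(seed, context)`,
#' so no lookup table is needed at decode time — re-instantiating the same
#' context label yields the same keys.
#'
#' @param tokens salient tokens of the dependency (pass the output of
#'   [filter_salient()]).
#' @param vocab an [hrr_vocabulary()].
#' @param seed tag-generation seed (one per model, not per exemplar).
#' @param context context label; defaults to the first token.
#' @param max_order tag capacity; defaults to `length(tokens)`.
#' @return a numeric vector of dimension `vocab$dim`.
#' @export
encode_dependency <- function(tokens, vocab, seed, context = tokens[1],
                              max_order = length(tokens)) {
  tg <- make_tagset(paste0("ctx:", context), vocab$dim, max_order, seed)
  encode_chunk(tokens, vocab, tg)
}

#' Declare a chunk layout over serial positions
#'
#' A structure specification says which serial positions of a source sequence
#' form which chunks. Positions are 1-based indices into the source token
#' list; within a chunk they must be strictly increasing and no position may
#' be claimed by two chunks. For `kind = "nested"` the chunk spans, projected
#' to intervals, must be properly nested or disjoint (A1 A2 B2 B1); for
#' `kind = "crossed"` at least two spans must interleave (A1 A2 B1 B2).
#'
#' @param chunks a list of integer vectors of serial positions, in chunk
#'   order.
#' @param kind one of `"adjacent"`, `"nonadjacent"`, `"nested"`, `"crossed"`,
#'   `"custom"`.
#' @return an object of class `structure_spec`.
#' @examples
#' structure_spec(list(c(1, 4), c(2, 3)), kind = "nested")
#' @export
structure_spec <- function(chunks,
                           kind = c("custom", "adjacent", "nonadjacent",
                                    "nested", "crossed")) {
  kind <- match.arg(kind)
  if (length(chunks) == 0) vs_error("vsbind_spec_error", "no chunks")
  chunks <- lapply(chunks, as.integer)
  for (ch in chunks) {
    if (length(ch) == 0 || any(ch < 1) || any(diff(ch) <= 0)) {
      vs_error("vsbind_spec_error",
               "chunk positions must be strictly increasing and >= 1")
    }
  }
  all_pos <- unlist(chunks)
  if (anyDuplicated(all_pos)) {
    vs_error("vsbind_spec_error", "a serial position appears in two chunks")
  }
  iv <- t(vapply(chunks, range, integer(2)))
  crossing <- FALSE
  if (length(chunks) > 1) {
    for (a in seq_len(length(chunks) - 1)) {
      for (b in (a + 1):length(chunks)) {
        lo <- iv[, 1]; hi <- iv[, 2]
        disjoint <- hi[a] < lo[b] || hi[b] < lo[a]
        nested_ab <- (lo[a] <= lo[b] && hi[b] <= hi[a]) ||
          (lo[b] <= lo[a] && hi[a] <= hi[b])
        if (!disjoint && !nested_ab) crossing <- TRUE
      }
    }
  }
  if (kind == "nested" && crossing) {
    vs_error("vsbind_spec_error", "chunk spans interleave; not a nested layout")
  }
  if (kind == "crossed" && !crossing) {
    vs_error("vsbind_spec_error", "no interleaving chunk spans; not a crossed layout")
  }
  structure(list(chunks = chunks, kind = kind), class = "structure_spec")
}

#' @export
print.structure_spec <- function(x, ...) {
  cat(sprintf("<structure_spec> %s: %s\n", x$kind,
              paste(vapply(x$chunks, function(ch)
                paste0("(", paste(ch, collapse = ","), ")"), character(1)),
                collapse = " ")))
  invisible(x)
}

#' Encode a hierarchical structure as a superchunk
#'
#' Each chunk named by the spec is gathered from the source tokens (items
#' re-indexed from 1 within the chunk — boundary-relative), encoded with
#' [encode_chunk()], bound to its chunk-level tag, and the chunk bindings are
#' superposed:
#' \deqn{Structure = \sum_c c\degree_C \otimes \big(\sum_i i\degree_I \otimes item_{c,i}\big).}
#' Nested and crossed dependencies use the identical mechanism — only the
#' spec's position layout differs. The result keeps the atomic
#' dimensionality no matter the depth (a reduced representation).
#'
#' @param tokens source token sequence (vocabulary names).
#' @param spec a [structure_spec()].
#' @param vocab an [hrr_vocabulary()].
#' @param item_tags,chunk_tags tag sets for the two levels.
#' @return an object of class `structure_trace`: `vector`, `spec`, `dim`,
#'   `item_level`, `chunk_level`, `levels` (2).
#' @examples
#' voc <- hrr_vocabulary(c("A1", "A2", "B1", "B2"), 1024, seed = 5)
#' it <- make_tagset("item", 1024, 2, seed = 5)
#' ch <- make_tagset("chunk", 1024, 2, seed = 5)
#' sp <- structure_spec(list(c(1, 4), c(2, 3)), "nested")
#' st <- encode_structure(c("A1", "A2", "B2", "B1"), sp, voc, it, ch)
#' unpack_structure(st, voc, it, ch)
#' @export
encode_structure <- function(tokens, spec, vocab, item_tags, chunk_tags) {
  stopifnot(inherits(spec, "structure_spec"))
  tokens <- as.character(tokens)
  if (max(unlist(spec$chunks)) > length(tokens)) {
    vs_error("vsbind_spec_error", "spec references positions beyond the sequence")
  }
  if (length(spec$chunks) > chunk_tags$max_order) {
    vs_error("vsbind_capacity_error", "more chunks than chunk tags")
  }
  vec <- numeric(chunk_tags$dim)
  for (c_i in seq_along(spec$chunks)) {
    chunk_vec <- encode_chunk(tokens[spec$chunks[[c_i]]], vocab, item_tags)
    vec <- vec + hrr_bind(tagset_get(chunk_tags, c_i), chunk_vec)
  }
  structure(list(vector = vec, spec = spec, dim = chunk_tags$dim,
                 item_level = item_tags$level, chunk_level = chunk_tags$level,
                 levels = 2L),
            class = "structure_trace")
}

#' @export
print.structure_trace <- function(x, ...) {
  cat(sprintf("<structure_trace> %d chunks (%s), dim %d\n",
              length(x$spec$chunks), x$spec$kind, x$dim))
  invisible(x)
}

#' Query a structure trace with a composite key
#'
#' Unbinds the trace with an inverted key. A fully specified key (an order at
#' both the chunk and item level, e.g. !(2°_I (x) 1°_C)) releases a single
#' slot, cleaned up directly. A partially specified key releases a whole
#' stratum: !1°_C recovers all position-item bindings of the first chunk, and
#' the unspecified level's tags are then iterated to clean up each slot in
#' turn; !2°_I likewise recovers the second item of every chunk, iterated in
#' chunk order.
#'
#' @param trace a [encode_structure()] result.
#' @param key an inverted [compose_key()] over the trace's levels.
#' @param vocab the vocabulary for cleanup.
#' @param item_tags,chunk_tags tag sets; needed to iterate whichever level
#'   the key leaves unspecified.
#' @param threshold cleanup no-match threshold.
#' @return a list of `cleanup_result` (length 1 if the key is full).
#' @export
query_structure <- function(trace, key, vocab, item_tags = NULL,
                            chunk_tags = NULL, threshold = 0.1) {
  stopifnot(inherits(trace, "structure_trace"), inherits(key, "query_key"))
  if (!key$inverted) vs_error("vsbind_state_error", "key must be inverted first")
  lvls <- names(key$level_orders)
  known <- c(trace$item_level, trace$chunk_level)
  if (!all(lvls %in% known)) {
    vs_error("vsbind_key_error",
             sprintf("key levels (%s) not in trace levels (%s)",
                     paste(lvls, collapse = ","), paste(known, collapse = ",")))
  }
  released <- hrr_bind(trace$vector, key$vector)
  missing_lvl <- setdiff(known, lvls)
  if (length(missing_lvl) == 0) {
    return(list(cleanup(released, vocab, threshold)))
  }
  iter <- if (missing_lvl == trace$item_level) item_tags else chunk_tags
  if (is.null(iter) || iter$level != missing_lvl) {
    vs_error("vsbind_key_error",
             sprintf("tag set for level '%s' needed to iterate slots", missing_lvl))
  }
  lapply(seq_len(iter$max_order), function(k) {
    cleanup(hrr_unbind(released, tagset_get(iter, k)), vocab, threshold)
  })
}

#' Fully decode a structure trace
#'
#' Iterates every (chunk, item) key from [all_keys()] and cleans up each
#' released slot, recovering all constituents with their positions. Slots
#' that clean up below threshold are omitted; their count is attached as the
#' `n_nomatch` attribute.
#'
#' @inheritParams query_structure
#' @return a data frame with columns `chunk`, `item`, `name`, `score`, one
#'   row per recovered slot, ordered chunk-major.
#' @export
unpack_structure <- function(trace, vocab, item_tags, chunk_tags,
                             threshold = 0.1) {
  stopifnot(inherits(trace, "structure_trace"))
  keys <- all_keys(list(chunk_tags, item_tags))
  rows <- lapply(keys, function(k) {
    r <- cleanup(hrr_bind(trace$vector, k$vector), vocab, threshold)
    if (!r$matched) return(NULL)
    data.frame(chunk = as.integer(k$level_orders[[chunk_tags$level]]),
               item = as.integer(k$level_orders[[item_tags$level]]),
               name = r$name, score = r$score, stringsAsFactors = FALSE)
  })
  nomatch <- sum(vapply(rows, is.null, logical(1)))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chunk = integer(0), item = integer(0),
                      name = character(0), score = numeric(0))
  }
  attr(out, "n_nomatch") <- nomatch
  out
}

#' Accumulate dependency traces into a long-term memory trace
#'
#' Superposing many dependency representations over time yields a memory
#' trace shaped by the distribution of structures encountered — an implicit
#' learning stand-in. Weights can emulate rehearsal. Similarity of a new
#' structure's vector to the accumulated trace acts as a familiarity score
#' (see [familiarity()]).
#'
#' @param traces a list of `structure_trace` objects or plain numeric
#'   vectors, all of one dimensionality.
#' @param weights non-negative weights, recycled from length 1.
#' @return the weighted superposition (numeric vector).
#' @export
accumulate_grammar_trace <- function(traces, weights = 1) {
  if (length(traces) == 0) vs_error("vsbind_param_error", "no traces")
  vecs <- lapply(traces, function(tr) {
    if (inherits(tr, "structure_trace") || inherits(tr, "sequence_trace")) {
      tr$vector
    } else tr
  })
  if (length(weights) == 1) weights <- rep(weights, length(vecs))
  if (length(weights) != length(vecs)) {
    vs_error("vsbind_param_error", "weights and traces differ in length")
  }
  if (any(weights < 0)) vs_error("vsbind_param_error", "weights must be >= 0")
  out <- numeric(length(vecs[[1]]))
  for (i in seq_along(vecs)) {
    vs_check_dim(out, vecs[[i]])
    out <- out + weights[i] * vecs[[i]]
  }
  out
}

#' Familiarity of a probe trace to an accumulated memory trace
#'
#' Cosine similarity between a probe and the accumulated trace; continuous —
#' grammaticality thresholding, if wanted, is left to the caller.
#'
#' @param probe a trace object or numeric vector.
#' @param memory the accumulated trace (numeric vector).
#' @return a scalar in \[-1, 1\].
#' @export
familiarity <- function(probe, memory) {
  if (inherits(probe, "structure_trace") || inherits(probe, "sequence_trace")) {
    probe <- probe$vector
  }
  hrr_similarity(probe, memory)
}
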
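#' Build a level-specific set of positional tags
#'
#' Positional tags mark boundary-relative ordinal position ("primary",
#' "secondary", ...; written 1°, 2°) within a chunk or sequence. Each level of
#' the hierarchy (items, chunks, superchunks) gets its own tag family so that
#' distinct structures never collapse to identical codes. Tags are generated
#' as convolutional powers of a single unitary base vector by repeated
#' self-binding: `tags[[1]]` is the base and `tags[[k]] = tags[[k-1]] (x) base`,
#' i.e. 2° = 1° (x) 1°. Because the base is unitary every tag is unitary too,
#' so every tag has an exact inverse and positional unbinding is lossless up
#' to superposition noise.
#'
#' The base is drawn from a child seed of `(seed, level)`. At `dim >= 256` the
#' construction screens the family for mutual coherence: if any pair of
#' distinct tags has |cosine| above `coherence_limit` the base is regenerated
#' with the next child seed, up to 10 times, after which a capacity error
#' advises a larger dimensionality.
#'
#' @param level a label naming the hierarchy level (e.g. `"item"`, `"chunk"`).
#'   Distinct labels yield independent bases.
#' @param dim dimensionality (>= 2).
#' @param max_order number of tags K (>= 1).
#' @param seed integer seed; the same `(level, dim, max_order, seed)` always
#'   reproduces the same tags bit-for-bit.
#' @param coherence_limit maximum tolerated |cosine| between distinct tags
#'   when screening (default 0.2).
#' @return an object of class `hrr_tagset`: `level`, `base`, `max_order`,
#'   `tags` (a `dim x max_order` matrix, column k = tag k°), `dim`, `seed`.
#' @examples
#' ts <- make_tagset("item", dim = 256, max_order = 4, seed = 1)
#' all.equal(ts$tags[, 2], hrr_bind(ts$tags[, 1], ts$tags[, 1]))
#' @export
make_tagset <- function(level, dim, max_order, seed, coherence_limit = 0.2) {
  if (max_order < 1) vs_error("vsbind_param_error", "max_order must be >= 1")
  if (dim < 2) vs_error("vsbind_param_error", "dim must be >= 2")
  for (attempt in 0:9) {
    base <- hrr_random(dim, child_seed(seed, paste0("tagset:", level), attempt),
                       mode = "unitary")
    tags <- matrix(0, dim, max_order)
    tags[, 1] <- base
    if (max_order > 1) {
      for (k in 2:max_order) tags[, k] <- hrr_bind(tags[, k - 1], base)
    }
    ok <- TRUE
    if (dim >= 256 && max_order > 1) {
      co <- abs(crossprod(tags))  # tags are unit norm
      diag(co) <- 0
      ok <- max(co) < coherence_limit
    }
    if (ok) {
      return(structure(list(level = level, base = base, max_order = max_order,
                            tags = tags, dim = dim, seed = seed),
                       class = "hrr_tagset"))
    }
  }
  vs_error("vsbind_capacity_error",
           sprintf("could not find a tag family with |cos| < %.2f at dim %d; use a larger dim",
                   coherence_limit, dim))
}

#' @export
print.hrr_tagset <- function(x, ...) {
  cat(sprintf("<hrr_tagset> level '%s', %d tags, dim %d, seed %d\n",
              x$level, x$max_order, x$dim, x$seed))
  invisible(x)
}

tagset_get <- function(tags, order) {
  stopifnot(inherits(tags, "hrr_tagset"))
  if (order < 1 || order > tags$max_order) {
    vs_error("vsbind_key_error",
             sprintf("order %d out of range 1..%d for level '%s'",
                     order, tags$max_order, tags$level))
  }
  tags$tags[, order]
}

find_tagset <- function(tagsets, level) {
  if (inherits(tagsets, "hrr_tagset")) tagsets <- list(tagsets)
  for (ts in tagsets) if (ts$level == level) return(ts)
  vs_error("vsbind_key_error", sprintf("no tag set for level '%s'", level))
}

#' Compose a (possibly multi-level) query key
#'
#' A query key addresses a slot in a hierarchical trace by naming an order at
#' one or more levels, e.g. `c(item = 2, chunk = 1)` for "the second item of
#' the first chunk". The key vector is the bind-product of the named tags —
#' binding commutes, so the order of levels is immaterial — written
#' 2°_I (x) 1°_C in the algebra. Apply [invert_key()] before querying.
#'
#' @param tagsets an [make_tagset()] object or list of them, one per level.
#' @param orders a named integer vector, `c(<level> = <order>, ...)`.
#' @return an object of class `query_key`: `level_orders` (named integer),
#'   `vector`, `inverted` (FALSE).
#' @examples
#' it <- make_tagset("item", 256, 2, 1); ch <- make_tagset("chunk", 256, 2, 1)
#' k <- compose_key(list(it, ch), c(item = 2, chunk = 1))
#' @export
compose_key <- function(tagsets, orders) {
  if (is.null(names(orders)) || any(!nzchar(names(orders)))) {
    vs_error("vsbind_key_error", "orders must be a named vector, c(level = order)")
  }
  vec <- NULL
  for (i in seq_along(orders)) {
    tg <- tagset_get(find_tagset(tagsets, names(orders)[i]), orders[[i]])
    vec <- if (is.null(vec)) tg else hrr_bind(vec, tg)
  }
  structure(list(level_orders = orders, vector = vec, inverted = FALSE),
            class = "query_key")
}

#' Invert a query key
#'
#' Replaces the key vector by its involution so it can be bound with a trace
#' to release the addressed slot. Because tags are unitary the inversion is
#' exact. A key can only be inverted once.
#'
#' @param key a [compose_key()] result with `inverted = FALSE`.
#' @return the key with `vector` involuted and `inverted = TRUE`.
#' @export
invert_key <- function(key) {
  stopifnot(inherits(key, "query_key"))
  if (key$inverted) vs_error("vsbind_state_error", "key is already inverted")
  key$vector <- hrr_inverse(key$vector)
  key$inverted <- TRUE
  key
}

#' @export
print.query_key <- function(x, ...) {
  cat(sprintf("<query_key>%s %s\n", if (x$inverted) " !" else "",
              paste(sprintf("%s:%d", names(x$level_orders),
                            as.integer(x$level_orders)), collapse = " (x) ")))
  invisible(x)
}

#' Enumerate every inverted key over a set of levels
#'
#' Iterating through every possible tag combination retrieves all stored
#' constituents of a trace in sequence. Keys are enumerated coarse-major in
#' the order the tag sets are given, with the last-listed level varying
#' fastest; `list(chunk, item)` therefore yields
#' (1_C,1_I), (1_C,2_I), (2_C,1_I), (2_C,2_I). Every key is returned already
#' inverted, ready for [query_structure()].
#'
#' @param tagsets a non-empty list of [make_tagset()] objects (coarse first).
#' @return a list of inverted `query_key` objects.
#' @export
all_keys <- function(tagsets) {
  if (inherits(tagsets, "hrr_tagset")) tagsets <- list(tagsets)
  if (length(tagsets) == 0) vs_error("vsbind_param_error", "no tag sets given")
  grids <- lapply(rev(tagsets), function(ts) seq_len(ts$max_order))
  combos <- expand.grid(grids)  # first column varies fastest = last level
  lvls <- vapply(tagsets, function(ts) ts$level, character(1))
  lapply(seq_len(nrow(combos)), function(i) {
    orders <- stats::setNames(rev(as.integer(combos[i, ])), lvls)
    invert_key(compose_key(tagsets, orders))
  })
}
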
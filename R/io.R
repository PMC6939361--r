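# Serialization: every on-disk object is a JSON sidecar (<path>.json) holding
# the metadata plus, where an array is stored, a tab-separated matrix
# (<path>.vec) of float64 written with "%.17g", which round-trips doubles
# bit-exactly.

write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = "\t"), con)
  }
  invisible(path)
}

read_matrix_txt <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  do.call(rbind, lapply(rows, as.numeric))
}

sidecar <- function(path) paste0(path, ".json")
arrfile <- function(path) paste0(path, ".vec")

#' Write and read a vocabulary container
#'
#' Stores the vocabulary as a JSON sidecar (`<path>.json`: names, dim, mode,
#' seed, sparsity) plus a `<path>.vec` matrix, one row per name in JSON name
#' order. The round trip is bit-exact.
#'
#' @param vocab an [hrr_vocabulary()].
#' @param path file stem (no extension).
#' @return `path`, invisibly (`write`); the vocabulary (`read`).
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "hrr_vocabulary"))
  meta <- list(type = "vocabulary", names = vocab$names, dim = vocab$dim,
               seed = vocab$seed, mode = vocab$mode, sparsity = vocab$sparsity)
  jsonlite::write_json(meta, sidecar(path), auto_unbox = TRUE, digits = NA)
  write_matrix_txt(t(vocab$vectors), arrfile(path))
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  meta <- jsonlite::read_json(sidecar(path), simplifyVector = TRUE)
  stopifnot(identical(meta$type, "vocabulary"))
  vecs <- t(read_matrix_txt(arrfile(path)))
  colnames(vecs) <- meta$names
  structure(list(vectors = vecs, names = meta$names, dim = as.integer(meta$dim),
                 seed = as.integer(meta$seed), mode = meta$mode,
                 sparsity = meta$sparsity),
            class = "hrr_vocabulary")
}

#' Write and read a tag-set container
#'
#' Same container convention as [write_vocabulary()]: JSON metadata plus the
#' tag matrix (rows = orders 1..K). Bit-exact round trip.
#'
#' @param tags an [make_tagset()].
#' @param path file stem.
#' @export
write_tagset <- function(tags, path) {
  stopifnot(inherits(tags, "hrr_tagset"))
  meta <- list(type = "tagset", level = tags$level, dim = tags$dim,
               max_order = tags$max_order, seed = tags$seed)
  jsonlite::write_json(meta, sidecar(path), auto_unbox = TRUE, digits = NA)
  write_matrix_txt(t(cbind(tags$base, tags$tags)), arrfile(path))
  invisible(path)
}

#' @rdname write_tagset
#' @export
read_tagset <- function(path) {
  meta <- jsonlite::read_json(sidecar(path), simplifyVector = TRUE)
  stopifnot(identical(meta$type, "tagset"))
  m <- t(read_matrix_txt(arrfile(path)))
  structure(list(level = meta$level, base = m[, 1],
                 max_order = as.integer(meta$max_order),
                 tags = m[, -1, drop = FALSE], dim = as.integer(meta$dim),
                 seed = as.integer(meta$seed)),
            class = "hrr_tagset")
}

#' Write and read a sequence trace
#'
#' JSON metadata plus the trace vector. The token log is omitted unless
#' `with_log = TRUE` (it is inspection-only metadata; nothing in decoding
#' reads it).
#'
#' @param trace a `sequence_trace`.
#' @param path file stem.
#' @param with_log include the token log in the sidecar.
#' @export
write_trace <- function(trace, path, with_log = FALSE) {
  stopifnot(inherits(trace, "sequence_trace"))
  meta <- list(type = "sequence_trace", length = trace$length, dim = trace$dim,
               level = trace$level, gamma = trace$gamma, rho = trace$rho)
  if (with_log) meta$log <- trace$log
  jsonlite::write_json(meta, sidecar(path), auto_unbox = TRUE, digits = NA)
  write_matrix_txt(matrix(trace$vector, nrow = 1), arrfile(path))
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  meta <- jsonlite::read_json(sidecar(path), simplifyVector = TRUE)
  stopifnot(identical(meta$type, "sequence_trace"))
  structure(list(vector = as.numeric(read_matrix_txt(arrfile(path))[1, ]),
                 length = as.integer(meta$length), dim = as.integer(meta$dim),
                 level = meta$level, gamma = meta$gamma, rho = meta$rho,
                 log = if (is.null(meta$log)) character(0) else meta$log),
            class = "sequence_trace")
}

#' Read or write a structure spec as JSON
#'
#' Format: `{"kind": "nested", "chunks": [[1,4],[2,3]]}` with 1-based serial
#' positions.
#'
#' @param spec a [structure_spec()].
#' @param path JSON file path.
#' @export
write_structure_spec <- function(spec, path) {
  stopifnot(inherits(spec, "structure_spec"))
  jsonlite::write_json(list(kind = spec$kind, chunks = spec$chunks), path,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_structure_spec
#' @export
read_structure_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  chunks <- if (is.matrix(x$chunks)) {
    lapply(seq_len(nrow(x$chunks)), function(i) x$chunks[i, ])
  } else as.list(x$chunks)
  structure_spec(chunks, kind = x$kind)
}

#' Write an oscillator event log as CSV
#'
#' Columns: `time_step`, `source`, `kind`, `decoded_order`.
#'
#' @param events an event data frame.
#' @param path CSV path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
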
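#' Mask a repeat array out of a spacer record
#'
#' Excises the array span exactly and joins the flanking segments, so the
#' divergent repeat region cannot distort the spacer alignment.  The
#' excised interval and substring are recorded: concatenating the masked
#' pieces with the excised substring reconstructs the original sequence.
#'
#' @param record A [spacer_record()] or a single named sequence.
#' @param array A `repeat_array` (or NULL / zero-length span for no-op).
#' @return A `masked_spacer`: list with `id`, `sequence`, `excised`
#'   (0-based half-open interval), `excised_seq`, `original_length`.
#' @export
mask_repeats <- function(record, array) {
  if (!inherits(record, "spacer_record")) {
    id <- names(record) %||% "seq"
    record <- spacer_record(id[1], record[[1]])
  }
  n <- nchar(record$sequence)
  if (is.null(array) || (!is.null(array$span) && diff(array$span) == 0L)) {
    return(structure(list(id = record$id, sequence = record$sequence,
                          excised = c(0L, 0L), excised_seq = "",
                          original_length = n),
                     class = "masked_spacer"))
  }
  span <- array$span
  if (span[1] < 0L || span[2] > n || span[1] > span[2])
    stop("array span out of bounds for record ", record$id)
  masked <- paste0(substr(record$sequence, 1L, span[1]),
                   substr(record$sequence, span[2] + 1L, n))
  structure(list(id = record$id, sequence = masked,
                 excised = c(span[1], span[2]),
                 excised_seq = substr(record$sequence, span[1] + 1L, span[2]),
                 original_length = n),
            class = "masked_spacer")
}

#' @export
print.masked_spacer <- function(x, ...) {
  cat(sprintf("Masked spacer %s: %d nt (excised [%d, %d) of %d)\n",
              x$id, nchar(x$sequence), x$excised[1], x$excised[2],
              x$original_length))
  invisible(x)
}
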
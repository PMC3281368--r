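## Unit delimitation inside a detected array: unit boundaries sit at
## occurrences of the conserved 5' motif, preferentially at "junctions"
## where the 3' motif of one unit abuts the 5' motif of the next.  Units
## whose motifs have decayed fall back to periodic cuts and are flagged.

#' A spacer record
#'
#' @param id Record identifier.
#' @param sequence Nucleotide sequence (IUPAC letters; uppercased).
#' @param species_code Short species label used to name units (defaults to
#'   the record id, which keeps unit names unique across records).
#' @return A `spacer_record` list.
#' @export
spacer_record <- function(id, sequence, species_code = NULL) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty")
  bad <- which(!seq_to_chars(sequence) %in% IUPAC_LETTERS)
  if (length(bad))
    stop("non-IUPAC character at position ", bad[1], " in record ", id)
  structure(list(id = id,
                 species_code = species_code %||% id,
                 sequence = sequence),
            class = "spacer_record")
}

#' Delimit repeat units inside an array span
#'
#' Boundaries are placed at occurrences of `motif5` (IUPAC semantics, so
#' `CAYCC` covers CACCC and CATCC for `motif3`), preferring junction
#' positions where a `motif3` occurrence ends within 2 nt of a `motif5`
#' start.  The unit period is re-estimated from the junction spacing (the
#' dot-plot period can be a multiple of the true unit length when adjacent
#' units belong to different groups).  Long gaps between junctions are
#' subdivided by periodic cuts snapped to nearby `motif5` hits; cuts with
#' no motif support are flagged `"periodic_fallback"`.  Short terminal
#' units are retained as long as their motifs are present.
#'
#' @param sequence The full spacer sequence.
#' @param array_span 0-based half-open interval from [infer_array()].
#' @param period Estimated repeat period (nt).
#' @param motif5,motif3 Terminal motifs (IUPAC strings).
#' @return A `repeat_array`: list with `span` (0-based half-open) and a
#'   `units` data.frame (`index`, `start`, `end`, `flag`).
#' @export
delimit_units <- function(sequence, array_span, period,
                          motif5 = "GGGTG", motif3 = "CAYCC") {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  span_len <- array_span[2] - array_span[1]
  if (span_len < period) stop("array span shorter than one period")
  len3 <- nchar(motif3)
  min_sep <- nchar(motif5) + len3 + 10L

  h5 <- motif_hits(sequence, motif5)
  h3e <- motif_hits(sequence, motif3) + len3
  junctions <- h5[vapply(h5, function(p) any(abs(h3e - p) <= 2L), logical(1))]

  win <- c(array_span[1] - 3 * period, array_span[2] + 3 * period)
  junctions <- sort(junctions[junctions >= win[1] & junctions <= win[2]])

  if (length(junctions) == 0L)
    return(periodic_array(sequence, array_span, period, h5))

  ## unit period from junction spacing (robust to multi-group dot-plot
  ## periods, which are multiples of the true unit length): junction gaps
  ## that are plausible single-unit lengths vote; gaps spanning a missing
  ## junction (about a multiple of the period) do not
  jd <- diff(junctions)
  jd <- jd[jd >= min_sep]
  cand <- cluster_reps(sort(jd), 5)
  cand <- cand[cand <= 1.5 * period]
  p_unit <- if (length(cand)) round(stats::median(cand)) else period
  if (is.na(p_unit) || p_unit < min_sep) p_unit <- period

  ## chain junctions: links up to ~2.6 unit lengths (a missing junction is
  ## bridged and subdivided below); pick the chain overlapping the span most
  chains <- split(junctions, cumsum(c(TRUE, diff(junctions) > 2.6 * p_unit)))
  overlap <- vapply(chains, function(ch) {
    lo <- max(min(ch) - p_unit, array_span[1]); hi <- min(max(ch) + p_unit, array_span[2])
    max(0, hi - lo)
  }, numeric(1))
  chain <- chains[[which.max(overlap)]]

  ## first unit start: motif5 hit one unit-length before the first
  ## junction, preferring a hit at the array-span boundary when one is
  ## there (the span anchors the terminal unit; ties fall to the grid)
  first_cand <- h5[h5 < chain[1] & chain[1] - h5 >= min_sep &
                     chain[1] - h5 <= 1.6 * p_unit]
  flags <- character(0)
  if (length(first_cand)) {
    near_span <- first_cand[abs(first_cand - array_span[1]) <= 10L]
    s0 <- if (length(near_span))
      near_span[which.min(abs(near_span - array_span[1]))]
    else first_cand[which.min(abs((chain[1] - first_cand) - p_unit))]
    f0 <- ""
  } else {
    s0 <- max(0L, chain[1] - p_unit)
    f0 <- "periodic_fallback"
  }
  cuts <- c(s0, chain)
  flags <- c(f0, rep("", length(chain)))

  ## last unit end: motif3 end past the last start, preferring a hit at
  ## the span boundary, otherwise the one nearest the periodic grid
  last <- cuts[length(cuts)]
  end_cand <- h3e[h3e >= last + min_sep & h3e <= last + 1.6 * p_unit]
  if (length(end_cand)) {
    near_span <- end_cand[abs(end_cand - array_span[2]) <= 10L]
    array_end <- if (length(near_span))
      near_span[which.min(abs(near_span - array_span[2]))]
    else end_cand[which.min(abs(end_cand - (last + p_unit)))]
    end_flag <- ""
  } else {
    array_end <- min(n, last + p_unit)
    end_flag <- "periodic_fallback"
  }
  if (nzchar(end_flag))
    flags[length(flags)] <- paste0(flags[length(flags)], end_flag)

  ## subdivide gaps spanning more than ~1.7 unit lengths
  bounds <- c(cuts, array_end)
  new_cuts <- numeric(0); new_flags <- character(0)
  for (k in seq_len(length(bounds) - 1L)) {
    gap <- bounds[k + 1L] - bounds[k]
    new_cuts <- c(new_cuts, bounds[k]); new_flags <- c(new_flags, flags[k])
    if (gap > 1.7 * p_unit) {
      m <- round(gap / p_unit)
      if (m >= 2L) {
        extra <- bounds[k] + round(gap / m * seq_len(m - 1L))
        for (x in extra) {
          near <- h5[abs(h5 - x) <= 10L]
          if (length(near)) {
            new_cuts <- c(new_cuts, near[which.min(abs(near - x))])
            new_flags <- c(new_flags, "grid_snap")
          } else {
            new_cuts <- c(new_cuts, x)
            new_flags <- c(new_flags, "periodic_fallback")
          }
        }
      }
    }
  }
  ord <- order(new_cuts)
  new_cuts <- as.integer(new_cuts[ord]); new_flags <- new_flags[ord]
  starts <- new_cuts
  ends <- c(new_cuts[-1L], as.integer(array_end))
  keep <- ends - starts >= min_sep
  repeat_array_obj(starts[keep], ends[keep], new_flags[keep])
}

## pure periodic fallback when no junction is recoverable
#' @noRd
periodic_array <- function(sequence, array_span, period, h5) {
  n_units <- max(1L, round((array_span[2] - array_span[1]) / period))
  grid <- array_span[1] + round((array_span[2] - array_span[1]) / n_units *
                                  (seq_len(n_units) - 1L))
  starts <- integer(0); flags <- character(0)
  for (g in grid) {
    near <- h5[abs(h5 - g) <= 10L]
    if (length(near)) {
      starts <- c(starts, near[which.min(abs(near - g))])
      flags <- c(flags, "grid_snap")
    } else {
      starts <- c(starts, g)
      flags <- c(flags, "periodic_fallback")
    }
  }
  ends <- c(starts[-1L], array_span[2])
  repeat_array_obj(as.integer(starts), as.integer(ends), flags)
}

#' @noRd
repeat_array_obj <- function(starts, ends, flags) {
  if (!length(starts)) stop("no units could be delimited")
  units <- data.frame(index = seq_along(starts), start = starts, end = ends,
                      flag = flags, stringsAsFactors = FALSE)
  structure(list(span = c(min(starts), max(ends)), units = units),
            class = "repeat_array")
}

#' @export
print.repeat_array <- function(x, ...) {
  cat(sprintf("Repeat array: %d units over [%d, %d)\n",
              nrow(x$units), x$span[1], x$span[2]))
  print(x$units)
  invisible(x)
}

#' Extract and name the units of a delimited array
#'
#' Units are named `<species_code>-<index>` in 5.8S-to-28S order and carry
#' the exact substring of the record.
#'
#' @param record A [spacer_record()] (or a single named sequence).
#' @param array A `repeat_array` from [delimit_units()].
#' @return A `repeat_units` data.frame: `parent_id`, `index`, `start`,
#'   `end` (0-based half-open), `name`, `sequence`, `flag`.
#' @export
extract_units <- function(record, array) {
  if (!inherits(record, "spacer_record")) {
    id <- names(record) %||% "seq"
    record <- spacer_record(id[1], record[[1]])
  }
  u <- array$units
  out <- data.frame(
    parent_id = record$id,
    index = u$index,
    start = u$start,
    end = u$end,
    name = paste0(record$species_code, "-", u$index),
    sequence = substring(record$sequence, u$start + 1L, u$end),
    flag = u$flag,
    stringsAsFactors = FALSE)
  structure(out, class = c("repeat_units", "data.frame"))
}

#' Inverted (reverse-complement) content of a repeat unit
#'
#' Scans a sequence against its own reverse complement and reports every
#' maximal self-complementary stem of length >= `min_stem` -- segment pairs
#' that could base-pair into hairpin secondary structure.  The score is the
#' fraction of positions covered by at least one stem arm.
#'
#' @param unit_sequence Nucleotide string.
#' @param min_stem Minimum stem (arm) length, >= 4.
#' @return An `inverted_report`: list with `stems` (data.frame of 0-based
#'   half-open arm intervals and lengths) and `score`.
#' @export
inverted_content <- function(unit_sequence, min_stem = 4L) {
  if (min_stem < 4L) stop("min_stem must be >= 4")
  chars <- seq_to_chars(toupper(unit_sequence))
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  cc <- unname(comp[chars])
  stems <- list()
  for (P in 3:(2L * n - 1L)) {          # pair sum (1-based positions)
    xs <- seq.int(max(1L, P - n), floor((P - 1) / 2))
    if (!length(xs)) next
    ok <- chars[xs] == cc[P - xs]
    ok[is.na(ok)] <- FALSE
    if (!any(ok)) next
    r <- rle(ok)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_stem)) {
      x1 <- xs[starts[k]]; x2 <- xs[ends[k]]
      stems[[length(stems) + 1L]] <- data.frame(
        left_start = x1 - 1L, left_end = x2,
        right_start = P - x2 - 1L, right_end = P - x1,
        length = x2 - x1 + 1L)
    }
  }
  stems <- if (length(stems)) do.call(rbind, stems) else
    data.frame(left_start = integer(0), left_end = integer(0),
               right_start = integer(0), right_end = integer(0),
               length = integer(0))
  covered <- logical(n)
  for (k in seq_len(nrow(stems))) {
    covered[(stems$left_start[k] + 1L):stems$left_end[k]] <- TRUE
    covered[(stems$right_start[k] + 1L):stems$right_end[k]] <- TRUE
  }
  structure(list(stems = stems, score = sum(covered) / n),
            class = "inverted_report")
}

#' @export
print.inverted_report <- function(x, ...) {
  cat(sprintf("Inverted content: %d stem(s), %.0f%% of positions in stems\n",
              nrow(x$stems), 100 * x$score))
  invisible(x)
}
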
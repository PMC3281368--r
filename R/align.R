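## Progressive multiple alignment: pairwise global affine-gap alignments
## feed an NJ guide tree; profiles are merged postorder with a
## profile-profile dynamic program (src/align.cpp).

#' Align repeat units into a multiple alignment
#'
#' Progressive sequence alignment over a neighbor-joining guide tree built
#' from pairwise global-alignment identities.  Scoring is plain
#' match/mismatch with affine gaps; the result is deterministic for fixed
#' inputs and parameters.
#'
#' @param units Sequences to align: a named character vector, a
#'   `repeat_units` table from [extract_units()], or a list with `name` and
#'   `sequence` fields.
#' @param match,mismatch Per-column substitution scores (defaults 2, -1).
#' @param gap_open,gap_extend Affine gap costs; `gap_open` is charged once
#'   per gap in addition to `gap_extend` per gapped position (defaults -5, -2).
#' @return A `unit_alignment`: list with `labels`, `rows` (named gapped
#'   strings, all the same length) and the scoring `params`.  Degapping a
#'   row reproduces the input sequence exactly.
#' @export
align_units <- function(units, match = 2, mismatch = -1,
                        gap_open = -5, gap_extend = -2) {
  seqs <- as_named_sequences(units)
  if (length(seqs) < 2L) stop("need at least 2 sequences to align")
  if (anyDuplicated(names(seqs))) stop("duplicate sequence names")
  params <- list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend)
  n <- length(seqs)
  rows_chars <- lapply(seqs, function(s) seq_to_chars(toupper(s)))

  if (n == 2L) {
    merged <- merge_blocks(rows_chars[1], rows_chars[2], params)
  } else {
    d <- guide_distances(rows_chars, params)
    dimnames(d) <- list(names(seqs), names(seqs))
    guide <- ape::nj(stats::as.dist(d))
    merged <- align_by_guide(guide, rows_chars, names(seqs), params)
  }
  rows <- vapply(merged, chars_to_seq, character(1))
  rows <- rows[names(seqs)]
  structure(list(labels = names(seqs), rows = rows, params = params),
            class = "unit_alignment")
}

#' @export
print.unit_alignment <- function(x, ...) {
  cat("Multiple alignment: ", length(x$labels), " sequences, ",
      nchar(x$rows[[1]]), " columns\n", sep = "")
  if (!is.null(x$removed_columns))
    cat("Gap-containing columns removed:", x$removed_columns, "\n")
  invisible(x)
}

#' @noRd
as_named_sequences <- function(units) {
  if (is.data.frame(units)) {
    stats::setNames(as.character(units$sequence), units$name)
  } else if (is.list(units) && !is.null(units[[1]]$sequence)) {
    stats::setNames(vapply(units, `[[`, character(1), "sequence"),
                    vapply(units, `[[`, character(1), "name"))
  } else if (is.character(units)) {
    if (is.null(names(units))) names(units) <- paste0("seq", seq_along(units))
    units
  } else stop("unsupported sequence container")
}

## 4 x ncol frequency profile of a block of aligned rows (gap weight 0)
#' @noRd
block_profile <- function(block) {
  L <- length(block[[1]])
  prof <- matrix(0, 4L, L)
  for (r in block) {
    idx <- match(r, BASES)
    ok <- !is.na(idx)
    cols <- which(ok)
    prof[cbind(idx[ok], cols)] <- prof[cbind(idx[ok], cols)] + 1
  }
  prof / length(block)
}

## Merge two blocks of gapped character vectors via the profile DP.
#' @noRd
merge_blocks <- function(a, b, params) {
  pa <- block_profile(a)
  pb <- block_profile(b)
  M <- matrix(params$mismatch, 4L, 4L)
  diag(M) <- params$match
  S <- t(pa) %*% M %*% pb
  res <- affine_dp_cpp(S, params$gap_open, params$gap_extend)
  path <- res$path
  na <- ncol(pa)
  out <- vector("list", length(a) + length(b))
  names(out) <- c(names(a), names(b))
  gap_into <- function(row, idx) {
    new <- rep("-", nrow(path))
    new[idx > 0L] <- row[idx[idx > 0L]]
    new
  }
  for (i in seq_along(a)) out[[i]] <- gap_into(a[[i]], path[, 1])
  for (i in seq_along(b)) out[[length(a) + i]] <- gap_into(b[[i]], path[, 2])
  out
}

## Pairwise guide distances: 1 - identity of the global pairwise alignment.
#' @noRd
guide_distances <- function(rows_chars, params) {
  n <- length(rows_chars)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      al <- merge_blocks(rows_chars[i], rows_chars[j], params)
      x <- al[[1]]; y <- al[[2]]
      ident <- sum(x == y & x != "-") / length(x)
      d[i, j] <- d[j, i] <- 1 - ident
    }
  }
  d
}

## Postorder merge following the (unrooted) guide tree, treating ape's
## internal root node as the top.  Children are visited in order of their
## smallest descendant input index, so the result is order-independent.
#' @noRd
align_by_guide <- function(guide, rows_chars, labels, params) {
  ntip <- length(guide$tip.label)
  tip_index <- match(guide$tip.label, labels)
  kids <- split(guide$edge[, 2], guide$edge[, 1])
  rec <- function(node) {
    if (node <= ntip) {
      blk <- rows_chars[tip_index[node]]
      names(blk) <- labels[tip_index[node]]
      return(blk)
    }
    ch <- kids[[as.character(node)]]
    sub <- lapply(ch, rec)
    ord <- order(vapply(sub, function(b) min(match(names(b), labels)), 1L))
    sub <- sub[ord]
    blk <- sub[[1]]
    for (k in seq_along(sub)[-1]) blk <- merge_blocks(blk, sub[[k]], params)
    blk
  }
  rec(ntip + 1L)
}

#' Align masked spacers and optionally drop gap-containing columns
#'
#' Runs the same progressive alignment engine as [align_units()] on
#' repeat-masked spacer sequences, then (by default) removes every column
#' in which any sequence has a gap, emulating complete exclusion of gapped
#' positions before distance estimation.
#'
#' @param masked_records Named character vector of sequences, a list of
#'   `masked_spacer` objects from [mask_repeats()], or a `repeat_units`-style
#'   table.
#' @param exclude_gap_columns Remove all columns containing a gap (default
#'   TRUE).  The number of removed columns is recorded in the result.
#' @inheritParams align_units
#' @return A `unit_alignment` with an extra `removed_columns` count.
#' @export
align_and_filter <- function(masked_records, exclude_gap_columns = TRUE,
                             match = 2, mismatch = -1,
                             gap_open = -5, gap_extend = -2) {
  if (is.list(masked_records) && inherits(masked_records[[1]], "masked_spacer"))
    masked_records <- stats::setNames(
      vapply(masked_records, `[[`, character(1), "sequence"),
      vapply(masked_records, `[[`, character(1), "id"))
  aln <- align_units(masked_records, match, mismatch, gap_open, gap_extend)
  removed <- 0L
  if (exclude_gap_columns) {
    mat <- do.call(rbind, lapply(aln$rows, seq_to_chars))
    gap_col <- apply(mat == "-", 2L, any)
    removed <- sum(gap_col)
    if (all(gap_col)) stop("all alignment columns contain gaps")
    kept <- mat[, !gap_col, drop = FALSE]
    aln$rows <- stats::setNames(apply(kept, 1L, chars_to_seq), aln$labels)
  }
  aln$removed_columns <- removed
  aln
}
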
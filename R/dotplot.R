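## Repeat detection by self-comparison: word-seeded diagonal scanning with
## greedy merging across mismatches, verified post hoc against a minimum
## identity, emulating dot-plot inspection with an explicit >30 bp floor.

#' Detect repeats in a sequence by dot-plot self-comparison
#'
#' Finds all maximal matching diagonal runs between a sequence and itself.
#' Exact runs are seeded by shared words of length `word_size` and read off
#' the full diagonal, so every maximal exact run of length >=
#' `min_match_length` is reported exactly once.  Runs on the same diagonal
#' separated by small mismatching stretches (<= `max_merge_gap` positions)
#' are greedily merged while the merged run keeps identity >=
#' `min_identity`, which lets decayed repeat copies surface.  The trivial
#' self-diagonal (offset 0) is excluded.
#'
#' @param sequence Nucleotide string.
#' @param word_size Seed word length (default 11, must be >= 4).
#' @param min_match_length Minimum reported run length (default 30, the
#'   detection floor for long spacer repeats; must be >= `word_size`).
#' @param min_identity Minimum identity of any reported (merged) run
#'   (default 0.7).
#' @param max_merge_gap Largest mismatching stretch bridged when merging
#'   runs on one diagonal (default 15; set 0 for exact-only detection).
#' @return A `dotplot_matches` data.frame with columns `offset` (difference
#'   between the two matching start positions), `start` (0-based position of
#'   the left copy), `length`, and `identity`.
#' @export
self_dotplot <- function(sequence, word_size = 11L, min_match_length = 30L,
                         min_identity = 0.7, max_merge_gap = 15L) {
  if (!nzchar(sequence)) stop("empty sequence")
  if (word_size < 4L) stop("word_size must be >= 4")
  if (min_match_length < word_size)
    stop("min_match_length must be >= word_size")
  chars <- seq_to_chars(toupper(sequence))
  diags <- seeded_diagonals(chars, chars, word_size, self = TRUE)
  res <- scan_diagonals(chars, chars, diags, word_size, min_match_length,
                        min_identity, max_merge_gap)
  out <- data.frame(offset = res$diag, start = res$start,
                    length = res$length, identity = res$identity)
  out <- out[order(out$offset, out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("dotplot_matches", "data.frame"),
            params = list(word_size = word_size,
                          min_match_length = min_match_length,
                          min_identity = min_identity,
                          max_merge_gap = max_merge_gap))
}

## Cross-sequence variant used for rescue of records whose repeats are too
## decayed for self-comparison: matches of `query` against `subject`.
#' @noRd
cross_dotplot <- function(query, subject, word_size = 11L,
                          min_match_length = 30L, min_identity = 0.7,
                          max_merge_gap = 15L) {
  a <- seq_to_chars(toupper(query))
  b <- seq_to_chars(toupper(subject))
  diags <- seeded_diagonals(a, b, word_size, self = FALSE)
  res <- scan_diagonals(a, b, diags, word_size, min_match_length,
                        min_identity, max_merge_gap)
  data.frame(diag = res$diag, start_query = res$start,
             start_subject = res$start + res$diag,
             length = res$length, identity = res$identity)
}

## Diagonals (offset = pos_b - pos_a) holding at least one shared word.
#' @noRd
seeded_diagonals <- function(a, b, w, self) {
  na <- length(a); nb <- length(b)
  if (na < w || nb < w) return(integer(0))
  worda <- substring(chars_to_seq(a), seq_len(na - w + 1L), seq.int(w, na))
  wordb <- if (self) worda else
    substring(chars_to_seq(b), seq_len(nb - w + 1L), seq.int(w, nb))
  ga <- split(seq_along(worda), worda)
  gb <- if (self) ga else split(seq_along(wordb), wordb)
  shared <- intersect(names(ga), names(gb))
  ds <- integer(0)
  for (word in shared) {
    ia <- ga[[word]]; ib <- gb[[word]]
    if (self && length(ia) < 2L) next
    d <- unique(as.vector(outer(ib, ia, `-`)))
    ds <- c(ds, d)
  }
  ds <- unique(ds)
  if (self) ds <- ds[ds > 0L]
  sort(ds)
}

## For each seeded diagonal, read the full match/mismatch vector, take
## maximal exact runs >= w, then greedily merge across gaps.
#' @noRd
scan_diagonals <- function(a, b, diags, w, min_len, min_ident, max_gap) {
  out <- list(diag = integer(0), start = integer(0),
              length = integer(0), identity = numeric(0))
  na <- length(a); nb <- length(b)
  for (d in diags) {
    ia <- max(1L, 1L - d); ib <- ia + d
    len <- min(na - ia, nb - ib) + 1L
    if (len < w) next
    cmp <- a[seq.int(ia, ia + len - 1L)] == b[seq.int(ib, ib + len - 1L)]
    r <- rle(cmp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= w
    if (!any(keep)) next
    segs <- cbind(start = starts[keep], end = ends[keep])
    merged <- merge_segments(segs, cmp, max_gap, min_ident)
    for (k in seq_len(nrow(merged))) {
      s <- merged[k, 1L]; e <- merged[k, 2L]
      L <- e - s + 1L
      if (L < min_len) next
      ident <- sum(cmp[s:e]) / L
      if (ident < min_ident) next
      out$diag <- c(out$diag, d)
      out$start <- c(out$start, ia + s - 2L)      # 0-based
      out$length <- c(out$length, L)
      out$identity <- c(out$identity, ident)
    }
  }
  out
}

## Greedy left-to-right chaining of exact segments on one diagonal.
#' @noRd
merge_segments <- function(segs, cmp, max_gap, min_ident) {
  if (nrow(segs) == 1L || max_gap <= 0L) return(segs)
  out <- matrix(integer(0), 0L, 2L)
  cur <- segs[1L, ]
  for (k in 2L:nrow(segs)) {
    nxt <- segs[k, ]
    gap <- nxt[1L] - cur[2L] - 1L
    cand_ident <- sum(cmp[cur[1L]:nxt[2L]]) / (nxt[2L] - cur[1L] + 1L)
    if (gap <= max_gap && cand_ident >= min_ident) {
      cur[2L] <- nxt[2L]
    } else {
      out <- rbind(out, cur)
      cur <- nxt
    }
  }
  rbind(out, cur)
}

#' Infer a tandem array from dot-plot matches
#'
#' Groups match evidence into overlapping regions, keeps the densest one,
#' and estimates the repeat period as the modal pairwise difference among
#' the region's diagonal offsets (offsets within 5 nt are pooled).  A match
#' at offset `d` and length `L` starting at `s` evidences repeated sequence
#' over `[s, s + d + L)`.  Dispersed (non-tandem) duplications yield a
#' "no array" result: the evidence span must hold at least ~2 periods.
#'
#' @param matches A `dotplot_matches` data.frame from [self_dotplot()].
#' @param sequence The scanned sequence (used only for bounds checking).
#' @return An `array_candidate`: list with `found` (logical), `span`
#'   (0-based half-open), `period`, `offsets`, `n_matches`.
#' @export
infer_array <- function(matches, sequence) {
  if (nrow(matches) == 0L) stop("non-empty match list required")
  n <- nchar(sequence)
  iv_start <- matches$start
  iv_end <- matches$start + matches$offset + matches$length
  ord <- order(iv_start)
  regions <- integer(nrow(matches))
  reg <- 0L; reg_end <- -1L
  for (k in ord) {
    if (iv_start[k] > reg_end) { reg <- reg + 1L; reg_end <- iv_end[k] }
    else reg_end <- max(reg_end, iv_end[k])
    regions[k] <- reg
  }
  dens <- tapply(matches$length, regions, sum)
  best <- as.integer(names(dens)[which.max(dens)])
  sel <- regions == best
  span <- c(min(iv_start[sel]), min(max(iv_end[sel]), n))
  offs <- matches$offset[sel]
  period <- modal_offset_difference(offs, tol = 5L)
  found <- !is.na(period) && (span[2] - span[1]) >= 1.6 * min(offs)
  structure(list(found = found, span = span,
                 period = if (found) period else NA_integer_,
                 offsets = sort(unique(offs)), n_matches = sum(sel)),
            class = "array_candidate")
}

## Modal pairwise difference among offsets, pooling values within `tol`.
#' @noRd
modal_offset_difference <- function(offsets, tol = 5L) {
  reps <- cluster_reps(sort(unique(offsets)), tol)
  if (length(reps) == 1L) return(as.integer(reps))
  diffs <- as.vector(outer(reps, reps, `-`))
  diffs <- diffs[diffs > 0]
  dreps <- cluster_reps(sort(diffs), tol)
  counts <- vapply(dreps, function(r) sum(abs(diffs - r) <= tol), 1L)
  as.integer(dreps[which.max(counts)])
}

## collapse sorted values into cluster medians (gap > tol starts a cluster)
#' @noRd
cluster_reps <- function(x, tol) {
  if (!length(x)) return(numeric(0))
  grp <- cumsum(c(TRUE, diff(x) > tol))
  as.numeric(tapply(x, grp, stats::median))
}

#' @export
print.array_candidate <- function(x, ...) {
  if (!x$found) cat("No tandem array detected\n")
  else cat(sprintf("Tandem array candidate: span [%d, %d), period ~%d nt, %d matches\n",
                   x$span[1], x$span[2], x$period, x$n_matches))
  invisible(x)
}
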
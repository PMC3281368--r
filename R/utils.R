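## Internal helpers shared across pipeline stages.

BASES <- c("A", "C", "G", "T")

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- c(names(IUPAC_EXPAND), "-")

#' @noRd
seq_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' @noRd
chars_to_seq <- function(x) paste(x, collapse = "")

## A, C, G, T -> 1..4; anything else (gap, ambiguity) -> 0
#' @noRd
seq_to_int <- function(x) {
  m <- match(seq_to_chars(x), BASES)
  m[is.na(m)] <- 0L
  as.integer(m)
}

#' @noRd
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")
  chars_to_seq(rev(unname(comp[seq_to_chars(x)])))
}

## All concrete ACGT strings matching an IUPAC motif
#' @noRd
iupac_expansions <- function(motif) {
  sets <- lapply(seq_to_chars(toupper(motif)), function(ch) {
    s <- IUPAC_EXPAND[[ch]]
    if (is.null(s)) stop("invalid IUPAC letter in motif: ", ch)
    s
  })
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  apply(grid[, rev(seq_along(sets)), drop = FALSE], 1L, paste, collapse = "")
}

## 0-based start positions where the IUPAC motif matches `sequence`
#' @noRd
motif_hits <- function(sequence, motif) {
  n <- nchar(sequence)
  k <- nchar(motif)
  if (k == 0L || n < k) return(integer(0))
  chars <- seq_to_chars(toupper(sequence))
  ok <- rep(TRUE, n - k + 1L)
  mchars <- seq_to_chars(toupper(motif))
  for (i in seq_len(k)) {
    allowed <- IUPAC_EXPAND[[mchars[i]]]
    ok <- ok & chars[seq.int(i, i + n - k)] %in% allowed
  }
  which(ok) - 1L
}

## Deterministic per-stage seed derived from the top-level seed, so stages
## draw from isolated substreams.  Kept below 2^31 - 1.
#' @noRd
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) %% 65011 + 1) * 32749 + h) %% 2147483629L
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @noRd
random_dna <- function(n) chars_to_seq(sample(BASES, n, replace = TRUE))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
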
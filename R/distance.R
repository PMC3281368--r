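#' Jukes-Cantor distance between two aligned rows
#'
#' Estimates the number of substitutions per site between two equal-length
#' gapped sequences under the Jukes-Cantor model,
#' \eqn{d = -\frac{3}{4}\log(1 - \frac{4p}{3})}, where \eqn{p} is the
#' proportion of differing sites among the valid ones.  With pairwise
#' deletion (the default and only policy), a site is valid for a pair when
#' neither row carries a gap there; ambiguity codes are treated as gaps,
#' which is the conservative reading of pairwise deletion.
#'
#' @param row_a,row_b Equal-length gapped nucleotide strings (gap `"-"`).
#' @param pairwise_deletion Logical; kept for interface clarity, must be TRUE.
#' @return The JC distance (substitutions/site), a non-negative number.
#'   Errors with class `"jc_no_sites_error"` when no site is valid for the
#'   pair, and `"jc_saturation_error"` when the observed proportion of
#'   differences reaches 3/4, where the JC estimator is undefined.
#' @examples
#' jc_distance("ACGTACGT", "ACGTACGT")    # 0
#' # 10 differences over 100 valid sites -> 0.1073
#' a <- strrep("A", 100)
#' b <- paste0(strrep("C", 10), strrep("A", 90))
#' jc_distance(a, b)
#' @export
jc_distance <- function(row_a, row_b, pairwise_deletion = TRUE) {
  if (!isTRUE(pairwise_deletion))
    stop("only pairwise deletion of gaps is implemented")
  if (nchar(row_a) != nchar(row_b))
    stop("rows must be equal length (", nchar(row_a), " vs ", nchar(row_b), ")")
  a <- seq_to_int(toupper(row_a))
  b <- seq_to_int(toupper(row_b))
  valid <- a > 0L & b > 0L
  n <- sum(valid)
  if (n == 0L)
    stop(errorCondition("no valid sites shared by the two rows",
                        class = c("jc_no_sites_error", "error", "condition")))
  p <- sum(a[valid] != b[valid]) / n
  jc_from_p(p)
}

## p -> d, with the saturation condition signalled as its own class
#' @noRd
jc_from_p <- function(p) {
  if (p >= 0.75)
    stop(errorCondition(
      sprintf("proportion of differences %.3f >= 0.75: JC distance undefined (saturation)", p),
      class = c("jc_saturation_error", "error", "condition")))
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix for a multiple alignment
#'
#' Computes all pairwise JC distances with pairwise deletion of gaps
#' (ambiguity codes excluded as gaps).  This is the single distance engine
#' used for repeat-unit grouping and for the species trees.
#'
#' @param alignment A `unit_alignment` (see [align_units()]), a named
#'   character vector of equal-length gapped sequences, or a character
#'   matrix (rows = sequences, one character per cell).
#' @param saturation One of `"error"` (default: any saturated pair aborts,
#'   signalled as `"jc_saturation_error"`), `"na"` (saturated pairs become
#'   `NA`), or `"cap"` (saturated pairs are set to twice the largest
#'   finite distance in the matrix, so downstream tree building stays
#'   defined; the JC estimate itself is undefined there).
#' @return A symmetric matrix with zero diagonal, dimnames set to the
#'   sequence labels, and attributes `model = "JC"`,
#'   `deletion = "pairwise"`.
#' @export
jc_dist_matrix <- function(alignment, saturation = c("error", "na", "cap")) {
  saturation <- match.arg(saturation)
  m <- alignment_int_matrix(alignment)
  cnt <- jc_pair_counts_cpp(m)
  n <- nrow(m)
  p <- matrix(0, n, n)
  valid <- cnt$valid
  if (any(valid[upper.tri(valid)] == 0L))
    stop(errorCondition("some sequence pair shares no valid sites",
                        class = c("jc_no_sites_error", "error", "condition")))
  p[] <- cnt$diff / pmax(valid, 1L)
  sat <- p >= 0.75
  diag(sat) <- FALSE
  if (any(sat)) {
    if (saturation == "error")
      stop(errorCondition("saturated pair(s): proportion of differences >= 0.75",
                          class = c("jc_saturation_error", "error", "condition")))
  }
  d <- -0.75 * log(pmax(1 - 4 * p / 3, .Machine$double.eps))
  d[sat] <- NA_real_
  diag(d) <- 0
  if (saturation == "cap" && any(sat)) {
    finite <- d[!sat & upper.tri(d)]
    d[sat] <- max(2 * max(finite, 0), 3)
    attr(d, "capped_pairs") <- sum(sat) / 2L
  }
  dimnames(d) <- list(alignment_labels(alignment), alignment_labels(alignment))
  attr(d, "model") <- "JC"
  attr(d, "deletion") <- "pairwise"
  d
}

## Accept the three alignment representations used in the package and
## return an integer matrix (A,C,G,T = 1..4; gap/ambiguity = 0).
#' @noRd
alignment_int_matrix <- function(alignment) {
  if (inherits(alignment, "unit_alignment")) alignment <- alignment$rows
  if (is.matrix(alignment) && is.character(alignment)) {
    m <- match(toupper(alignment), BASES)
    m[is.na(m)] <- 0L
    return(matrix(as.integer(m), nrow(alignment), ncol(alignment)))
  }
  if (is.character(alignment)) {
    lens <- nchar(alignment)
    if (length(unique(lens)) != 1L) stop("alignment rows differ in length")
    return(do.call(rbind, lapply(toupper(alignment), seq_to_int)))
  }
  stop("unsupported alignment representation")
}

#' @noRd
alignment_labels <- function(alignment) {
  if (inherits(alignment, "unit_alignment")) return(alignment$labels)
  if (is.matrix(alignment)) return(rownames(alignment) %||% as.character(seq_len(nrow(alignment))))
  names(alignment) %||% as.character(seq_along(alignment))
}
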
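## Neighbor-joining trees, bootstrap support, and bipartition utilities.
## ape provides the NJ agglomeration and the phylo container; this layer
## adds negative-branch clamping, seeded column-resampling bootstrap, and
## Robinson-Foulds style tree comparison.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via [ape::nj()]) with one post-processing
#' step: negative branch lengths are clamped to zero and the deficit is
#' moved to the sister branch, preserving the path length between the two
#' children.
#'
#' @param dmatrix Symmetric labelled distance matrix (or `dist`).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dmatrix) {
  if (inherits(dmatrix, "dist")) dmatrix <- as.matrix(dmatrix)
  if (nrow(dmatrix) < 3L) stop("need at least 3 labels for NJ")
  if (any(is.na(dmatrix))) stop("distance matrix contains NA")
  tr <- ape::nj(stats::as.dist(dmatrix))
  clamp_negative_branches(tr)
}

#' @noRd
clamp_negative_branches <- function(tr) {
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1L]
    sibs <- setdiff(which(tr$edge[, 1L] == parent), e)
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    if (length(sibs))
      tr$edge.length[sibs[1L]] <- max(0, tr$edge.length[sibs[1L]] + deficit)
  }
  tr
}

## Non-trivial bipartitions of an (un)rooted phylo as canonical keys.
## Each bipartition is represented by the side NOT containing the
## alphabetically first label, sorted and collapsed.
#' @noRd
tree_bipartitions <- function(tr) {
  labs <- tr$tip.label
  n <- length(labs)
  if (n < 4L) return(character(0))
  ref <- sort(labs)[1L]
  parts <- ape::prop.part(tr)
  keys <- character(0)
  for (p in parts) {
    side <- labs[p]
    if (ref %in% side) side <- setdiff(labs, side)
    if (length(side) < 2L || length(side) > n - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  unique(keys)
}

#' Bootstrap support for an NJ tree of an alignment
#'
#' Columns are resampled with replacement `n_replicates` times; a JC + NJ
#' tree is built per replicate and the support of each bipartition of the
#' original tree is the percentage of replicates containing it.  Saturated
#' or degenerate replicates (no valid sites for some pair) are dropped with
#' the divisor unchanged, so support stays conservative.  Fully seeded:
#' the same seed and inputs give identical supports.
#'
#' @param alignment A `unit_alignment` (or named character vector of
#'   equal-length gapped rows).
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed.
#' @return A `supported_tree`: list with `tree` (the original NJ `phylo`
#'   with node labels set to integer support percentages) and `splits`
#'   (data.frame of bipartition keys and supports).
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L) {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  m <- alignment_int_matrix(alignment)
  labs <- alignment_labels(alignment)
  rownames(m) <- labs
  if (ncol(m) < 2L) stop("alignment must have at least 2 columns")
  d0 <- jc_dist_matrix(alignment, saturation = "cap")
  tr <- nj_tree(d0)
  keys <- tree_bipartitions(tr)
  counts <- stats::setNames(numeric(length(keys)), keys)
  with_seed(stage_seed(seed, "bootstrap"), {
    for (r in seq_len(n_replicates)) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      rep_keys <- tryCatch({
        dr <- jc_matrix_int(m[, cols, drop = FALSE])
        tree_bipartitions(ape::nj(stats::as.dist(dr)))
      }, error = function(e) NULL)
      if (is.null(rep_keys)) next
      hit <- keys %in% rep_keys
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- round(100 * counts / n_replicates)
  tr <- attach_node_support(tr, support)
  structure(list(tree = tr,
                 splits = data.frame(key = keys, support = unname(support),
                                     stringsAsFactors = FALSE),
                 n_replicates = n_replicates, seed = seed),
            class = "supported_tree")
}

## JC matrix straight from an integer matrix (bootstrap fast path);
## same conventions as jc_dist_matrix with saturation = "cap".
#' @noRd
jc_matrix_int <- function(m) {
  cnt <- jc_pair_counts_cpp(m)
  if (any(cnt$valid[upper.tri(cnt$valid)] == 0L)) stop("pair with no valid sites")
  p <- cnt$diff / pmax(cnt$valid, 1L)
  sat <- p >= 0.75
  diag(sat) <- FALSE
  d <- -0.75 * log(pmax(1 - 4 * p / 3, .Machine$double.eps))
  diag(d) <- 0
  if (any(sat)) {
    finite <- d[!sat & upper.tri(d)]
    d[sat] <- max(2 * max(finite, 0), 3)
  }
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

## write per-bipartition support into the node labels of the tree
#' @noRd
attach_node_support <- function(tr, support) {
  labs <- tr$tip.label
  ref <- sort(labs)[1L]
  parts <- ape::prop.part(tr)
  node_lab <- rep("", tr$Nnode)
  for (i in seq_along(parts)) {
    side <- labs[parts[[i]]]
    if (ref %in% side) side <- setdiff(labs, side)
    key <- paste(sort(side), collapse = "\r")
    if (key %in% names(support)) node_lab[i] <- as.character(support[[key]])
  }
  tr$node.label <- node_lab
  tr
}

#' @export
print.supported_tree <- function(x, ...) {
  cat("NJ tree with bootstrap support (", x$n_replicates, " replicates)\n",
      sep = "")
  print(x$tree)
  invisible(x)
}

#' Species tree from a (filtered) alignment
#'
#' JC distances with pairwise deletion, NJ, and column-resampling
#' bootstrap; unrooted unless outgroup labels are supplied, in which case
#' the tree is rooted on their branch.
#'
#' @param alignment A `unit_alignment`, e.g. from [align_and_filter()].
#' @param bootstrap_n Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @param outgroup Optional character vector of tip labels to root on.
#' @return A `supported_tree`; its `tree` element is rooted iff an
#'   outgroup was given.
#' @export
species_tree <- function(alignment, bootstrap_n = 1000L, seed = 1L,
                         outgroup = NULL) {
  labs <- alignment_labels(alignment)
  if (length(labs) < 3L) stop("need at least 3 sequences")
  if (!is.null(outgroup) && !all(outgroup %in% labs))
    stop("outgroup name(s) absent from alignment: ",
         paste(setdiff(outgroup, labs), collapse = ", "))
  st <- bootstrap_support(alignment, bootstrap_n, seed)
  if (!is.null(outgroup))
    st$tree <- ape::root(st$tree, outgroup = outgroup, resolve.root = TRUE)
  st$rooted <- !is.null(outgroup)
  st
}

#' Compare two trees by their bipartitions
#'
#' Robinson-Foulds style comparison: the symmetric-difference count of
#' non-trivial bipartitions, plus the lists of bipartitions unique to each
#' tree.  Both trees must share the same leaf set.
#'
#' @param tree_a,tree_b `phylo` trees (or `supported_tree`s).
#' @return A `tree_comparison`: list with `rf_distance`, `shared` count,
#'   and `conflicts_a`, `conflicts_b` (lists of label sets).
#' @export
compare_trees <- function(tree_a, tree_b) {
  if (inherits(tree_a, "supported_tree")) tree_a <- tree_a$tree
  if (inherits(tree_b, "supported_tree")) tree_b <- tree_b$tree
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("trees have different leaf sets")
  ka <- tree_bipartitions(tree_a)
  kb <- tree_bipartitions(tree_b)
  ua <- setdiff(ka, kb); ub <- setdiff(kb, ka)
  structure(list(rf_distance = length(ua) + length(ub),
                 shared = length(intersect(ka, kb)),
                 conflicts_a = lapply(ua, function(k) strsplit(k, "\r")[[1]]),
                 conflicts_b = lapply(ub, function(k) strsplit(k, "\r")[[1]])),
            class = "tree_comparison")
}

#' @export
print.tree_comparison <- function(x, ...) {
  cat("Bipartition comparison: RF distance", x$rf_distance,
      "(", x$shared, "shared )\n")
  invisible(x)
}
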
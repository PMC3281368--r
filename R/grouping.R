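## Repeat-unit grouping: single-linkage components of the sub-threshold
## distance graph, with two bootstrap-support overrides mirroring the
## judgement calls the threshold rule alone cannot make: a strongly
## supported clade can pull a distant unit into a group (merge), and a
## strongly supported pair of clades can cut a sub-threshold link (split).

#' Cluster repeat units into groups at a distance threshold
#'
#' Base rule: two units belong to the same group when they are connected by
#' a chain of pairwise distances strictly below `threshold` (single
#' linkage).  With a supported tree, two overrides apply, each logged:
#' *split* -- sub-threshold links are cut either when a component is
#' exactly the union of two disjoint clades each supported at
#' `support_override` or more, or when a unit whose median distance to
#' the rest of its component reaches the threshold (it hangs on a single
#' noisy link) is contradicted by supported bipartitions on every one of
#' its links; *merge* --
#' a unit outside any multi-member group joins a group when a supported
#' clade contains it together with members of exactly that group and the
#' unit sits within `merge_distance_factor * threshold` of the group (the
#' override exists to rescue borderline, just-over-threshold units, not to
#' group arbitrarily distant sequences).  Components of size 1 after
#' overrides are reported as ungrouped.
#'
#' @param dmatrix Symmetric labelled distance matrix (e.g. from
#'   [jc_dist_matrix()]).
#' @param threshold Distance below which units are linked (default 0.1).
#' @param tree_with_support Optional `supported_tree` from
#'   [bootstrap_support()]; NULL disables both overrides.
#' @param support_override Minimum bootstrap percentage for an override
#'   (default 70).
#' @param merge_distance_factor Multiple of `threshold` within which the
#'   merge override may act (default 1.5).
#' @return A `group_assignment`: list with `assignment` (data.frame of
#'   `unit`, `group` -- integer id or NA for ungrouped), `threshold`,
#'   `support_override` and `overrides` (data.frame log).
#' @export
cluster_groups <- function(dmatrix, threshold = 0.1,
                           tree_with_support = NULL,
                           support_override = 70,
                           merge_distance_factor = 1.5) {
  if (inherits(dmatrix, "dist")) dmatrix <- as.matrix(dmatrix)
  if (threshold <= 0) stop("threshold must be > 0")
  labs <- rownames(dmatrix)
  if (is.null(labs)) stop("distance matrix must be labelled")
  adj <- dmatrix < threshold
  diag(adj) <- FALSE
  log <- list()

  supported <- list()   # one canonical side per supported bipartition
  sided <- list()       # both orientations, for the merge override
  if (!is.null(tree_with_support)) {
    sp <- tree_with_support$splits
    keep <- sp$support >= support_override
    all_labs <- tree_with_support$tree$tip.label
    for (k in which(keep)) {
      side <- strsplit(sp$key[k], "\r")[[1]]
      supported[[length(supported) + 1L]] <-
        list(side = side, support = sp$support[k])
      sided[[length(sided) + 1L]] <- list(side = side, support = sp$support[k])
      sided[[length(sided) + 1L]] <- list(side = setdiff(all_labs, side),
                                          support = sp$support[k])
    }
  }

  ## split override: a sub-threshold link is cut when its two endpoints
  ## lie in disjoint *group-like* clades -- supported at the override
  ## level and distance-tight (median internal distance < threshold), so
  ## each side could itself be a group.  A lone unit counts as a
  ## degenerate clade only when its median distance to the rest of its
  ## component reaches the threshold (it hangs on a single noisy link,
  ## the known weakness of single linkage).  Requiring BOTH sides to be
  ## group-like blocks cuts driven by chance sister pairs inside genuine
  ## groups, whose complements are never group-like.
  if (length(sided)) {
    tight <- Filter(function(cl) {
      s <- cl$side
      length(s) >= 2L &&
        stats::median(dmatrix[s, s][upper.tri(diag(length(s)))]) < threshold
    }, sided)
    changed <- TRUE
    iter <- 0L
    while (changed && iter < 20L) {
      changed <- FALSE
      iter <- iter + 1L
      comps <- split(labs, graph_components(adj))
      for (C in comps) {
        if (length(C) < 3L) next
        atypical <- vapply(C, function(x)
          stats::median(dmatrix[x, setdiff(C, x)]) >= threshold, logical(1))
        names(atypical) <- C
        idx <- which(adj[C, C] & upper.tri(diag(length(C))), arr.ind = TRUE)
        for (r in seq_len(nrow(idx))) {
          i <- C[idx[r, 1L]]; j <- C[idx[r, 2L]]
          if (!adj[i, j]) next
          hit <- NA_real_
          for (S in tight) {
            if (i %in% S$side == j %in% S$side) next
            u <- if (i %in% S$side) j else i     # endpoint outside S
            ## the other side: a disjoint tight clade, or u alone if u is
            ## distance-atypical in its component
            other <- Filter(function(TT)
              u %in% TT$side && !any(TT$side %in% S$side), tight)
            if (length(other) || atypical[[u]]) {
              hit <- S$support
              break
            }
          }
          if (!is.na(hit)) {
            adj[i, j] <- adj[j, i] <- FALSE
            log[[length(log) + 1L]] <- data.frame(
              event = "split", units = paste(i, j, sep = ","),
              support = hit)
            changed <- TRUE
          }
        }
        if (changed) break
      }
    }
  }

  comp <- graph_components(adj)
  groups <- split(labs, comp)

  ## merge override: a supported clade of one multi-member group plus a
  ## near-threshold, otherwise-ungrouped unit pulls that unit in
  if (length(sided)) {
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      multi <- which(lengths(groups) >= 2L)
      singles <- unlist(groups[lengths(groups) == 1L])
      for (cl in sided) {
        touched <- which(vapply(groups[multi], function(g)
          length(intersect(g, cl$side)) > 0L, logical(1)))
        if (length(touched) != 1L) next
        gi <- multi[touched]
        extra <- intersect(setdiff(cl$side, groups[[gi]]), singles)
        if (!length(extra)) next
        if (!all(cl$side %in% c(groups[[gi]], extra))) next
        near <- vapply(extra, function(u)
          min(dmatrix[u, groups[[gi]]]) < merge_distance_factor * threshold,
          logical(1))
        extra <- extra[near]
        if (!length(extra)) next
        groups[[gi]] <- c(groups[[gi]], extra)
        groups <- groups[!(lengths(groups) == 1L &
                             vapply(groups, `[`, character(1), 1) %in% extra)]
        log[[length(log) + 1L]] <- data.frame(
          event = "merge", units = paste(sort(extra), collapse = ","),
          support = cl$support)
        changed <- TRUE
        break
      }
    }
  }

  ## contiguous numbering by first member in label order; singletons ungrouped
  multi <- groups[lengths(groups) >= 2L]
  first_pos <- vapply(multi, function(g) min(match(g, labs)), 1L)
  multi <- multi[order(first_pos)]
  assignment <- data.frame(unit = labs, group = NA_integer_,
                           stringsAsFactors = FALSE)
  for (i in seq_along(multi))
    assignment$group[assignment$unit %in% multi[[i]]] <- i
  overrides <- if (length(log)) do.call(rbind, log) else
    data.frame(event = character(0), units = character(0),
               support = numeric(0))
  structure(list(assignment = assignment, threshold = threshold,
                 support_override = support_override, overrides = overrides),
            class = "group_assignment")
}

## connected components of a logical adjacency matrix (BFS)
#' @noRd
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      nb <- which(adj[u, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.group_assignment <- function(x, ...) {
  g <- x$assignment$group
  n_groups <- length(unique(g[!is.na(g)]))
  cat(sprintf("Grouping at threshold %g: %d groups, %d ungrouped\n",
              x$threshold, n_groups, sum(is.na(g))))
  if (nrow(x$overrides))
    cat("Overrides applied:", nrow(x$overrides), "\n")
  invisible(x)
}

#' Summary counts of a group assignment
#' @param object A `group_assignment`.
#' @param ... Unused.
#' @return List with `n_groups`, `n_ungrouped`, `sizes`.
#' @export
summary.group_assignment <- function(object, ...) {
  g <- object$assignment$group
  list(n_groups = length(unique(g[!is.na(g)])),
       n_ungrouped = sum(is.na(g)),
       sizes = as.integer(table(g)))
}
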
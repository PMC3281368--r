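# Shared fixture builders: everything is generated in code, seeded.

rand_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Brute-force maximal exact diagonal runs of a self-comparison:
# for every offset d > 0, runs where s[i] == s[i + d], length >= min_len.
brute_force_self_matches <- function(seq, min_len) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  out <- list()
  for (d in seq_len(n - 1)) {
    len <- n - d
    if (len < min_len) break
    cmp <- chars[1:len] == chars[(1 + d):n]
    r <- rle(cmp)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len)) {
      out[[length(out) + 1L]] <- data.frame(
        offset = d, start = starts[k] - 1L, length = r$lengths[k])
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(offset = integer(0), start = integer(0), length = integer(0))
}

# Random additive distance matrix: random topology + exponential branch
# lengths, distances = patristic distances of the generating tree.
random_additive_case <- function(n_taxa, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n_taxa, br = function(k) stats::rexp(k, 10) + 0.05)
    tr <- ape::unroot(tr)
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}

# A small aligned fixture with two clearly separated clades.
two_clade_alignment <- function(n_per_clade = 4, len = 600, within = 0.01,
                                between = 0.3, seed = 1) {
  withr::with_seed(seed, {
    anc <- rand_seq(len)
    c1 <- mutate_jc(anc, between / 2)
    c2 <- mutate_jc(anc, between / 2)
    rows <- c(
      stats::setNames(vapply(seq_len(n_per_clade),
                             function(i) mutate_jc(c1, within / 2), ""),
                      paste0("x", seq_len(n_per_clade))),
      stats::setNames(vapply(seq_len(n_per_clade),
                             function(i) mutate_jc(c2, within / 2), ""),
                      paste0("y", seq_len(n_per_clade))))
    rows
  })
}
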
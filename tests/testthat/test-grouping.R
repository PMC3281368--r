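# Threshold grouping with bootstrap-support overrides.

test_that("zero distances collapse to one group with nothing ungrouped", {
  n <- 5
  d <- matrix(0, n, n, dimnames = list(paste0("u", 1:n), paste0("u", 1:n)))
  ga <- cluster_groups(d, threshold = 0.1)
  expect_identical(unique(ga$assignment$group), 1L)
  expect_identical(summary(ga)$n_ungrouped, 0L)
  expect_error(cluster_groups(d, threshold = 0), "threshold")
})

test_that("threshold components equal the brute-force graph oracle", {
  skip_if_not_installed("igraph")
  withr::with_seed(19, {
    for (i in 1:10) {
      n <- sample(10:40, 1)
      d <- matrix(stats::runif(n * n, 0, 0.3), n, n)
      d <- (d + t(d)) / 2
      diag(d) <- 0
      dimnames(d) <- list(paste0("u", 1:n), paste0("u", 1:n))
      ga <- cluster_groups(d, threshold = 0.1)
      g <- igraph::graph_from_adjacency_matrix(d < 0.1 & d > 0,
                                               mode = "undirected")
      memb <- igraph::components(g)$membership
      # same partition: multi-member components map 1:1 onto groups
      oracle_sizes <- sort(as.integer(table(memb)[table(memb) >= 2]))
      got_sizes <- sort(summary(ga)$sizes)
      expect_identical(got_sizes, oracle_sizes)
      expect_identical(summary(ga)$n_ungrouped, sum(table(memb) == 1))
      # every pair below threshold shares a group under single linkage
      for (k in 1:20) {
        ij <- sample(n, 2)
        if (memb[ij[1]] == memb[ij[2]])
          expect_identical(ga$assignment$group[ij[1]],
                           ga$assignment$group[ij[2]])
      }
    }
  })
})

test_that("two planted groups are recovered exactly", {
  withr::with_seed(9, {
    cfg <- sim_config(seed = 77L, species = "S1", units_per_species = 8L,
                      n_groups = 2L, unit_pattern = "alternating",
                      within_group_divergence = 0.02,
                      between_group_divergence = 0.2)
    dat <- generate_dataset(cfg)
    u <- dat$truth
    seqs <- stats::setNames(substring(dat$records[[1]], u$start + 1, u$end),
                            u$name)
    m <- jc_dist_matrix(align_units(seqs))
    ga <- cluster_groups(m, threshold = 0.1)
    expect_identical(summary(ga)$n_groups, 2L)
    expect_identical(summary(ga)$n_ungrouped, 0L)
    # assignment matches truth up to label switching
    expect_identical(length(unique(paste(ga$assignment$group, u$group))), 2L)
  })
})

test_that("merge override pulls a near-threshold unit into its clade", {
  # x sits at ~0.12 from a tight pair {a1, a2}: above threshold but inside
  # the supported clade, like the published A1-1 / A1-5 / A1-8 case
  rows <- withr::with_seed(3, {
    anc <- rand_seq(800)
    far <- mutate_jc(anc, 0.35)
    c(a1 = anc,
      a2 = mutate_jc(anc, 0.02),
      x = mutate_jc(anc, 0.12),
      b1 = far, b2 = mutate_jc(far, 0.02), b3 = mutate_jc(far, 0.025))
  })
  al <- align_units(rows)
  m <- jc_dist_matrix(al)
  st <- bootstrap_support(al, 200, seed = 4)
  ga <- cluster_groups(m, threshold = 0.1, st, support_override = 70)
  x_grp <- ga$assignment$group[ga$assignment$unit == "x"]
  a_grp <- ga$assignment$group[ga$assignment$unit == "a1"]
  expect_identical(x_grp, a_grp)
  expect_true(any(ga$overrides$event == "merge"))
  # without the tree there is no override
  ga0 <- cluster_groups(m, threshold = 0.1)
  expect_true(is.na(ga0$assignment$group[ga0$assignment$unit == "x"]))
})

test_that("split override cuts a sub-threshold link between supported clades", {
  # two tight clades whose closest members sit just under the threshold
  rows <- withr::with_seed(12, {
    anc <- rand_seq(1000)
    cA <- mutate_jc(anc, 0.045)
    cB <- mutate_jc(anc, 0.045)
    c(a1 = cA, a2 = mutate_jc(cA, 0.01), a3 = mutate_jc(cA, 0.012),
      b1 = cB, b2 = mutate_jc(cB, 0.01), b3 = mutate_jc(cB, 0.012))
  })
  al <- align_units(rows)
  m <- jc_dist_matrix(al)
  # only meaningful if at least one cross link is below threshold
  cross <- m[c("a1", "a2", "a3"), c("b1", "b2", "b3")]
  expect_true(min(cross) < 0.1)
  st <- bootstrap_support(al, 200, seed = 5)
  ga <- cluster_groups(m, threshold = 0.1, st, support_override = 70)
  expect_identical(summary(ga)$n_groups, 2L)
  expect_true(any(ga$overrides$event == "split"))
  # the same matrix without the tree keeps everything in one group
  ga0 <- cluster_groups(m, threshold = 0.1)
  expect_identical(summary(ga0)$n_groups, 1L)
})
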
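# Progressive aligner: row integrity, gap placement, determinism, and
# recovery of the planted group structure.

test_that("identical sequences align without gaps at identity 1", {
  rows <- c(u1 = "GGGTGACACGTACACC", u2 = "GGGTGACACGTACACC")
  al <- align_units(rows)
  expect_identical(unname(al$rows), unname(rows))
  expect_identical(nchar(al$rows[[1]]), nchar(rows[[1]]))
})

test_that("a single deletion produces exactly one gap column", {
  al <- align_units(c(a = "GGGTGAAACACCC", b = "GGGTGAACACCC"))
  m <- do.call(rbind, strsplit(unname(al$rows), ""))
  gap_cols <- which(apply(m == "-", 2, any))
  expect_length(gap_cols, 1L)
  # gapped row is the shorter one; degapping restores inputs
  expect_identical(gsub("-", "", al$rows[["a"]]), "GGGTGAAACACCC")
  expect_identical(gsub("-", "", al$rows[["b"]]), "GGGTGAACACCC")
})

test_that("pairwise alignment agrees with the Biostrings oracle score", {
  skip_if_not_installed("Biostrings")
  withr::with_seed(17, {
    for (i in 1:10) {
      a <- rand_seq(60)
      b <- mutate_jc(a, 0.1)
      b <- paste0(substr(b, 1, 30), substr(b, 34, 60))   # 3 nt deletion
      al <- align_units(c(a = a, b = b),
                        match = 2, mismatch = -1, gap_open = -5,
                        gap_extend = -2)
      # score the alignment we produced
      x <- strsplit(al$rows[["a"]], "")[[1]]
      y <- strsplit(al$rows[["b"]], "")[[1]]
      score <- 0; in_gap <- FALSE
      for (k in seq_along(x)) {
        if (x[k] == "-" || y[k] == "-") {
          score <- score + (-2) + if (!in_gap) -5 else 0
          in_gap <- TRUE
        } else {
          score <- score + if (x[k] == y[k]) 2 else -1
          in_gap <- FALSE
        }
      }
      ora <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(a), Biostrings::DNAString(b),
        substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
          match = 2, mismatch = -1, baseOnly = TRUE),
        gapOpening = 5, gapExtension = 2, type = "global")
      expect_equal(score, Biostrings::score(ora))
    }
  })
})

test_that("alignment rows always degap to their inputs", {
  withr::with_seed(23, {
    anc <- rand_seq(120)
    seqs <- stats::setNames(
      vapply(1:8, function(i) {
        s <- mutate_jc(anc, 0.1)
        if (i %% 2 == 0) s <- paste0(substr(s, 1, 50), substr(s, 53, 120))
        s
      }, ""), paste0("u", 1:8))
    al <- align_units(seqs)
    L <- unique(nchar(al$rows))
    expect_length(L, 1L)
    for (n in names(seqs))
      expect_identical(gsub("-", "", al$rows[[n]]), unname(seqs[[n]]))
    # deterministic and input-order invariant up to row naming
    al2 <- align_units(seqs[sample(names(seqs))])
    expect_identical(sort(unname(nchar(al2$rows))),
                     sort(unname(nchar(al$rows))))
  })
})

test_that("planted groups are closer within than between after alignment", {
  cfg <- barbirostris_config(seed = 41L)
  dat <- generate_dataset(cfg)
  u <- dat$truth
  seqs <- stats::setNames(
    substring(dat$records[u$record], u$start + 1, u$end), u$name)
  al <- align_units(seqs)
  m <- jc_dist_matrix(al)
  grp <- u$group
  same <- outer(grp, grp, "==") & upper.tri(m)
  diffp <- outer(grp, grp, "!=") & upper.tri(m)
  expect_lt(mean(m[same]), mean(m[diffp]))
  expect_lt(mean(m[same]), 0.08)
  expect_gt(mean(m[diffp]), 0.15)
})

test_that("gap-column exclusion removes exactly the insertion columns", {
  base <- rand_seq(90, seed = 77)
  with_ins <- paste0(substr(base, 1, 40), "ACGTA", substr(base, 41, 90))
  al <- align_and_filter(c(s1 = base, s2 = base, s3 = with_ins))
  expect_identical(al$removed_columns, 5L)
  expect_identical(unique(nchar(al$rows)), 90L)
  expect_identical(unname(al$rows[["s1"]]), base)
  # alignment length after filtering never exceeds the shortest input
  expect_lte(nchar(al$rows[[1]]), min(nchar(c(base, with_ins))))
  # no-gap case removes nothing
  al0 <- align_and_filter(c(a = base, b = base))
  expect_identical(al0$removed_columns, 0L)
})
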
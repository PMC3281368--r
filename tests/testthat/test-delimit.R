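# Unit delimitation by terminal motifs, naming, and the inverted-content
# scan.

make_exact_array <- function(n_units = 3, unit_len = 100, flank = 150,
                             seed = 2) {
  withr::with_seed(seed, {
    # keep chance motif occurrences out of the flanks and interior
    repeat {
      unit <- paste0("GGGTG", rand_seq(unit_len - 10), "CACCC")
      f5 <- rand_seq(flank); f3 <- rand_seq(flank)
      s <- paste0(f5, paste(rep(unit, n_units), collapse = ""), f3)
      h5 <- gregexpr("GGGTG", s)[[1]]
      if (length(h5) == n_units && !grepl("CA[CT]CC", paste0(f5, f3)) &&
          !grepl("GGGTG|CA[CT]CC", substr(unit, 2, unit_len - 1))) break
    }
    list(seq = s, unit = unit, flank = flank, unit_len = unit_len)
  })
}

test_that("an exact triplicated unit is cut into three equal units", {
  fx <- make_exact_array()
  span <- c(fx$flank, fx$flank + 3 * fx$unit_len)
  arr <- delimit_units(fx$seq, span, fx$unit_len)
  expect_identical(nrow(arr$units), 3L)
  expect_true(all(arr$units$end - arr$units$start == fx$unit_len))
  expect_equal(arr$units$start, fx$flank + fx$unit_len * 0:2)
  expect_error(delimit_units(fx$seq, c(10, 50), 100), "shorter than one")
})

test_that("a mutated motif falls back to a periodic cut and is flagged", {
  fx <- make_exact_array(n_units = 4)
  # destroy the motif5 of the third unit
  s <- fx$seq
  pos <- fx$flank + 2 * fx$unit_len
  substr(s, pos + 1, pos + 5) <- "TTTTT"
  span <- c(fx$flank, fx$flank + 4 * fx$unit_len)
  arr <- delimit_units(s, span, fx$unit_len)
  expect_identical(nrow(arr$units), 4L)
  expect_true(any(nzchar(arr$units$flag)))
  expect_true(all(abs(arr$units$start - (fx$flank + fx$unit_len * 0:3)) <= 5))
})

test_that("short terminal units like the A3 74/81 nt repeats are retained", {
  ok <- 0L
  for (s in 1:10) {
    cfg <- sim_config(seed = s, species = "A3", units_per_species = 3L,
                      n_groups = 3L,
                      unit_pattern = list(c(1L, 2L, 3L)),
                      group_lengths = c(74L, NA, 81L),
                      within_group_divergence = 0.03,
                      indel_rate = 0)
    dat <- generate_dataset(cfg)
    tr <- dat$truth
    arr <- delimit_units(dat$records[[1]],
                         c(dat$spans$array_start, dat$spans$array_end), 104)
    if (nrow(arr$units) == 3 &&
        all(abs(arr$units$start - tr$start) <= 3) &&
        all(abs(arr$units$end - tr$end) <= 3)) ok <- ok + 1L
  }
  expect_gte(ok, 9L)
})

test_that("extracted units are named in order and tile the span", {
  fx <- make_exact_array(n_units = 3)
  span <- c(fx$flank, fx$flank + 3 * fx$unit_len)
  rec <- spacer_record("A1", fx$seq)
  arr <- delimit_units(fx$seq, span, fx$unit_len)
  units <- extract_units(rec, arr)
  expect_identical(units$name, c("A1-1", "A1-2", "A1-3"))
  expect_identical(paste(units$sequence, collapse = ""),
                   substr(fx$seq, span[1] + 1, span[2]))
  expect_true(all(units$sequence == fx$unit))
  # single unit
  arr1 <- its2repeats:::repeat_array_obj(10L, 110L, "")
  u1 <- extract_units(spacer_record("ca", fx$seq), arr1)
  expect_identical(u1$name, "ca-1")
})

test_that("unit boundary recovery across seeded synthetic datasets", {
  # within-group divergence <= 0.05: unit count exact in >= 90% of records
  # and every boundary within 5 nt of truth
  n_ok <- 0L; n_rec <- 0L; boundary_ok <- TRUE
  for (s in 1:12) {
    cfg <- barbirostris_config(seed = s)
    dat <- generate_dataset(cfg)
    rep <- run_all(cfg, seed = s, bootstrap = 1L)
    for (rid in names(dat$records)) {
      n_rec <- n_rec + 1L
      tr <- subset(dat$truth, record == rid)
      u <- rep$units[rep$units$parent_id == rid, ]
      if (nrow(u) == nrow(tr)) {
        n_ok <- n_ok + 1L
        if (any(abs(u$start - tr$start) > 5) || any(abs(u$end - tr$end) > 5))
          boundary_ok <- FALSE
      }
    }
  }
  expect_gte(n_ok / n_rec, 0.9)
  expect_true(boundary_ok)
})

test_that("inverted content finds planted stems and skips homopolymers", {
  r <- inverted_content("AAAATTTT", min_stem = 4)
  expect_identical(nrow(r$stems), 1L)
  expect_identical(r$stems$left_start, 0L)
  expect_identical(r$stems$left_end, 4L)
  expect_identical(r$stems$right_start, 4L)
  expect_identical(r$stems$right_end, 8L)
  expect_equal(r$score, 1)

  expect_identical(nrow(inverted_content(strrep("A", 40))$stems), 0L)

  withr::with_seed(3, {
    arm <- rand_seq(20)
    rc <- its2repeats:::revcomp(arm)
    hp <- paste0("CCCCC", arm, "AAGAAGAA", rc, "CCCCC")
    r2 <- inverted_content(hp, min_stem = 6)
    big <- r2$stems[which.max(r2$stems$length), ]
    expect_gte(big$length, 20L)
    expect_lte(big$left_start, 5L)
  })
  expect_error(inverted_content("ACGT", min_stem = 3), "min_stem")
})
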
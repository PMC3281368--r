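# Synthetic generator: config validation, motif placement, JC calibration,
# determinism, and length conservation.

test_that("config validation rejects impossible setups", {
  expect_error(sim_config(unit_length_range = c(12L, 15L)),
               "too short to host")
  expect_error(sim_config(within_group_divergence = 0.3,
                          between_group_divergence = 0.2),
               "within_group_divergence")
  expect_error(sim_config(units_per_species = c(0L, 3L)),
               "at least one unit")
  expect_error(sim_config(unit_pattern = list(c(1L, 2L))),
               "one vector per species")
})

test_that("consensi carry the terminal motifs and the planted divergence", {
  cfg <- sim_config(seed = 3L, n_groups = 4L)
  cons <- make_group_consensi(cfg)
  expect_length(cons, 4L)
  expect_true(all(startsWith(cons, "GGGTG")))
  expect_true(all(grepl("CA[CT]CC$", cons)))
  # single group: nothing to diverge
  cons1 <- make_group_consensi(sim_config(seed = 3L, n_groups = 1L))
  expect_length(cons1, 1L)
})

test_that("pairwise consensus divergence is calibrated (Monte-Carlo)", {
  # two groups at between = 0.2, unit length ~100: the mean estimated JC
  # distance over replicate draws must sit within 3 simulation SE of 0.2
  target <- 0.2
  n_rep <- 400
  ds <- withr::with_seed(21, {
    vapply(seq_len(n_rep), function(i) {
      cfg <- sim_config(seed = i, n_groups = 2L,
                        unit_length_range = c(100L, 100L),
                        between_group_divergence = target)
      cons <- make_group_consensi(cfg, seed = sample.int(1e6, 1))
      al <- align_units(cons)
      jc_distance(al$rows[[1]], al$rows[[2]])
    }, numeric(1))
  })
  se <- stats::sd(ds) / sqrt(n_rep)
  expect_lt(abs(mean(ds) - target), 3 * se)
})

test_that("mutate_jc hits its target distance and respects protection", {
  s <- rand_seq(10000, seed = 4)
  expect_identical(mutate_jc(s, 0), s)
  # 200 replicates at target 0.1: mean estimate within 2 SE
  ds <- withr::with_seed(8, {
    vapply(1:200, function(i) jc_distance(s, mutate_jc(s, 0.1)), numeric(1))
  })
  se <- stats::sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - 0.1), 2 * se)
  # saturation guard
  expect_error(mutate_jc(s, 2.0), class = "jc_saturation_error")
  # protected positions never change
  prot <- 1:50
  out <- mutate_jc(s, 0.3, seed = 1, protect = prot)
  expect_identical(substr(out, 1, 50), substr(s, 1, 50))
})

test_that("within-group unit divergence converges to the configured value", {
  cfg <- sim_config(seed = 2L, species = "S1", units_per_species = 6L,
                    n_groups = 1L, within_group_divergence = 0.03,
                    indel_rate = 0, unit_length_range = c(104L, 104L))
  ds <- vapply(1:60, function(s) {
    dat <- generate_dataset(cfg, seed = s)
    u <- dat$truth
    seqs <- substring(dat$records[[1]], u$start + 1, u$end)
    al <- align_units(stats::setNames(seqs, u$name))
    m <- jc_dist_matrix(al)
    mean(m[upper.tri(m)])
  }, numeric(1))
  se <- stats::sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - 0.03), max(2 * se, 0.002))
})

test_that("datasets conserve structure, coordinates and determinism", {
  cfg <- sim_config(seed = 5L, species = "S1", units_per_species = 3L,
                    n_groups = 1L, unit_pattern = "block", indel_rate = 0)
  dat <- generate_dataset(cfg)
  u <- dat$truth
  # block pattern, single record: array span = sum of unit lengths
  expect_identical(dat$spans$array_end - dat$spans$array_start,
                   sum(u$end - u$start))
  # units tile the span contiguously and sit inside it
  expect_identical(u$start[-1], u$end[-nrow(u)])
  expect_true(all(u$start >= dat$spans$array_start &
                    u$end <= dat$spans$array_end))
  # every unit substring starts with motif5
  seqs <- substring(dat$records[[1]], u$start + 1, u$end)
  expect_true(all(startsWith(seqs, "GGGTG")))
  # seeded determinism, byte-for-byte, including the FASTA writer
  dat2 <- generate_dataset(cfg)
  expect_identical(dat$records, dat2$records)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(dat, d1); write_dataset(dat2, d2)
  expect_identical(readLines(file.path(d1, "spacers.fasta")),
                   readLines(file.path(d2, "spacers.fasta")))
})

test_that("alternating pattern plants the expected group sequence", {
  # emulates an 8-unit array alternating between two groups
  cfg <- sim_config(seed = 6L, species = "A4", units_per_species = 8L,
                    n_groups = 2L, unit_pattern = "alternating")
  dat <- generate_dataset(cfg)
  expect_identical(dat$truth$group, rep(c(1L, 2L), 4L))
})

test_that("the five-species default emulates the published architecture", {
  cfg <- barbirostris_config(seed = 1L)
  dat <- generate_dataset(cfg)
  counts <- table(factor(dat$truth$record, levels = names(dat$records)))
  expect_identical(as.integer(counts), c(10L, 8L, 3L, 8L, 8L))
  expect_identical(nrow(dat$truth), 37L)
  # two short terminal units in the A3 analog (74 and 81 nt before indels)
  a3 <- subset(dat$truth, record == "A3")
  expect_lt(a3$end[1] - a3$start[1], 80)
  expect_lt(a3$end[3] - a3$start[3], 90)
  # spacer lengths in the published 900-1700 nt range
  expect_true(all(nchar(dat$records) >= 900 & nchar(dat$records) <= 1750))
})
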
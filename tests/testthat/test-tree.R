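# NJ trees, bootstrap support, and bipartition comparison.

test_that("three-taxon NJ branch lengths follow the closed form", {
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["a"]], 1)
  expect_equal(bl[["b"]], 1)
  expect_equal(bl[["c"]], 3)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive matrices exactly", {
  # patristic distances reproduce the input within 1e-9 and the topology
  # matches the generating tree
  for (i in 1:30) {
    case <- random_additive_case(sample(6:10, 1), seed = 100 + i)
    tr <- nj_tree(case$d)
    got <- ape::cophenetic.phylo(tr)[rownames(case$d), colnames(case$d)]
    expect_lt(max(abs(got - case$d)), 1e-9)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), case$tree)), 0)
  }
})

test_that("label order does not change the unrooted topology", {
  case <- random_additive_case(8, seed = 55)
  tr1 <- nj_tree(case$d)
  perm <- sample(rownames(case$d))
  tr2 <- nj_tree(case$d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(tr1, tr2)), 0)
})

test_that("negative branches are clamped with the deficit moved to the sister", {
  # a matrix violating the four-point condition can yield negative NJ edges
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 0.1
  d["a", "c"] <- d["c", "a"] <- 0.11
  d["b", "c"] <- d["c", "b"] <- 0.01
  d["a", "d"] <- d["d", "a"] <- 0.3
  d["b", "d"] <- d["d", "b"] <- 0.35
  d["c", "d"] <- d["d", "c"] <- 0.28
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
  raw <- ape::nj(stats::as.dist(d))
  # total path content preserved where a clamp occurred
  if (any(raw$edge.length < 0))
    expect_equal(sum(tr$edge.length), sum(raw$edge.length))
})

test_that("bootstrap support separates planted clades and is deterministic", {
  rows <- two_clade_alignment(n_per_clade = 4, between = 0.3, within = 0.01,
                              seed = 31)
  st <- bootstrap_support(align_units(rows), n_replicates = 100, seed = 9)
  key <- paste(sort(paste0("y", 1:4)), collapse = "\r")
  sup <- st$splits$support[st$splits$key == key]
  expect_gte(sup, 95)
  st2 <- bootstrap_support(align_units(rows), n_replicates = 100, seed = 9)
  expect_identical(st$splits, st2$splits)
})

test_that("identical sequences give a defined, unsupported star-like tree", {
  rows <- stats::setNames(rep(strrep("ACGT", 50), 5), paste0("s", 1:5))
  st <- bootstrap_support(rows, n_replicates = 20, seed = 2)
  expect_true(all(st$splits$support >= 0 & st$splits$support <= 100))
})

test_that("tree comparison counts bipartition differences", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  expect_identical(compare_trees(t1, t1)$rf_distance, 0L)

  # one NNI on a 5-leaf tree changes exactly one bipartition on each side
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  cmp <- compare_trees(t1, t2)
  expect_identical(cmp$rf_distance, 2L)

  # caterpillar vs balanced 6-leaf: oracle by exhaustive bipartition listing
  cat6 <- ape::read.tree(text = "(a,(b,(c,(d,(e,f)))));")
  bal6 <- ape::read.tree(text = "((a,(b,c)),(d,(e,f)));")
  enum <- function(tr) {
    n <- length(tr$tip.label)
    parts <- ape::prop.part(tr)
    keys <- character(0)
    for (p in parts) {
      side <- sort(tr$tip.label[p])
      if (length(side) %in% c(0, 1, n - 1, n)) next
      if ("a" %in% side) side <- sort(setdiff(tr$tip.label, side))
      keys <- c(keys, paste(side, collapse = "|"))
    }
    unique(keys)
  }
  ka <- enum(cat6); kb <- enum(bal6)
  oracle <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  expect_identical(compare_trees(cat6, bal6)$rf_distance, oracle)

  skip_if_not_installed("phangorn")
  expect_equal(compare_trees(cat6, bal6)$rf_distance,
               as.integer(phangorn::RF.dist(cat6, bal6)))

  t3 <- ape::read.tree(text = "((a,b),(c,x),e);")
  expect_error(compare_trees(t1, t3), "leaf sets")
})
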
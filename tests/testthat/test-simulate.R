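sp8 <- study_tree8()

test_that("the deterministic regime reproduces closed-form copy counts", {
  cfg <- simulationConfig(sp8,
    events = data.frame(branch = c("N1", "N5"), type = c("WGD", "WGT")),
    nFamilies = 3, seed = 11)
  expected <- vapply(sp8$tip.label, function(s) expectedCopyCounts(cfg, s), 0L)
  expect_identical(unname(expected[c("S1", "S5", "S7")]), c(2L, 3L, 1L))
  for (i in 1:3) {
    fam <- simulateFamily(cfg, i)
    sp <- leafSpecies(fam$tree)
    counts <- table(factor(sp, levels = sp8$tip.label))
    expect_identical(as.integer(counts), unname(expected))
  }
})

test_that("expectedCopyCounts multiplies nested events and rejects noise", {
  cfg <- simulationConfig(sp8,
    events = data.frame(branch = c("N1", "N2"), type = c("WGD", "WGT")))
  expect_identical(expectedCopyCounts(cfg, "S1"), 6L)  # 2 x 3
  expect_identical(expectedCopyCounts(cfg, "S3"), 2L)
  expect_identical(expectedCopyCounts(cfg, "S8"), 1L)
  noisy <- simulationConfig(sp8, lambdaLoss = 0.1)
  expect_error(expectedCopyCounts(noisy, "S1"), "deterministic regime")
  expect_error(expectedCopyCounts(cfg, "N1"), "not a species tip")
})

test_that("no events and no noise yields families congruent with the species tree", {
  cfg <- simulationConfig(sp8, nFamilies = 5, seed = 3)
  for (i in 1:5) {
    fam <- simulateFamily(cfg, i)
    expect_false(fam$extinct)
    rec <- reconcileFamily(fam$tree, sp8, "f")
    expect_identical(nDuplications(rec), 0L)
    expect_identical(nrow(fam$truth), 0L)
  }
})

test_that("loss-only families reconcile with zero duplications", {
  cfg <- simulationConfig(sp8, lambdaLoss = 0.4, nFamilies = 40, seed = 17)
  nonExtinct <- 0L
  for (i in 1:40) {
    fam <- simulateFamily(cfg, i)
    if (fam$extinct || ape::Ntip(fam$tree) < 2) next
    nonExtinct <- nonExtinct + 1L
    rec <- reconcileFamily(fam$tree, sp8, "f")
    expect_identical(nDuplications(rec), 0L)
    ## leaves are a subset restriction of the species tree
    expect_true(all(leafSpecies(fam$tree) %in% sp8$tip.label))
  }
  expect_gt(nonExtinct, 10L)
})

test_that("per-copy WGD retention is binomial with the configured rate", {
  r <- 0.7
  two <- readNewick("(A:1,B:1)R;")
  cfg <- simulationConfig(two,
    events = data.frame(branch = "A", type = "WGD", retention = r),
    nFamilies = 1000, seed = 23)
  retained <- vapply(1:1000, function(i) {
    tr <- simulateFamily(cfg, i)$truth
    tr$copies_after[tr$type == "WGD"] == 2L
  }, TRUE)
  phat <- mean(retained)
  se <- sqrt(r * (1 - r) / 1000)
  expect_lt(abs(phat - r), 3 * se)
})

test_that("truth tables account for copies crossing each event", {
  cfg <- simulationConfig(sp8,
    events = data.frame(branch = c("N1", "N1"), type = "WGD",
                        position = c(0.4, 0.6), retention = 1),
    nFamilies = 1, seed = 5)
  tr <- simulateFamily(cfg, 1)$truth
  tr <- tr[order(tr$position), ]
  expect_identical(tr$copies_before, c(1L, 2L))
  expect_identical(tr$copies_after, c(2L, 4L))
})

test_that("datasets re-simulate byte-identically from the same seed", {
  cfg <- simulationConfig(sp8,
    events = data.frame(branch = "N1", type = "WGD", retention = 0.8),
    lambdaDup = 0.02, lambdaLoss = 0.1, nFamilies = 6, seed = 99)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulateDataset(cfg, d1)
  simulateDataset(cfg, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (k in seq_along(f1))
    expect_identical(readLines(f1[k]), readLines(f2[k]))
  ## a different seed changes the forest
  cfg2 <- simulationConfig(sp8,
    events = data.frame(branch = "N1", type = "WGD", retention = 0.8),
    lambdaDup = 0.02, lambdaLoss = 0.1, nFamilies = 6, seed = 100)
  d3 <- withr::local_tempdir()
  simulateDataset(cfg2, d3)
  trees1 <- readLines(file.path(d1, "fam0001.nwk"))
  trees3 <- readLines(file.path(d3, "fam0001.nwk"))
  expect_false(identical(trees1, trees3))
})

test_that("families are reproducible individually, independent of order", {
  cfg <- simulationConfig(sp8, lambdaDup = 0.05, lambdaLoss = 0.1,
                          nFamilies = 4, seed = 7)
  f3 <- simulateFamily(cfg, 3)
  simulateFamily(cfg, 1)  # interleave other draws
  f3again <- simulateFamily(cfg, 3)
  expect_identical(writeNewick(f3$tree), writeNewick(f3again$tree))
  expect_identical(f3$truth, f3again$truth)
})

test_that("invalid configurations are rejected", {
  expect_error(simulationConfig(sp8,
    events = data.frame(branch = "N1", type = "WGD", position = 1.2)),
    "strictly inside")
  expect_error(simulationConfig(sp8,
    events = data.frame(branch = "N1", type = "WGD", retention = 1.5)),
    "retention")
  expect_error(simulationConfig(sp8,
    events = data.frame(branch = "nope", type = "WGD")), "unknown node")
  expect_error(simulationConfig(sp8, lambdaLoss = -1), "rates")
})
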
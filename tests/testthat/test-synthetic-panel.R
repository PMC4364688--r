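test_that("same parameters and seed reproduce the panel bit for bit", {
  p <- panelParams(nLines = 30, nMarkers = 40, nChrom = 2,
                   mapLengthCM = 90, seed = 11)
  a <- simulatePanel(p)
  b <- simulatePanel(p)
  expect_identical(calls(a$panel), calls(b$panel))
  expect_identical(positions(a$map), positions(b$map))
})

test_that("panel respects its declared invariants", {
  sim <- simulatePanel(panelParams(nLines = 50, nMarkers = 60, nChrom = 3,
                                   mapLengthCM = 135, seed = 2))
  m <- calls(sim$panel)
  expect_false(anyNA(m))
  expect_true(all(m %in% c(0L, 1L)))
  maf <- pmin(colMeans(m), 1 - colMeans(m))
  expect_true(all(maf >= 0.01))
  expect_equal(ncol(m), 60)
  for (chr in 1:3) {
    pos <- positions(sim$map)[chromosomes(sim$map) == chr]
    expect_true(all(diff(pos) > 0))
  }
})

test_that("without mosaic switching every line copies one founder per chromosome", {
  sim <- simulatePanel(panelParams(nLines = 40, nMarkers = 60, nChrom = 2,
                                   mapLengthCM = 135, nFounders = 2,
                                   mosaicSwitchRate = 0, mutationRate = 0,
                                   seed = 5))
  m <- calls(sim$panel)
  for (chr in 1:2) {
    ids <- markerIds(sim$map)[chromosomes(sim$map) == chr]
    patterns <- unique(apply(m[, ids], 1, paste, collapse = ""))
    expect_lte(length(patterns), 2)
    # adjacent segregating pairs are in complete LD (two-founder limit)
    sub <- m[, ids]
    v <- apply(sub, 2, var)
    for (j in which(v[-length(v)] > 0 & v[-1] > 0))
      expect_equal(pairwiseR2(sub[, j], sub[, j + 1]), 1)
  }
})

test_that("mosaic calls equal the founder haplotypes along the founder path", {
  sim <- simulatePanel(panelParams(nLines = 30, nMarkers = 50, nChrom = 2,
                                   mapLengthCM = 112, nFounders = 6,
                                   mutationRate = 0, seed = 7))
  m <- calls(sim$panel)
  fh <- sim$founderHap
  fp <- sim$founderPath
  rebuilt <- matrix(0L, nrow(m), ncol(m))
  for (j in seq_len(ncol(m))) rebuilt[, j] <- fh[fp[, j], j]
  expect_identical(unname(m), rebuilt)
})

test_that("realized founder-switch count tracks the per-cM intensity", {
  rate <- 0.01
  sims <- lapply(1:2, function(s)
    simulatePanel(panelParams(nLines = 50, nMarkers = 400, nChrom = 4,
                              mapLengthCM = 900, mosaicSwitchRate = rate,
                              seed = s)))
  nsw <- unlist(lapply(sims, `[[`, "nSwitches"))
  expected <- rate * 900
  se <- sd(nsw) / sqrt(length(nsw))
  # small allowance for the 1 - exp(-rate d) vs rate d curvature
  expect_lt(abs(mean(nsw) - expected), 3 * se + 0.02 * expected)
})

test_that("adjacent LD is non-increasing in the mosaic switch rate", {
  rates <- c(0.002, 0.05, 1)
  means <- sapply(rates, function(r) {
    mean(sapply(1:10, function(s) {
      sim <- simulatePanel(panelParams(nLines = 80, nMarkers = 60,
                                       nChrom = 2, mapLengthCM = 135,
                                       mosaicSwitchRate = r, seed = s))
      panelSummary(sim$panel, sim$map)$meanAdjacentR2
    }))
  })
  expect_true(all(diff(means) <= 0))
})

test_that("infeasible MAF floor fails after bounded redraw rounds", {
  expect_error(
    simulatePanel(panelParams(nLines = 10, nMarkers = 30, nChrom = 1,
                              mapLengthCM = 60, mafFloor = 0.49,
                              maxRedrawRounds = 3, seed = 1)),
    "mafFloor")
})

test_that("array designation is evenly spaced, sized and deterministic", {
  gm <- GeneticMap(paste0("M", 1:20), rep(1:2, each = 10),
                   rep(seq(0, 90, by = 10), 2))
  des <- designateArrays(gm, 0.5)
  expect_identical(lowSet(des),
                   paste0("M", c(seq(1, 9, 2), seq(11, 19, 2))))
  expect_identical(lowSet(des), lowSet(designateArrays(gm, 0.5)))
  expect_length(imputeSet(des), 10)

  # study-scale size check: |lowSet| tracks the 1,573 : 9,926 nesting ratio
  perChrom <- rep(9926 %/% 21, 21) + c(rep(1, 9926 %% 21), rep(0, 21 - 9926 %% 21))
  big <- GeneticMap(sprintf("S%05d", 1:9926), rep(1:21, perChrom),
                    unlist(lapply(perChrom, function(k) seq_len(k) * 2.14)))
  desBig <- designateArrays(big, 1573 / 9926)
  expect_lte(abs(length(lowSet(desBig)) - 1573), 21)
  expect_error(designateArrays(gm, 1.2), "lowFraction")
})

test_that("panel summary matches hand-counted LD and MAF", {
  m <- toyCalls(cbind(rep(c(1L, 0L), c(5, 5)), rep(c(1L, 0L), c(3, 7))))
  gm <- GeneticMap(colnames(m), c(1L, 1L), c(0, 1))
  ps <- panelSummary(GenotypePanel(m), gm)
  expect_equal(ps$meanAdjacentR2, 3 / 7, tolerance = 1e-10)
  expect_equal(ps$meanMaf, mean(c(0.5, 0.3)))
  expect_equal(ps$nAdjacentPairs, 1L)

  # identical columns: complete LD, both MAF 0.5
  m2 <- toyCalls(cbind(rep(c(1L, 0L), each = 4), rep(c(1L, 0L), each = 4)))
  ps2 <- panelSummary(GenotypePanel(m2), GeneticMap(colnames(m2), c(1L, 1L), c(0, 1)))
  expect_equal(ps2$meanAdjacentR2, 1)
  expect_equal(ps2$meanMaf, 0.5)

  # identical lines: monomorphic everywhere, no evaluable pair
  m3 <- toyCalls(matrix(1L, 4, 3))
  ps3 <- panelSummary(GenotypePanel(m3), GeneticMap(colnames(m3), rep(1L, 3), 1:3))
  expect_equal(ps3$meanMaf, 0)
  expect_equal(ps3$nAdjacentPairs, 0L)
  expect_equal(ps3$nSkippedPairs, 2L)
})
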
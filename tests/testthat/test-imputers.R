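test_that("frequency baseline writes observed allele frequencies", {
  m <- toyCalls(cbind(c(1L, 1L, 0L, 0L, 1L, 0L), rep(1L, 6)))
  mk <- maskCells(m, c(5L, 6L, 10L))   # rows 5-6 of marker 1, row 4 of marker 2
  ip <- imputeFreq(mk)
  expect_equal(unname(dosages(ip)[5:6, 1]), c(0.5, 0.5))
  expect_equal(unname(dosages(ip)[4, 2]), 1)    # monomorphic observed marker
  # dosage at every masked cell equals that marker's observed mean
  freq <- colMeans(calls(mk), na.rm = TRUE)
  miss <- which(is.na(calls(mk)))
  expect_equal(unname(dosages(ip)[miss]),
               unname(freq[(miss - 1) %/% 6 + 1]))
})

test_that("frequency baseline fails on a fully missing marker", {
  m <- toyCalls(cbind(c(NA, NA, NA, NA), c(0L, 1L, 0L, 1L)))
  mk <- maskCells(m, c(5L))   # mask one cell of marker 2; marker 1 orig-missing
  expect_error(imputeFreq(mk), "zero observed")
})

test_that("all imputers preserve observed cells, bounds and determinism", {
  sim <- smallSim(21, nLines = 60, nMarkers = 42)
  des <- designateArrays(sim$map, 0.25)
  mk <- maskLowToHigh(sim$panel, des, refSize = 30, seed = 5)
  obs <- maskStates(mk) == MASK_OBSERVED
  runs <- list(
    freq = function() imputeFreq(mk),
    rf = function() imputeRandomForest(mk, rfParams(nTrees = 30, seed = 3)),
    window = function() imputeWindow(mk, sim$map),
    lshmm = function() imputeLsHmm(mk, sim$map))
  for (nm in names(runs)) {
    a <- runs[[nm]]()
    b <- runs[[nm]]()
    d <- dosages(a)
    expect_equal(d[obs], as.numeric(calls(mk)[obs]), ignore_attr = TRUE)
    expect_true(all(d >= 0 & d <= 1))
    expect_false(anyNA(d[maskStates(mk) == MASK_MASKED]))
    expect_identical(d, dosages(b))
    expect_identical(a@imputer, nm)
  }
})

test_that("random forest recovers a masked duplicate of an observed marker", {
  sim <- smallSim(22, nLines = 50, nMarkers = 30)
  m <- calls(sim$panel)
  m[, 2] <- m[, 1]   # marker 2 duplicates marker 1 pre-masking
  rows <- 11:30
  idx <- (2L - 1L) * nrow(m) + rows
  mk <- maskCells(m, idx)
  ip <- imputeRandomForest(mk, rfParams(seed = 9))
  err <- abs(dosages(ip)[rows, 2] - m[rows, 2])
  expect_lt(mean(err), 0.1)
})

test_that("random forest with nothing to impute returns the input", {
  sim <- smallSim(23, nLines = 20, nMarkers = 12)
  mk <- maskCells(calls(sim$panel), integer(0))
  ip <- imputeRandomForest(mk, rfParams(seed = 1))
  expect_equal(dosages(ip), matrix(as.numeric(calls(sim$panel)), 20, 12,
                                   dimnames = dimnames(calls(sim$panel))))
})

test_that("window matcher copies a unique perfect donor", {
  base <- rep(c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L), 2)
  m <- toyCalls(rbind(d1 = base, d2 = 1L - base, t = base))
  gm <- GeneticMap(colnames(m), rep(1L, 16), 1:16)
  idx <- (seq(2, 16, 2) - 1L) * 3L + 3L   # mask even markers of the target
  mk <- maskCells(m, idx)
  ip <- imputeWindow(mk, gm, windowParams(initialWindow = 8, minWindow = 4))
  expect_equal(unname(dosages(ip)[3, seq(2, 16, 2)]),
               as.numeric(base[seq(2, 16, 2)]))
})

test_that("window matcher averages tied donors and falls back to frequency", {
  base <- rep(c(0L, 1L), 8)
  other <- base; other[4] <- 1L - other[4]
  m <- toyCalls(rbind(d1 = base, d2 = other, t = base))
  gm <- GeneticMap(colnames(m), rep(1L, 16), 1:16)
  mk <- maskCells(m, (4L - 1L) * 3L + 3L)  # mask marker 4 of the target
  ip <- imputeWindow(mk, gm)
  # the two donors disagree only at the masked position: equal-weight tie
  expect_equal(unname(dosages(ip)[3, 4]), 0.5)

  # all lines missing somewhere in every window: no donors, frequency fallback
  m2 <- toyCalls(matrix(rep(c(0L, 1L, 1L), 8), 3, 8))
  miss <- c(1L, (2L - 1L) * 3L + 2L, (3L - 1L) * 3L + 3L,
            (4L - 1L) * 3L + 1L, (5L - 1L) * 3L + 2L, (6L - 1L) * 3L + 3L,
            (7L - 1L) * 3L + 1L, (8L - 1L) * 3L + 2L)
  mk2 <- maskCells(m2, miss)
  ip2 <- imputeWindow(mk2, GeneticMap(colnames(m2), rep(1L, 8), 1:8),
                      windowParams(initialWindow = 8, minWindow = 8))
  expect_equal(dosages(ip2)[miss], dosages(imputeFreq(mk2))[miss])
})

test_that("HMM posterior collapses onto a uniquely matching reference", {
  H <- rbind(c(1L, 1L, 1L, 1L), c(0L, 1L, 0L, 0L))
  m <- toyCalls(rbind(r1 = H[1, ], r2 = H[2, ],
                      t = c(1L, 1L, 1L, 1L)))
  gm <- GeneticMap(colnames(m), rep(1L, 4), c(0, 1, 2, 3))
  mk <- maskCells(m, c((2L - 1L) * 3L + 3L, (4L - 1L) * 3L + 3L))
  ip <- imputeLsHmm(mk, gm, hmmParams(errorRate = 1e-4,
                                      switchIntensity = 1e-4))
  expect_equal(unname(dosages(ip)[3, c(2, 4)]), c(1, 1), tolerance = 1e-3)
})

test_that("HMM forward and backward likelihoods agree and posteriors normalize", {
  sim <- smallSim(24, nLines = 40, nMarkers = 30)
  des <- designateArrays(sim$map, 0.3)
  mk <- maskLowToHigh(sim$panel, des, refSize = 20, seed = 6)
  ip <- imputeLsHmm(mk, sim$map)
  ll <- attr(ip, "loglik")
  expect_true(all(abs(ll[, "loglikF"] - ll[, "loglikB"]) /
                    abs(ll[, "loglikF"]) < 1e-8))
  H <- calls(sim$panel)[1:5, 1:8]
  obs <- c(1L, NA, 0L, NA, NA, 1L, 0L, NA)
  fb <- InbredImpute:::.lsForwardBackward(H, obs, rep(0.9, 7), 0.01)
  expect_equal(colSums(fb$gamma), rep(1, 8), tolerance = 1e-10)
})

test_that("HMM matches the exhaustive path-sum oracle on toy problems", {
  # canonical toy: opposite references, target observed [1, ., 1]
  H <- rbind(c(1L, 1L, 1L), c(0L, 0L, 0L))
  obs <- c(1L, NA, 1L)
  fb <- InbredImpute:::.lsForwardBackward(H, obs, c(0.9, 0.9), 0.01)
  dos <- colSums(fb$gamma * H)
  oracle <- lsPathOracle(H, obs, c(0.9, 0.9), 0.01)
  expect_equal(dos[2], oracle[2], tolerance = 1e-10)

  # randomized small cases: <= 4 markers x <= 3 references
  set.seed(77)
  for (case in 1:12) {
    K <- sample(2:3, 1); M <- sample(2:4, 1)
    H <- matrix(rbinom(K * M, 1, 0.5), K, M)
    obs <- rbinom(M, 1, 0.5)
    obs[sample(M, sample(M - 1, 1))] <- NA
    stay <- runif(M - 1, 0.5, 0.99)
    eps <- runif(1, 0.005, 0.2)
    fb <- InbredImpute:::.lsForwardBackward(H, obs, stay, eps)
    expect_equal(colSums(fb$gamma * H), lsPathOracle(H, obs, stay, eps),
                 tolerance = 1e-10)
  }
})
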
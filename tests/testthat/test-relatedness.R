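test_that("Rogers' distance equals the proportion of differing loci", {
  m <- toyCalls(rbind(a = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 1L, 1L),
                      b = c(1L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L, 1L),
                      c = c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 1L, 1L)))
  rd <- rogersDistance(m)
  expect_equal(rd["a", "b"], 0.3)          # differ at 3 of 10 loci
  expect_equal(rd["a", "c"], 0)            # identical lines
  expect_equal(rd, t(rd))
  expect_equal(unname(diag(rd)), rep(0, 3))
})

test_that("Rogers' distance equals normalized Hamming distance on random panels", {
  sim <- smallSim(51, nLines = 25, nMarkers = 40)
  m <- calls(sim$panel)
  rd <- rogersDistance(sim$panel)
  ham <- as.matrix(stats::dist(m, method = "manhattan")) / ncol(m)
  expect_equal(unname(rd), unname(ham), tolerance = 1e-12,
               ignore_attr = TRUE)
  # pairwise-complete handling is a no-op on complete data
  expect_equal(rogersDistance(m, pairwiseComplete = TRUE), rd,
               ignore_attr = TRUE)
})

test_that("pairwise-complete distances use per-pair locus counts", {
  m <- toyCalls(rbind(a = c(1L, 0L, 1L, NA), b = c(1L, 1L, NA, 0L),
                      c = c(0L, 0L, 0L, 0L)))
  rd <- rogersDistance(m, pairwiseComplete = TRUE)
  expect_equal(rd["a", "b"], 1 / 2)   # shared loci 1,2; differ at 2
  expect_equal(attr(rd, "nLoci")["a", "b"], 2)
  m2 <- toyCalls(rbind(a = c(1L, NA), b = c(NA, 0L)))
  expect_error(rogersDistance(m2, pairwiseComplete = TRUE), "share no")
  expect_error(rogersDistance(m), "pairwiseComplete")
})

test_that("dosages are rounded at 0.5 before the distance is taken", {
  d <- matrix(c(0.9, 0.2, 0.51, 0.49), 2, 2,
              dimnames = list(c("a", "b"), c("M1", "M2")))
  ip <- new("ImputedPanel", dosages = d, imputer = "x", params = list())
  rd <- rogersDistance(ip)
  expect_equal(rd["a", "b"], 1)   # (1,1) vs (0,0)
})

test_that("matrix correlation works on strict upper triangles", {
  ids <- c("a", "b", "c")
  A <- matrix(0, 3, 3, dimnames = list(ids, ids))
  B <- A
  A[upper.tri(A)] <- c(0.1, 0.2, 0.3); A <- A + t(A)
  B[upper.tri(B)] <- c(0.3, 0.2, 0.1); B <- B + t(B)
  expect_equal(matrixCorrelation(A, B), -1)
  expect_equal(matrixCorrelation(A, A), 1)
  expect_equal(matrixCorrelation(A, 2 * A), 1)   # linear invariance
  expect_error(matrixCorrelation(A, B[c(2, 1, 3), c(2, 1, 3)]), "share")
})

test_that("Mantel test: self-comparison p, determinism, noise sensitivity", {
  set.seed(61)
  ids <- sprintf("L%02d", 1:8)
  v <- runif(28)
  A <- matrix(0, 8, 8, dimnames = list(ids, ids))
  A[upper.tri(A)] <- v; A <- A + t(A)
  mt <- mantelTest(A, A, nPerm = 999, seed = 5)
  expect_equal(mt$observed, 1)
  expect_equal(mt$p, 1 / 1000)
  expect_equal(mantelTest(A, A, nPerm = 999, seed = 5)$p, mt$p)

  noise <- matrix(0, 8, 8, dimnames = list(ids, ids))
  noise[upper.tri(noise)] <- runif(28); noise <- noise + t(noise)
  pSmall <- mantelTest(A, A + 0.05 * noise, nPerm = 999, seed = 6)$p
  pBig <- mantelTest(A, A + 50 * noise, nPerm = 999, seed = 6)$p
  expect_lte(pSmall, pBig)
  expect_equal(pSmall, 1 / 1000)
})

test_that("Mantel p is roughly uniform under the null", {
  set.seed(62)
  ids <- sprintf("L%02d", 1:10)
  ps <- replicate(40, {
    A <- matrix(0, 10, 10, dimnames = list(ids, ids))
    B <- A
    A[upper.tri(A)] <- runif(45); A <- A + t(A)
    B[upper.tri(B)] <- runif(45); B <- B + t(B)
    mantelTest(A, B, nPerm = 199, seed = sample.int(1e6, 1))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("distance benchmark: perfect imputer scores 1 and the benchmark column is exact", {
  sim <- smallSim(52, nLines = 60, nMarkers = 42)
  des <- designateArrays(sim$map, 0.25)
  mk <- maskLowToHigh(sim$panel, des, refSize = 30, seed = 3)
  m <- calls(sim$panel)
  perfect <- new("ImputedPanel",
                 dosages = matrix(as.numeric(m), nrow(m), ncol(m),
                                  dimnames = dimnames(m)),
                 imputer = "oracle", params = list())
  tab <- rdBenchmark(sim$panel, des, mk, list(oracle = perfect))
  expect_equal(tab$cor[tab$dataset == "oracle"], 1)
  tl <- testLines(mk)
  bench <- matrixCorrelation(
    rogersDistance(m[tl, lowSet(des)]),
    rogersDistance(m[tl, highSet(des)]))
  expect_equal(tab$cor[tab$dataset == "low-density benchmark"], bench)
})

test_that("HMM-imputed distances track truth better than the frequency baseline", {
  # freq fills every masked cell with a constant, so its test-line distance
  # matrix is degenerate (correlation undefined -> scored 0)
  diffs <- sapply(1:5, function(rep) {
    sim <- smallSim(60 + rep, nLines = 80, nMarkers = 84)
    des <- designateArrays(sim$map, 1573 / 9926)
    mk <- maskLowToHigh(sim$panel, des, refSize = 40,
                        seed = stableSeed(8, "rd", rep))
    tab <- suppressWarnings(
      rdBenchmark(sim$panel, des, mk,
                  list(freq = imputeFreq(mk),
                       lshmm = imputeLsHmm(mk, sim$map))))
    freqCor <- tab$cor[tab$dataset == "freq"]
    if (is.na(freqCor)) freqCor <- 0
    tab$cor[tab$dataset == "lshmm"] - freqCor
  })
  expect_gt(mean(diffs), 0)
})
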
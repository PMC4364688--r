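#' Expected overall missing rate of the low-to-high design
#'
#' Fraction of all panel cells that the nested-array design masks: test
#' lines make up (nLines - refSize)/nLines of the panel and each loses the
#' imputeSet fraction nImpute/nHigh of its markers. For the study's
#' dimensions (371 lines, 9,926 / 8,353 markers) the four canonical
#' reference sizes 50, 100, 200 and 300 give 72.8%, 61.5%, 38.8% and 16.1%.
#'
#' @param nLines panel size.
#' @param refSize reference-population size (0 < refSize <= nLines).
#' @param nHigh number of markers on the high-density array.
#' @param nImpute number of markers to impute (high minus low).
#' @return the expected missing fraction.
#' @examples
#' expectedMissingRate(371, 50, 9926, 8353)   # 0.728
#' @export
expectedMissingRate <- function(nLines, refSize, nHigh, nImpute) {
  if (nLines <= 0 || nHigh <= 0 || nImpute <= 0)
    stopf("all counts must be positive")
  if (refSize <= 0 || refSize > nLines)
    stopf("refSize must lie in (0, nLines]")
  if (nImpute >= nHigh) stopf("nImpute must be smaller than nHigh")
  ((nLines - refSize) / nLines) * (nImpute / nHigh)
}

.newMaskedPanel <- function(origCalls, maskedIdx, scenario,
                            refLines = character(0),
                            testLines = character(0)) {
  mask <- matrix(MASK_OBSERVED, nrow(origCalls), ncol(origCalls),
                 dimnames = dimnames(origCalls))
  mask[is.na(origCalls)] <- MASK_ORIG_MISSING
  mask[maskedIdx] <- MASK_MASKED
  truth <- matrix(NA_real_, nrow(origCalls), ncol(origCalls),
                  dimnames = dimnames(origCalls))
  truth[maskedIdx] <- as.numeric(origCalls[maskedIdx])
  cm <- origCalls
  cm[maskedIdx] <- NA_integer_
  new("MaskedPanel", panel = GenotypePanel(cm), mask = mask, truth = truth,
      scenario = scenario, refLines = refLines, testLines = testLines)
}

#' Mask a panel under the nested low-to-high array design
#'
#' Partitions the lines uniformly at random into a reference population of
#' size \code{refSize} (genotyped at full density) and a test population
#' (genotyped only at the low-density subset): for every test line, all
#' cells of the design's imputeSet are set to missing and recorded as
#' evaluation targets. Reference lines and low-density markers are never
#' masked; cells missing in the input panel are tracked separately and are
#' never evaluation targets.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param design an \linkS4class{ArrayDesign} over the panel's markers.
#' @param refSize reference-population size (< number of lines).
#' @param seed integer seed for the reference/test split.
#' @param replicate replicate index recorded in the scenario (default 1).
#' @return a \linkS4class{MaskedPanel}.
#' @export
maskLowToHigh <- function(panel, design, refSize, seed = NULL,
                          replicate = 1L) {
  cm <- calls(panel)
  if (!setequal(colnames(cm), highSet(design)))
    stopf("design markers do not match the panel")
  n <- nrow(cm)
  if (refSize <= 0 || refSize >= n)
    stopf("refSize must lie strictly between 0 and the number of lines")
  withSeed(seed, {
    ref <- sort(sample(rownames(cm), refSize))
    test <- setdiff(rownames(cm), ref)
    maskedIdx <- which(
      matrix(rownames(cm) %in% test, n, ncol(cm)) &
      matrix(colnames(cm) %in% imputeSet(design), n, ncol(cm), byrow = TRUE) &
      !is.na(cm))
    .newMaskedPanel(cm, maskedIdx,
                    scenario = list(kind = "low2high", refSize = refSize,
                                    replicate = as.integer(replicate),
                                    seed = seed),
                    refLines = ref, testLines = test)
  })
}

#' Mask a panel with GBS-like random depletion
#'
#' For each line independently, \code{round(missingRate * nMarkers)} marker
#' cells are chosen uniformly without replacement and set to missing,
#' mimicking the randomly scattered missingness of genotyping-by-sequencing
#' data. Cells already missing in the input stay originally-missing and the
#' per-line draw is taken over all markers, so the realized masked fraction
#' matches the nominal rate up to rounding.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param missingRate per-line fraction of markers to mask, in (0, 1).
#' @param seed integer seed.
#' @param replicate replicate index recorded in the scenario (default 1).
#' @return a \linkS4class{MaskedPanel}.
#' @export
maskGbsLike <- function(panel, missingRate, seed = NULL, replicate = 1L) {
  cm <- calls(panel)
  if (missingRate <= 0 || missingRate >= 1)
    stopf("missingRate must lie in (0, 1)")
  nm <- ncol(cm)
  k <- round(missingRate * nm)
  if (k >= nm)
    stopf("missingRate would mask every marker of a line, leaving no anchor")
  withSeed(seed, {
    maskedIdx <- integer(0)
    if (k > 0) {
      for (i in seq_len(nrow(cm))) {
        cols <- sample.int(nm, k)
        cols <- cols[!is.na(cm[i, cols])]
        maskedIdx <- c(maskedIdx, (cols - 1L) * nrow(cm) + i)
      }
    }
    .newMaskedPanel(cm, maskedIdx,
                    scenario = list(kind = "gbs", missingRate = missingRate,
                                    replicate = as.integer(replicate),
                                    seed = seed))
  })
}
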
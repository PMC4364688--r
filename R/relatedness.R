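# Coerce panel-like inputs to a numeric 0/1 matrix of allele calls.
# Continuous dosages are rounded at 0.5: Rogers' distance is defined on
# per-individual allele frequencies, i.e. on calls for inbred lines.
.asCallMatrix <- function(x) {
  m <- if (is(x, "GenotypePanel")) calls(x)
    else if (is(x, "MaskedPanel")) calls(x)
    else if (is(x, "ImputedPanel")) dosages(x)
    else if (is.matrix(x)) x
    else stopf("cannot interpret %s as a genotype matrix", class(x)[1])
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  ifelse(is.na(m), NA_real_, as.numeric(m >= 0.5))
}

#' Rogers' distance matrix
#'
#' Rogers' distance between two individuals is the per-locus Euclidean
#' allele-frequency distance averaged over loci,
#' RD = (1/m) sum_i sqrt(0.5 * sum_j (p_ij - q_ij)^2); for fully inbred 0/1
#' lines each locus term is 1 when the calls differ and 0 when they agree,
#' so RD reduces to the proportion of differing loci -- which makes it
#' linearly related to the coefficient of co-ancestry for homozygous lines.
#' Continuous dosages are rounded at 0.5 before the distance is taken.
#'
#' @param x a \linkS4class{GenotypePanel}, \linkS4class{MaskedPanel},
#'   \linkS4class{ImputedPanel} or plain matrix (lines x markers).
#' @param markerSubset optional marker ids restricting the computation.
#' @param pairwiseComplete when TRUE, loci missing in either line of a pair
#'   are dropped for that pair and the per-pair locus count is used (the
#'   treatment required for non-imputed GBS-like data).
#' @return a symmetric distance matrix in [0, 1] with zero diagonal; the
#'   attribute \code{nLoci} holds the per-pair evaluated-locus counts.
#' @examples
#' m <- rbind(a = c(0, 0, 1, 1), b = c(0, 1, 1, 0), c = c(0, 0, 1, 1))
#' colnames(m) <- paste0("M", 1:4)
#' rogersDistance(m)
#' @export
rogersDistance <- function(x, markerSubset = NULL, pairwiseComplete = FALSE) {
  m <- .asCallMatrix(x)
  if (!is.null(markerSubset)) {
    if (!all(markerSubset %in% colnames(m)))
      stopf("markerSubset contains unknown markers")
    m <- m[, markerSubset, drop = FALSE]
  }
  if (anyNA(m) && !pairwiseComplete)
    stopf("missing calls present; use pairwiseComplete = TRUE")
  a0 <- (m == 0); a0[is.na(a0)] <- FALSE
  a1 <- (m == 1); a1[is.na(a1)] <- FALSE
  storage.mode(a0) <- "numeric"; storage.mode(a1) <- "numeric"
  mism <- tcrossprod(a0, a1)
  mism <- mism + t(mism)
  obs <- (!is.na(m)) * 1
  shared <- tcrossprod(obs)
  off <- shared == 0 & row(shared) != col(shared)
  if (any(off)) {
    bad <- which(off, arr.ind = TRUE)[1, ]
    stopf("lines %s and %s share no evaluated locus",
          rownames(m)[bad[1]], rownames(m)[bad[2]])
  }
  rd <- mism / pmax(shared, 1)
  diag(rd) <- 0
  dimnames(rd) <- list(rownames(m), rownames(m))
  attr(rd, "nLoci") <- shared
  rd
}

#' Pearson correlation between two distance matrices
#'
#' Correlation over the strict upper triangles of two distance matrices on
#' the same lines in the same order -- the benchmark statistic used to ask
#' how well a distance landscape estimated from imputed (or reduced) data
#' reproduces the landscape from the full data.
#'
#' @param A,B symmetric matrices with identical dimnames.
#' @return Pearson correlation of the upper-triangle entries.
#' @export
matrixCorrelation <- function(A, B) {
  if (!identical(dim(A), dim(B)) ||
      !identical(rownames(A), rownames(B)))
    stopf("matrices must share dimensions and line ids")
  ut <- upper.tri(A)
  stats::cor(A[ut], B[ut])
}

#' Mantel permutation test for distance-matrix correlation
#'
#' One-sided (greater) permutation test: line labels of B are permuted
#' (simultaneous row/column permutation), the upper-triangle correlation is
#' recomputed, and p = (#\{perm cor >= observed\} + 1)/(nPerm + 1).
#'
#' @param A,B distance matrices as in \code{\link{matrixCorrelation}}.
#' @param nPerm number of permutations (default 999, minimum 99).
#' @param seed integer seed.
#' @return a list with \code{observed}, \code{nPerm}, \code{p}.
#' @export
mantelTest <- function(A, B, nPerm = 999L, seed = NULL) {
  if (nPerm < 99L) stopf("use at least 99 permutations")
  obs <- matrixCorrelation(A, B)
  n <- nrow(B)
  withSeed(seed, {
    hits <- 0L
    for (k in seq_len(nPerm)) {
      p <- sample.int(n)
      bp <- B[p, p, drop = FALSE]
      dimnames(bp) <- dimnames(B)
      if (matrixCorrelation(A, bp) >= obs) hits <- hits + 1L
    }
    list(observed = obs, nPerm = as.integer(nPerm),
         p = (hits + 1) / (nPerm + 1))
  })
}

#' Benchmark Rogers' distance landscapes across imputed data sets
#'
#' Low-to-high scenario: on the test lines and imputation-target markers,
#' the correlation between each imputed distance matrix and the truth, with
#' the low-density-array versus full-array correlation as the printed
#' benchmark analogue. GBS scenario: over all lines, the correlation of the
#' pairwise-complete non-imputed distance matrix and of each imputed matrix
#' against the truth.
#'
#' @param panel the complete \linkS4class{GenotypePanel} (truth).
#' @param design the \linkS4class{ArrayDesign} (low-to-high only; may be
#'   NULL for GBS).
#' @param masked the \linkS4class{MaskedPanel} of the scenario.
#' @param imputedSets named list of \linkS4class{ImputedPanel} objects.
#' @return a data.frame with columns \code{dataset} and \code{cor}.
#' @export
rdBenchmark <- function(panel, design, masked, imputedSets) {
  kind <- scenario(masked)$kind
  if (identical(kind, "low2high")) {
    tl <- testLines(masked)
    tgt <- intersect(imputeSet(design), markerIds(panel))
    truthRd <- rogersDistance(calls(panel)[tl, tgt, drop = FALSE])
    bench <- matrixCorrelation(
      rogersDistance(calls(panel)[tl, lowSet(design), drop = FALSE]),
      rogersDistance(calls(panel)[tl, highSet(design), drop = FALSE]))
    rows <- data.frame(dataset = "low-density benchmark", cor = bench,
                       stringsAsFactors = FALSE)
    for (nm in names(imputedSets)) {
      rd <- rogersDistance(
        dosages(imputedSets[[nm]])[tl, tgt, drop = FALSE])
      rows <- rbind(rows, data.frame(dataset = nm,
                                     cor = matrixCorrelation(truthRd, rd)))
    }
  } else {
    truthRd <- rogersDistance(calls(panel))
    nonImp <- rogersDistance(calls(masked), pairwiseComplete = TRUE)
    rows <- data.frame(dataset = "non-imputed pairwise-complete",
                       cor = matrixCorrelation(truthRd, nonImp),
                       stringsAsFactors = FALSE)
    for (nm in names(imputedSets)) {
      rd <- rogersDistance(dosages(imputedSets[[nm]]))
      rows <- rbind(rows, data.frame(dataset = nm,
                                     cor = matrixCorrelation(truthRd, rd)))
    }
  }
  rows
}
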
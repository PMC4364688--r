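#' Pairwise linkage disequilibrium r-squared between two loci
#'
#' Squared-correlation LD for fully inbred (phased haploid-equivalent)
#' lines: haplotype frequencies are counted directly and
#' r2 = D^2 / (p(A) p(a) p(B) p(b)) with D = p(AB) - p(A) p(B). Lines
#' missing at either locus are dropped pairwise.
#'
#' @param x,y 0/1 allele vectors over the same lines (NA allowed).
#' @return r-squared in [0, 1], or NA when either locus is monomorphic
#'   after pairwise deletion.
#' @examples
#' pairwiseR2(c(1,1,1,1,1,0,0,0,0,0), c(1,1,1,0,0,0,0,0,0,0))  # 0.4286
#' @export
pairwiseR2 <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors must align")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!length(x)) return(NA_real_)
  pA <- mean(x); pB <- mean(y)
  if (pA == 0 || pA == 1 || pB == 0 || pB == 1) return(NA_real_)
  pAB <- mean(x == 1 & y == 1)
  D <- pAB - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Per-marker imputation accuracy
#'
#' For every marker with masked cells, the Pearson correlation between the
#' pre-masking truth and the imputed dosages over that marker's masked cells
#' (originally missing cells are never evaluated). Markers whose truth or
#' dosage is constant over the masked cells get NA accuracy; summary means
#' are taken over defined records with the undefined count reported.
#'
#' @param masked the \linkS4class{MaskedPanel} that was imputed.
#' @param imputed the matching \linkS4class{ImputedPanel}.
#' @return a data.frame with one row per marker that has masked cells:
#'   \code{markerId}, \code{cor}, \code{nEval}, \code{maf} (MAF of the truth
#'   over masked cells). The attribute \code{summary} holds the mean over
#'   defined correlations and the undefined count.
#' @export
perMarkerAccuracy <- function(masked, imputed) {
  mk <- maskStates(masked)
  tr <- truthCalls(masked)
  ds <- dosages(imputed)[rownames(mk), colnames(mk), drop = FALSE]
  evalCols <- which(colSums(mk == MASK_MASKED) > 0L)
  rec <- data.frame(markerId = colnames(mk)[evalCols],
                    cor = NA_real_, nEval = 0L, maf = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_along(evalCols)) {
    j <- evalCols[r]
    rows <- mk[, j] == MASK_MASKED
    tv <- tr[rows, j]
    dv <- ds[rows, j]
    rec$nEval[r] <- length(tv)
    p <- mean(tv)
    rec$maf[r] <- min(p, 1 - p)
    if (isTRUE(stats::sd(tv) > 0) && isTRUE(stats::sd(dv) > 0))
      rec$cor[r] <- stats::cor(tv, dv)
  }
  attr(rec, "summary") <- list(
    meanCor = mean(rec$cor, na.rm = TRUE),
    nUndefined = sum(is.na(rec$cor)),
    nMarkers = nrow(rec))
  rec
}

#' Maximum LD between an imputed marker and the typed low-density markers
#'
#' Maximum pairwise r-squared between a target marker (its truth values)
#' and every low-density-array marker within a window of +/- windowCM
#' centimorgans on the same chromosome. This is the LD covariate against
#' which imputation accuracy is stratified: accuracy rises non-linearly
#' with the LD to the closest typed marker.
#'
#' @param markerId a marker in the design's imputeSet.
#' @param masked the \linkS4class{MaskedPanel} (its truth plus observed
#'   calls provide the allele vectors).
#' @param design the \linkS4class{ArrayDesign}.
#' @param map the \linkS4class{GeneticMap}.
#' @param windowCM search window half-width in cM (default 5).
#' @return maximum r-squared, or NA when no evaluable typed marker lies in
#'   the window.
#' @export
maxLdToTyped <- function(markerId, masked, design, map, windowCM = 5) {
  if (!(markerId %in% imputeSet(design)))
    stopf("%s is not an imputation target", markerId)
  i <- match(markerId, markerIds(map))
  sameChr <- chromosomes(map) == chromosomes(map)[i]
  inWin <- abs(positions(map) - positions(map)[i]) <= windowCM
  cand <- markerIds(map)[sameChr & inWin]
  cand <- intersect(cand, lowSet(design))
  if (!length(cand)) return(NA_real_)
  x <- .fullColumn(masked, markerId)
  r2 <- vapply(cand, function(cid)
    pairwiseR2(x, .fullColumn(masked, cid)), numeric(1))
  if (all(is.na(r2))) return(NA_real_)
  max(r2, na.rm = TRUE)
}

# Reconstruct a marker's full allele vector: observed calls where present,
# truth where masked, NA where originally missing.
.fullColumn <- function(masked, markerId) {
  v <- as.numeric(calls(masked)[, markerId])
  mk <- maskStates(masked)[, markerId]
  tr <- truthCalls(masked)[, markerId]
  v[mk == MASK_MASKED] <- tr[mk == MASK_MASKED]
  v
}

#' Stratify imputation accuracy by LD and MAF
#'
#' Cross-tabulates per-marker accuracies into LD bins x MAF classes and
#' reports per-cell mean, SD, coefficient of variation and marker count --
#' the structure behind accuracy-versus-LD displays (per MAF class) and the
#' transposed accuracy-versus-MAF view (per LD class).
#'
#' @param records data.frame from \code{\link{perMarkerAccuracy}} with an
#'   additional \code{maxLd} column.
#' @param ldBreaks LD bin edges (default \code{c(0, .25, .5, .75, 1)}).
#' @param mafBreaks MAF class edges (default \code{c(0, .05, .2, .5)}).
#' @return a data.frame with one row per (ldBin, mafClass) cell:
#'   \code{meanCor}, \code{sdCor}, \code{cv}, \code{n}.
#' @export
stratifyAccuracy <- function(records,
                             ldBreaks = c(0, 0.25, 0.5, 0.75, 1),
                             mafBreaks = c(0, 0.05, 0.2, 0.5)) {
  if (is.unsorted(ldBreaks, strictly = TRUE) ||
      is.unsorted(mafBreaks, strictly = TRUE))
    stopf("bin edges must be strictly increasing")
  if (!"maxLd" %in% names(records))
    stopf("records need a maxLd column (see maxLdToTyped)")
  ldBin <- cut(records$maxLd, ldBreaks, include.lowest = TRUE)
  mafClass <- cut(records$maf, mafBreaks, include.lowest = TRUE)
  grid <- expand.grid(ldBin = levels(ldBin), mafClass = levels(mafClass),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(g) {
    sel <- !is.na(ldBin) & !is.na(mafClass) &
      ldBin == grid$ldBin[g] & mafClass == grid$mafClass[g] &
      !is.na(records$cor)
    cc <- records$cor[sel]
    data.frame(ldBin = grid$ldBin[g], mafClass = grid$mafClass[g],
               meanCor = if (length(cc)) mean(cc) else NA_real_,
               sdCor = if (length(cc) > 1) stats::sd(cc) else NA_real_,
               cv = if (length(cc) > 1 && mean(cc) != 0)
                 stats::sd(cc) / mean(cc) else NA_real_,
               n = length(cc), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
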
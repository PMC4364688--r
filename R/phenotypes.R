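#' Simulate a polygenic phenotype with equal per-marker contributions
#'
#' Additive architecture mimicking a complex trait: every segregating
#' marker contributes equally (1/m) to the genetic variance. Effects are
#' beta_i = s_i * sqrt(sigmaG2 / (m v_i)) with random sign s_i and v_i the
#' sample variance of marker i (monomorphic markers get zero effect and do
#' not count towards m); the genetic value g = X beta is centered and
#' rescaled so its sample variance equals sigmaG2 exactly -- inter-marker
#' LD would otherwise inflate it -- and y = g + e with
#' e ~ N(0, sigmaG2 (1 - h2)/h2), so the expected realized heritability
#' var(g)/var(y) matches the target h2.
#'
#' @param panel a complete \linkS4class{GenotypePanel}.
#' @param h2 target heritability (default 0.91).
#' @param sigmaG genetic variance (default 1).
#' @param seed integer seed.
#' @return a \linkS4class{PhenotypeSim}.
#' @export
simulatePolygenicPhenotype <- function(panel, h2 = 0.91, sigmaG = 1,
                                       seed = NULL) {
  X <- calls(panel)
  if (anyNA(X)) stopf("phenotype simulation requires a complete panel")
  if (h2 <= 0 || h2 >= 1) stopf("h2 must lie in (0, 1)")
  X <- matrix(as.numeric(X), nrow(X), ncol(X), dimnames = dimnames(X))
  v <- apply(X, 2, stats::var)
  seg <- v > 0
  m <- sum(seg)
  if (m < 2) stopf("need at least two segregating markers")
  withSeed(seed, {
    beta <- numeric(ncol(X))
    beta[seg] <- sample(c(-1, 1), m, replace = TRUE) *
      sqrt(sigmaG / (m * v[seg]))
    g <- drop(X %*% beta)
    g <- g - mean(g)
    tau <- sqrt(sigmaG / stats::var(g))
    g <- g * tau
    beta <- beta * tau
    sigmaE <- sigmaG * (1 - h2) / h2
    e <- stats::rnorm(length(g), 0, sqrt(sigmaE))
    names(beta) <- colnames(X)
    y <- g + e
    names(y) <- names(g) <- rownames(X)
    new("PhenotypeSim", y = y, gTrue = g, beta = beta,
        qtlMarker = character(0), h2 = h2, qtlVarFraction = 0,
        sigmaG = sigmaG, sigmaE = sigmaE,
        seed = as.integer(seed %||% NA_integer_))
  })
}

# Max r2 between a candidate marker column and the low-density markers
# within +/- windowCM on its chromosome, from a complete panel.
.maxLdToLowSet <- function(X, map, design, markerId, windowCM = 5) {
  i <- match(markerId, markerIds(map))
  inWin <- chromosomes(map) == chromosomes(map)[i] &
    abs(positions(map) - positions(map)[i]) <= windowCM
  cand <- intersect(markerIds(map)[inWin], lowSet(design))
  if (!length(cand)) return(NA_real_)
  r2 <- vapply(cand, function(cid)
    pairwiseR2(X[, markerId], X[, cid]), numeric(1))
  if (all(is.na(r2))) return(NA_real_)
  max(r2, na.rm = TRUE)
}

#' Simulate a phenotype with one focal QTL plus polygenic background
#'
#' One QTL carries \code{qtlVarFraction} (default 10%) of the genetic
#' variance; all other segregating markers share the remainder equally as
#' in \code{\link{simulatePolygenicPhenotype}}. The QTL marker is drawn
#' uniformly among candidates with MAF above \code{mafMin} (default 0.3)
#' and, when \code{targetLd} is given, with maximum LD to the low-density
#' array within \code{ldTol} of the target -- the device used to study how
#' detection power depends on the LD between the causal marker and the
#' typed markers. The total genetic value is rescaled to sigmaG2 exactly;
#' because QTL and background are computed on the same panel their sample
#' covariance makes the realized QTL share fluctuate around the nominal
#' fraction.
#'
#' @param panel a complete \linkS4class{GenotypePanel}.
#' @param design \linkS4class{ArrayDesign}; required with \code{targetLd}
#'   (QTL candidates are then restricted to the imputeSet).
#' @param targetLd target max-LD class of the QTL (e.g. 0.1, 0.5, 0.9), or
#'   NULL for no LD constraint.
#' @param h2 target heritability (default 0.91).
#' @param qtlVarFraction fraction of genetic variance at the QTL (default
#'   0.10).
#' @param map \linkS4class{GeneticMap}; required with \code{targetLd}.
#' @param mafMin minimum QTL minor allele frequency (default 0.3).
#' @param ldTol tolerance around \code{targetLd} (default 0.05).
#' @param sigmaG genetic variance (default 1).
#' @param seed integer seed.
#' @return a \linkS4class{PhenotypeSim} with \code{qtlMarker} set.
#' @export
simulateQtlPhenotype <- function(panel, design = NULL, targetLd = NULL,
                                 h2 = 0.91, qtlVarFraction = 0.10,
                                 map = NULL, mafMin = 0.3, ldTol = 0.05,
                                 sigmaG = 1, seed = NULL) {
  X <- calls(panel)
  if (anyNA(X)) stopf("phenotype simulation requires a complete panel")
  X <- matrix(as.numeric(X), nrow(X), ncol(X), dimnames = dimnames(X))
  v <- apply(X, 2, stats::var)
  maf <- colMaf(X)
  elig <- colnames(X)[maf > mafMin]
  if (!is.null(targetLd)) {
    if (is.null(design) || is.null(map))
      stopf("targetLd selection needs design and map")
    elig <- intersect(elig, imputeSet(design))
    ld <- vapply(elig, function(id)
      .maxLdToLowSet(X, map, design, id), numeric(1))
    keep <- !is.na(ld) & abs(ld - targetLd) <= ldTol
    if (!any(keep))
      stopf("no QTL candidate near LD %.2f; available LD values: %s",
            targetLd, paste(round(sort(unique(round(ld, 2))), 2),
                            collapse = ", "))
    elig <- elig[keep]
  }
  if (!length(elig))
    stopf("no QTL candidate with MAF > %.2f", mafMin)

  withSeed(seed, {
    qtl <- if (length(elig) == 1L) elig else sample(elig, 1L)
    beta <- numeric(ncol(X))
    names(beta) <- colnames(X)
    beta[qtl] <- sample(c(-1, 1), 1L) * sqrt(qtlVarFraction * sigmaG / v[qtl])
    bg <- setdiff(colnames(X)[v > 0], qtl)
    m <- length(bg)
    if (m < 1 && qtlVarFraction < 1)
      stopf("no segregating background markers")
    if (qtlVarFraction < 1)
      beta[bg] <- sample(c(-1, 1), m, replace = TRUE) *
        sqrt((1 - qtlVarFraction) * sigmaG / (m * v[bg]))
    g <- drop(X %*% beta)
    g <- g - mean(g)
    tau <- sqrt(sigmaG / stats::var(g))
    g <- g * tau
    beta <- beta * tau
    sigmaE <- sigmaG * (1 - h2) / h2
    y <- g + stats::rnorm(length(g), 0, sqrt(sigmaE))
    names(y) <- names(g) <- rownames(X)
    new("PhenotypeSim", y = y, gTrue = g, beta = beta,
        qtlMarker = qtl, h2 = h2, qtlVarFraction = qtlVarFraction,
        sigmaG = sigmaG, sigmaE = sigmaE,
        seed = as.integer(seed %||% NA_integer_))
  })
}

#' Realized variance decomposition of a simulated phenotype
#'
#' Sample heritability var(g)/var(y) and, for QTL architectures, the
#' realized fraction of genetic variance carried by the focal QTL
#' (variance of the QTL component over variance of the total genetic
#' value, both on the panel the phenotype was simulated on).
#'
#' @param sim a \linkS4class{PhenotypeSim}.
#' @param panel the panel it was simulated on.
#' @return a list with \code{realizedH2} and \code{realizedQtlFraction}
#'   (NA for polygenic simulations).
#' @export
realizedComponents <- function(sim, panel) {
  h2real <- stats::var(sim@gTrue) / stats::var(sim@y)
  qfrac <- NA_real_
  if (length(sim@qtlMarker)) {
    x <- as.numeric(calls(panel)[, sim@qtlMarker])
    qcomp <- x * sim@beta[sim@qtlMarker]
    qfrac <- stats::var(qcomp) / stats::var(sim@gTrue)
  }
  list(realizedH2 = h2real, realizedQtlFraction = qfrac)
}
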
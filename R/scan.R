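#' Kinship-corrected mixed-model association scan
#'
#' Single-marker scan of y = mu + alpha m + g + e with a polygenic random
#' effect g ~ N(0, 2 K sigmaG2), where K is a kinship matrix (in this
#' package 1 minus the Rogers' distance matrix). The variance ratio is
#' estimated once by REML under the null model (no marker) via the spectral
#' decomposition of 2K and reused for every marker -- the standard
#' population-parameters-previously-determined approximation -- and each
#' marker's fixed effect is tested by the Wald-F statistic
#' alpha_hat^2 / var(alpha_hat) against F(1, n - 2). Monomorphic markers
#' are skipped and recorded.
#'
#' @param genotypes numeric lines x markers matrix (calls or dosages).
#' @param y named phenotype vector aligned to the rows.
#' @param kinship kinship matrix K (the scan uses 2K); typically
#'   \code{1 - rogersDistance(panel)}.
#' @param eig optional pre-computed \code{eigen(2 * kinship)} to reuse
#'   across repeated scans on the same panel.
#' @return a data.frame with one row per marker: \code{markerId},
#'   \code{alpha}, \code{F}, \code{p} (NA for skipped markers); variance
#'   components in the \code{varcomp} attribute.
#' @export
mixedModelScan <- function(genotypes, y, kinship, eig = NULL) {
  M <- matrix(as.numeric(genotypes), nrow(genotypes), ncol(genotypes),
              dimnames = dimnames(genotypes))
  n <- length(y)
  if (nrow(M) != n) stopf("genotypes and y must align")
  if (!is.null(names(y)) && !is.null(rownames(M)) &&
      !identical(names(y), rownames(M)))
    M <- M[names(y), , drop = FALSE]
  K2 <- 2 * kinship
  if (is.null(eig)) eig <- eigen(K2, symmetric = TRUE)
  d <- pmax(eig$values, 0)
  U <- eig$vectors

  ytil <- drop(crossprod(U, y))
  onetil <- drop(crossprod(U, rep(1, n)))
  opt <- stats::optimize(.remlProfile, c(-12, 12), ytil = ytil,
                         Xtil = matrix(onetil, n, 1), d = d, n = n, q = 1,
                         maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  w <- 1 / (d + delta)

  Mtil <- crossprod(U, M)
  a11 <- sum(w * onetil^2)
  a12 <- drop(crossprod(Mtil * w, onetil))
  a22 <- colSums(w * Mtil^2)
  b1 <- sum(w * onetil * ytil)
  b2 <- colSums(w * Mtil * ytil)
  det <- a11 * a22 - a12^2

  mono <- apply(M, 2, function(col) stats::var(col) == 0)
  alpha <- (a11 * b2 - a12 * b1) / det
  muhat <- (a22 * b1 - a12 * b2) / det
  yw2 <- sum(w * ytil^2)
  rss <- yw2 - (muhat * b1 + alpha * b2)
  sigma2 <- rss / (n - 2)
  varAlpha <- sigma2 * a11 / det
  Fstat <- alpha^2 / varAlpha
  p <- stats::pf(Fstat, 1, n - 2, lower.tail = FALSE)
  alpha[mono] <- Fstat[mono] <- p[mono] <- NA_real_

  out <- data.frame(markerId = colnames(M), alpha = alpha, F = Fstat, p = p,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  # variance components under the null, PPD-style
  XtWX <- a11
  beta0 <- b1 / a11
  sg <- sum(w * (ytil - onetil * beta0)^2) / (n - 1)
  attr(out, "varcomp") <- list(delta = delta, sigmaG2 = sg,
                               sigmaE2 = sg * delta,
                               nSkipped = sum(mono))
  out
}

#' QTL detection frequency over repeated association-mapping runs
#'
#' Power estimate for the mixed-model scan: phenotypes with one focal QTL
#' are simulated repeatedly, each run is scanned, and the fraction of runs
#' in which the tracked marker -- the QTL's perfect marker when it is in
#' the scanned set, otherwise a caller-chosen proxy such as the most
#' closely linked typed marker -- reaches significance under the alpha
#' policy is returned.
#'
#' @param panel complete \linkS4class{GenotypePanel} the phenotypes are
#'   simulated on.
#' @param kinship kinship matrix for the scan (1 - Rogers' distance).
#' @param nRuns number of simulation runs (default 100).
#' @param scanGenotypes matrix scanned per run (default the panel's calls;
#'   pass imputed dosages or a typed-marker subset to probe other designs).
#' @param h2,qtlVarFraction,mafMin,sigmaG passed to
#'   \code{\link{simulateQtlPhenotype}}.
#' @param design,map,targetLd,ldTol optional LD-targeted QTL selection,
#'   passed through.
#' @param alpha significance level before correction (default 0.05).
#' @param alphaPolicy \code{"bonferroni"} (alpha / markers tested, the
#'   default) or \code{"nominal"}.
#' @param proxyMarker optional function(sim) returning the marker id to
#'   track when the QTL itself is absent from \code{scanGenotypes}.
#' @param seed integer base seed; run r uses \code{stableSeed(seed, r)}.
#' @return a list with \code{frequency}, \code{nRuns}, and the per-run
#'   data.frame \code{runs} (qtl, tracked marker, p, significant).
#' @export
detectionFrequency <- function(panel, kinship, nRuns = 100L,
                               scanGenotypes = NULL,
                               h2 = 0.91, qtlVarFraction = 0.10,
                               mafMin = 0.3, sigmaG = 1,
                               design = NULL, map = NULL, targetLd = NULL,
                               ldTol = 0.05,
                               alpha = 0.05,
                               alphaPolicy = c("bonferroni", "nominal"),
                               proxyMarker = NULL, seed = NULL) {
  alphaPolicy <- match.arg(alphaPolicy)
  if (nRuns < 1L) stopf("need at least one run")
  if (is.null(scanGenotypes)) scanGenotypes <- calls(panel)
  eig <- eigen(2 * kinship, symmetric = TRUE)
  mTested <- ncol(scanGenotypes)
  thr <- if (alphaPolicy == "bonferroni") alpha / mTested else alpha
  runs <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    sim <- simulateQtlPhenotype(panel, design = design, targetLd = targetLd,
                                h2 = h2, qtlVarFraction = qtlVarFraction,
                                map = map, mafMin = mafMin, ldTol = ldTol,
                                sigmaG = sigmaG,
                                seed = stableSeed(seed %||% 0L, "qtlrun", r))
    tracked <- sim@qtlMarker
    if (!(tracked %in% colnames(scanGenotypes))) {
      if (is.null(proxyMarker))
        stopf("QTL %s not in the scanned set and no proxyMarker given",
              tracked)
      tracked <- proxyMarker(sim)
    }
    sc <- mixedModelScan(scanGenotypes, sim@y, kinship, eig = eig)
    pq <- sc$p[match(tracked, sc$markerId)]
    runs[[r]] <- data.frame(qtl = sim@qtlMarker, tracked = tracked,
                            p = pq, significant = !is.na(pq) && pq < thr,
                            stringsAsFactors = FALSE)
  }
  runs <- do.call(rbind, runs)
  list(frequency = mean(runs$significant), nRuns = as.integer(nRuns),
       threshold = thr, runs = runs)
}
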
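#' Parameters for the iterative Random Forest imputer
#'
#' @param nTrees regression trees per marker (default 100).
#' @param maxIter maximum number of refinement iterations (default 10).
#' @param convergenceTol stop when the sum of squared dosage changes over
#'   imputed cells falls below this value (default 1e-6); iteration also
#'   stops early when that sum starts to increase, in which case the
#'   previous iteration's dosages are kept.
#' @param seed integer seed controlling the stochastic initialization and
#'   the per-tree bootstrap/feature sampling.
#' @return a list of class \code{rfParams}.
#' @export
rfParams <- function(nTrees = 100L, maxIter = 10L, convergenceTol = 1e-6,
                     seed = NULL) {
  if (nTrees < 1L || maxIter < 1L) stopf("nTrees and maxIter must be >= 1")
  structure(list(nTrees = as.integer(nTrees), maxIter = as.integer(maxIter),
                 convergenceTol = convergenceTol, seed = seed),
            class = "rfParams")
}

#' Iterative Random Forest imputation
#'
#' Map-independent imputation by iterated Random Forest regression: markers
#' are processed in ascending order of missingness; missing cells are
#' initialized by Bernoulli draws at the observed allele frequency; then,
#' per iteration and per marker with missing values, an ensemble of
#' \code{nTrees} regression trees is grown on the lines observed at that
#' marker, using all other markers' current (observed or imputed) values as
#' predictors with sqrt(nMarkers - 1) candidates per split, and the
#' ensemble-mean prediction replaces the missing cells. Iteration stops at
#' convergence (sum of squared dosage changes below tolerance), when that
#' sum starts to increase (the previous iteration's values are kept), or
#' after \code{maxIter} rounds. Dosages are clipped to [0, 1].
#'
#' Markers whose tree ensemble cannot be grown fall back to the
#' allele-frequency baseline with a warning.
#'
#' @param masked a \linkS4class{MaskedPanel}.
#' @param params an \code{\link{rfParams}} object.
#' @return an \linkS4class{ImputedPanel}.
#' @export
imputeRandomForest <- function(masked, params = rfParams()) {
  stopifnot(inherits(params, "rfParams"))
  cm <- calls(masked)
  n <- nrow(cm); p <- ncol(cm)
  missIdx <- which(is.na(cm))
  X <- matrix(as.numeric(cm), n, p, dimnames = dimnames(cm))
  if (!length(missIdx))
    return(new("ImputedPanel", dosages = X, imputer = "rf",
               params = unclass(params)[c("nTrees", "maxIter")]))

  freq <- colMeans(cm, na.rm = TRUE)
  if (anyNA(freq)) stopf("marker(s) with zero observed calls")
  withSeed(params$seed, {
    X[missIdx] <- stats::rbinom(length(missIdx), 1L,
                                freq[(missIdx - 1L) %/% n + 1L])
  })

  nMissPerMarker <- colSums(is.na(cm))
  order_j <- order(nMissPerMarker)
  jobs <- order_j[nMissPerMarker[order_j] > 0L]
  mtry <- max(1L, floor(sqrt(p - 1)))
  deltaPrev <- Inf

  for (iter in seq_len(params$maxIter)) {
    Xprev <- X
    for (j in jobs) {
      obsRows <- which(!is.na(cm[, j]))
      missRows <- which(is.na(cm[, j]))
      fit <- tryCatch(
        ranger::ranger(x = X[obsRows, -j, drop = FALSE],
                       y = X[obsRows, j],
                       num.trees = params$nTrees,
                       mtry = min(mtry, p - 1L),
                       num.threads = 1L,
                       seed = stableSeed(params$seed %||% 0L, "rf", iter, j)),
        error = function(e) NULL)
      if (is.null(fit)) {
        warning(sprintf("marker %s: tree ensemble failed, frequency fallback",
                        colnames(cm)[j]))
        X[missRows, j] <- freq[j]
        next
      }
      X[missRows, j] <- stats::predict(
        fit, data = X[missRows, -j, drop = FALSE],
        num.threads = 1L)$predictions
    }
    delta <- sum((X[missIdx] - Xprev[missIdx])^2)
    if (delta > deltaPrev) { X <- Xprev; break }
    if (delta < params$convergenceTol) break
    deltaPrev <- delta
  }

  X[X < 0] <- 0; X[X > 1] <- 1
  X[!is.na(cm)] <- as.numeric(cm[!is.na(cm)])
  new("ImputedPanel", dosages = X, imputer = "rf",
      params = unclass(params)[c("nTrees", "maxIter")])
}
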
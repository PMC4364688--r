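#' Genomic relationship matrix
#'
#' VanRaden-type GRM: G = W W' / c with W the column-centered marker matrix
#' and c the sum of marker sample variances, so the diagonal averages about
#' one. With \code{pairwiseComplete}, each entry is computed over the
#' markers observed in both lines and normalized by that pair's variance
#' sum -- the treatment for randomly depleted (GBS-like) data used without
#' imputation.
#'
#' @param x a \linkS4class{GenotypePanel}, \linkS4class{MaskedPanel},
#'   \linkS4class{ImputedPanel} or numeric matrix (lines x markers;
#'   continuous dosages allowed).
#' @param pairwiseComplete drop, per pair, markers missing in either line.
#' @return a symmetric relationship matrix.
#' @export
buildGrm <- function(x, pairwiseComplete = FALSE) {
  m <- if (is(x, "GenotypePanel")) calls(x)
    else if (is(x, "MaskedPanel")) calls(x)
    else if (is(x, "ImputedPanel")) dosages(x)
    else x
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  if (anyNA(m) && !pairwiseComplete)
    stopf("missing calls present; use pairwiseComplete = TRUE")
  mu <- colMeans(m, na.rm = TRUE)
  v <- apply(m, 2, stats::var, na.rm = TRUE)
  W <- sweep(m, 2, mu)
  if (!anyNA(m)) return(tcrossprod(W) / sum(v))
  W0 <- W; W0[is.na(W0)] <- 0
  num <- tcrossprod(W0)
  obs <- (!is.na(m)) * 1
  den <- obs %*% (t(obs) * v)
  if (any(den == 0))
    stopf("line pair(s) share no observed marker")
  num / den
}

#' Ridge-regression BLUP (RR-BLUP) genomic prediction
#'
#' Fits y = mu + W u + e on the training lines with a common ridge penalty
#' on all marker effects; the shrinkage is derived from the REML-estimated
#' variance ratio on the marker-based relationship W W'/c, which makes
#' RR-BLUP numerically equivalent to GBLUP with G = W W'/c on the same data
#' and coding. The marker coding (training column means, variance sum c) is
#' recorded in the model and reused at prediction time.
#'
#' @param yTrain named numeric phenotype vector (training lines).
#' @param markersTrain numeric marker matrix for the training lines.
#' @return an object of class \code{rrblupModel} with marker effects
#'   \code{u}, intercept \code{mu}, the coding record, and the REML
#'   variance components.
#' @export
fitRrblup <- function(yTrain, markersTrain) {
  if (length(yTrain) < 10) stopf("need at least 10 training lines")
  M <- matrix(as.numeric(markersTrain), nrow(markersTrain),
              ncol(markersTrain), dimnames = dimnames(markersTrain))
  if (anyNA(M)) stopf("RR-BLUP needs complete (or imputed) marker data")
  center <- colMeans(M)
  v <- apply(M, 2, stats::var)
  cc <- sum(v)
  W <- sweep(M, 2, center)
  G <- tcrossprod(W) / cc
  fit <- remlFit(yTrain, G)
  mu <- fit$beta[1]
  # u = W' (W W' + c*delta I)^-1 (y - mu): ridge solution in marker space
  n <- length(yTrain)
  sol <- solve(tcrossprod(W) + diag(cc * fit$delta, n), yTrain - mu)
  u <- drop(crossprod(W, sol))
  structure(list(u = u, mu = mu, center = center, c = cc,
                 delta = fit$delta, sigmaG2 = fit$sigmaG2,
                 sigmaE2 = fit$sigmaE2),
            class = "rrblupModel")
}

#' @rdname fitRrblup
#' @param model a fitted \code{rrblupModel}.
#' @param markers marker matrix for the lines to predict (same markers and
#'   coding as in training).
#' @param gTrue optional named true genotypic values; when given, the
#'   prediction accuracy (Pearson correlation) is attached.
#' @return \code{predictRrblup}: a list with \code{predictions} (named),
#'   \code{accuracy} (NA without \code{gTrue}) and \code{model = "RRBLUP"}.
#' @export
predictRrblup <- function(model, markers, gTrue = NULL) {
  M <- matrix(as.numeric(markers), nrow(markers), ncol(markers),
              dimnames = dimnames(markers))
  W <- sweep(M, 2, model$center)
  pred <- drop(model$mu + W %*% model$u)
  names(pred) <- rownames(markers)
  acc <- if (!is.null(gTrue))
    stats::cor(pred, gTrue[names(pred)]) else NA_real_
  list(predictions = pred, accuracy = acc, model = "RRBLUP")
}

#' GBLUP genomic prediction from a relationship matrix
#'
#' Standard mixed-model BLUP of genotypic values: the variance ratio is
#' estimated by REML on the training block of the kinship, and genotypic
#' values of all lines in the kinship are predicted from the training
#' phenotypes via g_hat = K[, train] (K[train, train] + delta I)^-1
#' (y - mu). Accepts any positive semi-definite relationship matrix (a GRM,
#' possibly pairwise-complete, after a small diagonal jitter if needed).
#'
#' @param yTrain named numeric phenotypes; names must index rows of
#'   \code{kinship}.
#' @param kinship relationship matrix over all lines (training included).
#' @return an object of class \code{gblupModel}.
#' @export
fitGblup <- function(yTrain, kinship) {
  train <- names(yTrain)
  if (is.null(train) || !all(train %in% rownames(kinship)))
    stopf("yTrain must be named by lines present in the kinship")
  Ktt <- kinship[train, train]
  fit <- remlFit(yTrain, Ktt)
  structure(list(train = train, y = yTrain, mu = fit$beta[1],
                 delta = fit$delta, sigmaG2 = fit$sigmaG2,
                 sigmaE2 = fit$sigmaE2, kinship = fit$K),
            class = "gblupModel")
}

#' @rdname fitGblup
#' @param model a fitted \code{gblupModel}.
#' @param kinshipRows kinship rows for the lines to predict (columns must
#'   cover the training lines); typically the full kinship.
#' @param gTrue optional named true genotypic values for accuracy.
#' @return \code{predictGblup}: a list with \code{predictions},
#'   \code{accuracy} and \code{model = "GBLUP"}.
#' @export
predictGblup <- function(model, kinshipRows, gTrue = NULL) {
  train <- model$train
  Ktt <- model$kinship
  rhs <- solve(Ktt + diag(model$delta, length(train)),
               model$y - model$mu)
  pred <- drop(model$mu + kinshipRows[, train, drop = FALSE] %*% rhs)
  names(pred) <- rownames(kinshipRows)
  acc <- if (!is.null(gTrue))
    stats::cor(pred, gTrue[names(pred)]) else NA_real_
  list(predictions = pred, accuracy = acc, model = "GBLUP")
}
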
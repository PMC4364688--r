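# Single-variance-component REML by spectral decomposition.
#
# Model: y = X b + g + e, g ~ N(0, sigmaG2 * K), e ~ N(0, sigmaE2 * I).
# With K = U diag(d) U', the restricted likelihood is an explicit function
# of the variance ratio delta = sigmaE2 / sigmaG2, maximized by bounded
# scalar search on log(delta). Exact for one genetic variance component and
# reused by GBLUP, RR-BLUP and the association scan (which estimates delta
# once under the null and reuses it for every marker).

.remlProfile <- function(logDelta, ytil, Xtil, d, n, q) {
  delta <- exp(logDelta)
  w <- d + delta
  XtWX <- crossprod(Xtil, Xtil / w)
  XtWy <- crossprod(Xtil, ytil / w)
  beta <- solve(XtWX, XtWy)
  r <- ytil - Xtil %*% beta
  R <- sum(r^2 / w)
  nq <- n - q
  -0.5 * (nq * log(R) + sum(log(w)) + determinant(XtWX)$modulus[1]) -
    0.5 * nq * (1 + log(2 * pi / nq))
}

# Returns delta, variance components, fixed effects and the decomposition.
remlFit <- function(y, K, X = NULL, jitter = 1e-6) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  eg <- eigen(K, symmetric = TRUE)
  if (min(eg$values) < -1e-8) {
    # substantively indefinite (e.g. 1 - RD kinships): diagonal jitter
    K <- K + diag(jitter - min(eg$values), n)
    eg <- eigen(K, symmetric = TRUE)
    if (min(eg$values) < -1e-8)
      stopf("kinship is not positive semi-definite beyond jitter tolerance")
  }
  eg$values <- pmax(eg$values, 0)
  U <- eg$vectors
  d <- eg$values
  ytil <- crossprod(U, y)
  Xtil <- crossprod(U, X)
  q <- ncol(X)
  opt <- stats::optimize(.remlProfile, c(-12, 12), ytil = ytil, Xtil = Xtil,
                         d = d, n = n, q = q, maximum = TRUE, tol = 1e-8)
  delta <- exp(opt$maximum)
  w <- d + delta
  XtWX <- crossprod(Xtil, Xtil / w)
  beta <- solve(XtWX, crossprod(Xtil, ytil / w))
  r <- ytil - Xtil %*% beta
  sigmaG2 <- sum(r^2 / w) / (n - q)
  list(delta = delta, sigmaG2 = sigmaG2, sigmaE2 = sigmaG2 * delta,
       beta = drop(beta), U = U, d = d, K = K)
}
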
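#' Parameters for the Li-Stephens copying HMM imputer
#'
#' @param errorRate per-site copying error (emission mismatch) probability
#'   epsilon, in (0, 0.5).
#' @param switchIntensity per-cM intensity c of haplotype switches; across an
#'   inter-marker interval of d cM the chain stays on its reference with
#'   probability exp(-c d) plus the uniform share (1 - exp(-c d))/K.
#' @param minReferenceHaplotypes minimum number of eligible reference lines
#'   per chromosome (default 2).
#' @param seed unused by the deterministic forward-backward pass; kept for
#'   interface symmetry with the other imputers.
#' @return a list of class \code{hmmParams}.
#' @export
hmmParams <- function(errorRate = 0.01, switchIntensity = 0.02,
                      minReferenceHaplotypes = 2L, seed = NULL) {
  if (errorRate <= 0 || errorRate >= 0.5)
    stopf("errorRate must lie in (0, 0.5)")
  if (switchIntensity <= 0) stopf("switchIntensity must be positive")
  structure(list(errorRate = errorRate, switchIntensity = switchIntensity,
                 minReferenceHaplotypes = as.integer(minReferenceHaplotypes),
                 seed = seed),
            class = "hmmParams")
}

# Scaled forward-backward for one target line on one chromosome.
# H: K x M reference alleles; obs: length-M target with NA at missing sites;
# stay: length-(M-1) stay probabilities exp(-c d); eps: error rate.
# Returns posterior matrix gamma (K x M) plus forward/backward log-likelihoods.
.lsForwardBackward <- function(H, obs, stay, eps) {
  K <- nrow(H); M <- ncol(H)
  emis <- matrix(1, K, M)
  for (m in which(!is.na(obs)))
    emis[, m] <- ifelse(H[, m] == obs[m], 1 - eps, eps)

  alpha <- matrix(0, K, M)
  cvec <- numeric(M)
  a <- emis[, 1] / K
  cvec[1] <- sum(a)
  alpha[, 1] <- a / cvec[1]
  if (M > 1) for (m in 2:M) {
    s <- stay[m - 1]
    pred <- s * alpha[, m - 1] + (1 - s) / K   # sum(alpha[,m-1]) == 1
    a <- emis[, m] * pred
    cvec[m] <- sum(a)
    alpha[, m] <- a / cvec[m]
  }
  loglikF <- sum(log(cvec))

  beta <- matrix(0, K, M)
  beta[, M] <- 1
  if (M > 1) for (m in (M - 1):1) {
    s <- stay[m]
    v <- emis[, m + 1] * beta[, m + 1]
    beta[, m] <- (s * v + (1 - s) * sum(v) / K) / cvec[m + 1]
  }
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")

  # independently scaled backward pass for the likelihood cross-check
  bb <- rep(1, K)
  logd <- 0
  if (M > 1) for (m in (M - 1):1) {
    s <- stay[m]
    v <- emis[, m + 1] * bb
    bb <- s * v + (1 - s) * sum(v) / K
    d <- sum(bb)
    bb <- bb / d
    logd <- logd + log(d)
  }
  loglikB <- log(sum(emis[, 1] * bb / K)) + logd

  list(gamma = gamma, loglikF = loglikF, loglikB = loglikB)
}

#' Li-Stephens haploid copying HMM imputation
#'
#' Map-dependent imputation by a haploid Li-Stephens haplotype-copying
#' hidden Markov model, the core mechanism behind HMM-based population
#' imputation tools. Per chromosome, the hidden state is the index of the
#' reference haplotype being copied; transitions across an interval of d cM
#' keep the current reference with probability exp(-c d) + (1 - exp(-c d))/K
#' and move to each other reference with probability (1 - exp(-c d))/K;
#' observed target sites emit the reference allele with probability
#' 1 - epsilon (mismatch epsilon) and missing sites emit uninformatively.
#' Posterior state probabilities come from a scaled forward-backward pass
#' and the dosage at each missing cell is the posterior-weighted mean of the
#' reference alleles.
#'
#' Reference haplotypes are the lines fully observed at the chromosome's
#' markers (in the low-to-high scenario, the reference population).
#'
#' @param masked a \linkS4class{MaskedPanel}.
#' @param map the matching \linkS4class{GeneticMap}.
#' @param params an \code{\link{hmmParams}} object.
#' @return an \linkS4class{ImputedPanel}; the attribute \code{loglik} holds
#'   per-(line, chromosome) forward and backward log-likelihoods.
#' @export
imputeLsHmm <- function(masked, map, params = hmmParams()) {
  stopifnot(inherits(params, "hmmParams"))
  cm <- calls(masked)
  if (!setequal(colnames(cm), markerIds(map)))
    stopf("map does not cover the panel's markers")
  d <- matrix(as.numeric(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  logliks <- list()

  for (chr in unique(chromosomes(map))) {
    ids <- markerIds(map)[chromosomes(map) == chr]
    pos <- positions(map)[chromosomes(map) == chr]
    sub <- cm[, ids, drop = FALSE]
    refRows <- which(rowSums(is.na(sub)) == 0L)
    if (length(refRows) < params$minReferenceHaplotypes)
      stopf(paste("chromosome %s has %d fully observed reference lines",
                  "(need >= %d); use imputeWindow or imputeFreq"),
            chr, length(refRows), params$minReferenceHaplotypes)
    H <- sub[refRows, , drop = FALSE]
    stay <- exp(-params$switchIntensity * diff(pos))
    for (i in setdiff(seq_len(nrow(sub)), refRows)) {
      obs <- sub[i, ]
      fb <- .lsForwardBackward(H, obs, stay, params$errorRate)
      missHere <- which(is.na(obs))
      d[i, ids[missHere]] <- colSums(fb$gamma[, missHere, drop = FALSE] *
                                       H[, missHere, drop = FALSE])
      logliks[[length(logliks) + 1L]] <-
        c(line = i, chr = chr, loglikF = fb$loglikF, loglikB = fb$loglikB)
    }
  }
  d[d < 0] <- 0; d[d > 1] <- 1
  out <- new("ImputedPanel", dosages = d, imputer = "lshmm",
             params = unclass(params)[c("errorRate", "switchIntensity")])
  attr(out, "loglik") <- if (length(logliks)) do.call(rbind, logliks) else NULL
  out
}
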
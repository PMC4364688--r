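#' Parameters for the shrinking-window haplotype-matching imputer
#'
#' @param initialWindow starting window size in markers (default 64).
#' @param shrinkFactor divisor applied to the window size at each round
#'   (default 2).
#' @param minWindow smallest window size used (default 4).
#' @param overlapFraction fractional overlap between consecutive windows of
#'   the same size (default 0.5).
#' @return a list of class \code{windowParams}.
#' @export
windowParams <- function(initialWindow = 64L, shrinkFactor = 2,
                         minWindow = 4L, overlapFraction = 0.5) {
  if (minWindow < 2L || initialWindow < minWindow)
    stopf("need initialWindow >= minWindow >= 2")
  if (shrinkFactor <= 1) stopf("shrinkFactor must exceed 1")
  if (overlapFraction < 0 || overlapFraction >= 1)
    stopf("overlapFraction must lie in [0, 1)")
  structure(list(initialWindow = as.integer(initialWindow),
                 shrinkFactor = shrinkFactor,
                 minWindow = as.integer(minWindow),
                 overlapFraction = overlapFraction),
            class = "windowParams")
}

#' Shrinking-window haplotype-matching imputation
#'
#' Map-dependent imputation by exact haplotype matching in sliding windows,
#' in the spirit of population-based long-segment matchers: windows of
#' steadily shrinking size slide along each chromosome with overlap; within
#' a window, donor lines (fully observed there) that agree with the target
#' at every observed target position cast one vote per missing cell for
#' their own allele, weighted by the window size so that long shared
#' segments -- evidence of a recent common ancestor -- dominate. The final
#' dosage of a missing cell is the weighted vote share for allele 1; cells
#' no donor ever voted on fall back to the allele-frequency baseline.
#'
#' @param masked a \linkS4class{MaskedPanel}.
#' @param map the matching \linkS4class{GeneticMap}.
#' @param params a \code{\link{windowParams}} object.
#' @return an \linkS4class{ImputedPanel}.
#' @export
imputeWindow <- function(masked, map, params = windowParams()) {
  stopifnot(inherits(params, "windowParams"))
  cm <- calls(masked)
  if (!setequal(colnames(cm), markerIds(map)))
    stopf("map does not cover the panel's markers")
  n <- nrow(cm)
  votes1 <- matrix(0, n, ncol(cm), dimnames = dimnames(cm))
  votesT <- matrix(0, n, ncol(cm), dimnames = dimnames(cm))

  sizes <- integer(0)
  w <- params$initialWindow
  while (w >= params$minWindow) {
    sizes <- c(sizes, as.integer(w))
    w <- w / params$shrinkFactor
  }
  if (!length(sizes)) sizes <- params$minWindow

  for (chr in unique(chromosomes(map))) {
    ids <- markerIds(map)[chromosomes(map) == chr]
    M <- length(ids)
    sub <- cm[, ids, drop = FALSE]
    s0 <- (sub == 0L); s0[is.na(s0)] <- FALSE
    s1 <- (sub == 1L); s1[is.na(s1)] <- FALSE
    hasMiss <- rowSums(is.na(sub)) > 0L
    for (W in sizes) {
      Wc <- min(W, M)
      step <- max(1L, as.integer(round(Wc * (1 - params$overlapFraction))))
      starts <- unique(c(seq(1L, max(1L, M - Wc + 1L), by = step),
                         M - Wc + 1L))
      for (st in starts) {
        cols <- st:(st + Wc - 1L)
        blk <- sub[, cols, drop = FALSE]
        donors <- which(rowSums(is.na(blk)) == 0L)
        if (!length(donors)) next
        targets <- which(hasMiss & rowSums(is.na(blk)) > 0L)
        if (!length(targets)) next
        D <- blk[donors, , drop = FALSE]
        # mismatch counts at observed target positions, via 0/1 indicators
        t0 <- s0[targets, cols, drop = FALSE]
        t1 <- s1[targets, cols, drop = FALSE]
        mism <- t0 %*% t(D) + t1 %*% t(1L - D)
        match <- mism == 0
        nv <- rowSums(match)
        if (!any(nv > 0)) next
        v1 <- match %*% D                      # votes for allele 1 per cell
        gidx <- ids[cols]
        missBlk <- is.na(blk[targets, , drop = FALSE])
        add1 <- Wc * v1 * missBlk
        addT <- Wc * outer(nv, rep(1, Wc)) * missBlk
        votes1[targets, gidx] <- votes1[targets, gidx] + add1
        votesT[targets, gidx] <- votesT[targets, gidx] + addT
      }
    }
  }

  d <- matrix(as.numeric(cm), n, ncol(cm), dimnames = dimnames(cm))
  miss <- which(is.na(cm))
  voted <- miss[votesT[miss] > 0]
  d[voted] <- votes1[voted] / votesT[voted]
  unvoted <- miss[votesT[miss] == 0]
  if (length(unvoted)) {
    freq <- colMeans(cm, na.rm = TRUE)
    d[unvoted] <- freq[(unvoted - 1L) %/% n + 1L]
  }
  d[d < 0] <- 0; d[d > 1] <- 1
  new("ImputedPanel", dosages = d, imputer = "window",
      params = unclass(params))
}
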
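#' Parameters for the founder-mosaic panel simulator
#'
#' Bundles the knobs of \code{\link{simulatePanel}} with defaults calibrated
#' to emulate an elite inbred wheat diversity panel: 371 fully inbred lines,
#' markers spread over 21 chromosomes and 4,500 cM, a U-shaped allele
#' frequency spectrum with mean minor allele frequency near 0.13, and strong
#' but heterogeneous adjacent-marker linkage disequilibrium (mean r-squared
#' near 0.52 at the default ~2.25 cM marker spacing).
#'
#' @param nLines number of inbred lines (default 371).
#' @param nMarkers number of markers after the MAF filter (default 2000, a
#'   desk-scale stand-in for a ~10k array; the full scale is supported).
#' @param nChrom number of chromosomes (default 21).
#' @param mapLengthCM total map length in centimorgans (default 4500).
#' @param nFounders number of founder haplotypes the panel is a mosaic of
#'   (default 100; smaller values raise LD and allele frequencies).
#' @param founderAfShape shape parameter a of the symmetric Beta(a, a) from
#'   which founder allele frequencies are drawn at pattern-refresh positions
#'   (default 0.05, giving the strongly U-shaped spectrum of array data).
#' @param founderBlockRate per-cM intensity at which the founder allele
#'   pattern is redrawn along a chromosome; between refreshes adjacent
#'   markers share one founder pattern and are in near-complete LD. Controls
#'   the panel-wide mean adjacent r-squared.
#' @param mosaicSwitchRate per-cM intensity of founder switches along each
#'   line (default 0.005; elite panels are highly related, so segments are long).
#' @param mutationRate per-cell allele flip probability (default 1e-4).
#' @param mafFloor minimum minor allele frequency; markers below it are
#'   redrawn (default 0.01).
#' @param maxRedrawRounds bound on MAF-filter redraw rounds before failing.
#' @param seed integer seed; identical parameters and seed reproduce the
#'   panel bit for bit.
#' @return a list of class \code{panelParams}.
#' @export
panelParams <- function(nLines = 371L, nMarkers = 2000L, nChrom = 21L,
                        mapLengthCM = 4500, nFounders = 100L,
                        founderAfShape = 0.05, founderBlockRate = 0.32,
                        mosaicSwitchRate = 0.005, mutationRate = 1e-4,
                        mafFloor = 0.01, maxRedrawRounds = 50L,
                        seed = NULL) {
  p <- list(nLines = as.integer(nLines), nMarkers = as.integer(nMarkers),
            nChrom = as.integer(nChrom), mapLengthCM = mapLengthCM,
            nFounders = as.integer(nFounders),
            founderAfShape = founderAfShape,
            founderBlockRate = founderBlockRate,
            mosaicSwitchRate = mosaicSwitchRate,
            mutationRate = mutationRate, mafFloor = mafFloor,
            maxRedrawRounds = as.integer(maxRedrawRounds), seed = seed)
  if (any(vapply(p[c("nLines", "nMarkers", "nChrom", "nFounders")],
                 function(x) x < 1L, logical(1))))
    stopf("counts must be positive")
  if (p$mapLengthCM <= 0) stopf("mapLengthCM must be positive")
  if (p$mafFloor < 0 || p$mafFloor >= 0.5) stopf("mafFloor must lie in [0, 0.5)")
  if (p$founderAfShape <= 0) stopf("founderAfShape must be positive")
  if (p$mosaicSwitchRate < 0 || p$founderBlockRate < 0 ||
      p$mutationRate < 0) stopf("rates must be non-negative")
  class(p) <- "panelParams"
  p
}

# Draw one fresh founder allele pattern: frequency from Beta(a, a), alleles
# Bernoulli per founder, rejection-sampled until polymorphic among the
# founders (a monomorphic pattern could never pass the panel MAF floor).
.freshPattern <- function(nFounders, shape) {
  repeat {
    pat <- stats::rbinom(nFounders, 1L, stats::rbeta(1, shape, shape))
    s <- sum(pat)
    if (s > 0L && s < nFounders) return(pat)
  }
}

#' Simulate an inbred-line genotype panel with map structure
#'
#' Generates a panel of fully inbred lines as mosaics of a small set of
#' founder haplotypes. Founder allele patterns persist along each chromosome
#' in blocks (refreshed with per-cM intensity \code{founderBlockRate}), which
#' creates realistic, strongly bimodal adjacent-marker LD; each line copies a
#' founder and switches to a uniformly chosen founder across an inter-marker
#' interval of d cM with probability 1 - exp(-mosaicSwitchRate * d). Per-cell
#' mutation flips alleles at \code{mutationRate}. Markers whose minor allele
#' frequency falls below \code{mafFloor} have their founder pattern redrawn
#' (bounded number of rounds) so the final panel has exactly
#' \code{nMarkers} polymorphic markers and no missing calls.
#'
#' @param params a \code{\link{panelParams}} object.
#' @return a list with elements \code{panel} (\linkS4class{GenotypePanel}),
#'   \code{map} (\linkS4class{GeneticMap}), \code{nSwitches} (integer
#'   vector, realized founder-switch events per line), and the diagnostic
#'   matrices \code{founderHap} (founders x markers alleles) and
#'   \code{founderPath} (lines x markers founder indices).
#' @examples
#' sim <- simulatePanel(panelParams(nLines = 40, nMarkers = 60, nChrom = 3,
#'                                  mapLengthCM = 150, seed = 1))
#' sim$panel
#' @export
simulatePanel <- function(params) {
  stopifnot(inherits(params, "panelParams"))
  withSeed(params$seed, .simulatePanelImpl(params))
}

.simulatePanelImpl <- function(p) {
  nChrom <- p$nChrom
  # markers split as evenly as possible across chromosomes
  perChrom <- rep(p$nMarkers %/% nChrom, nChrom) +
    c(rep(1L, p$nMarkers %% nChrom), rep(0L, nChrom - p$nMarkers %% nChrom))
  if (any(perChrom < 1L)) stopf("more chromosomes than markers")
  chromLen <- p$mapLengthCM / nChrom

  chrom <- rep(seq_len(nChrom), perChrom)
  pos <- unlist(lapply(perChrom, function(m) sort(stats::runif(m, 0, chromLen))))
  mid <- sprintf("M%05d", seq_len(p$nMarkers))
  map <- GeneticMap(mid, chrom, pos)

  F <- p$nFounders
  calls <- matrix(NA_integer_, p$nLines, p$nMarkers,
                  dimnames = list(sprintf("L%04d", seq_len(p$nLines)), mid))
  founderHap <- matrix(0L, F, p$nMarkers)
  founderPath <- matrix(0L, p$nLines, p$nMarkers)
  nSwitches <- integer(p$nLines)

  for (chr in seq_len(nChrom)) {
    idx <- which(chrom == chr)
    M <- length(idx)
    d <- diff(pos[idx])
    # founder haplotypes: block-persistent allele patterns
    refresh <- c(TRUE, stats::runif(M - 1) >= exp(-p$founderBlockRate * d))
    pat <- .freshPattern(F, p$founderAfShape)
    for (j in seq_len(M)) {
      if (refresh[j] && j > 1L) pat <- .freshPattern(F, p$founderAfShape)
      founderHap[, idx[j]] <- pat
    }
    # line mosaics
    f <- sample.int(F, p$nLines, replace = TRUE)
    founderPath[, idx[1]] <- f
    if (M > 1L) {
      pSwitch <- 1 - exp(-p$mosaicSwitchRate * d)
      for (j in 2:M) {
        ev <- stats::runif(p$nLines) < pSwitch[j - 1]
        if (any(ev)) {
          f[ev] <- sample.int(F, sum(ev), replace = TRUE)
          nSwitches[ev] <- nSwitches[ev] + 1L
        }
        founderPath[, idx[j]] <- f
      }
    }
  }

  for (j in seq_len(p$nMarkers))
    calls[, j] <- founderHap[founderPath[, j], j]
  if (p$mutationRate > 0) {
    mut <- stats::runif(length(calls)) < p$mutationRate
    calls[mut] <- 1L - calls[mut]
  }

  # MAF floor: redraw the founder pattern of failing markers (fresh draws,
  # breaking block persistence at those columns only)
  for (round in seq_len(p$maxRedrawRounds)) {
    bad <- which(colMaf(calls) < p$mafFloor)
    if (!length(bad)) break
    for (j in bad) {
      pat <- .freshPattern(p$nFounders, p$founderAfShape)
      founderHap[, j] <- pat
      col <- pat[founderPath[, j]]
      if (p$mutationRate > 0) {
        mut <- stats::runif(p$nLines) < p$mutationRate
        col[mut] <- 1L - col[mut]
      }
      calls[, j] <- col
    }
  }
  if (any(colMaf(calls) < p$mafFloor))
    stopf(paste("could not reach mafFloor = %g for %d markers after %d",
                "redraw rounds; lower mafFloor or founderAfShape"),
          p$mafFloor, sum(colMaf(calls) < p$mafFloor), p$maxRedrawRounds)

  list(panel = GenotypePanel(calls), map = map, nSwitches = nSwitches,
       founderHap = founderHap, founderPath = founderPath)
}

#' Designate nested high- and low-density marker arrays
#'
#' Selects a low-density subset of markers, evenly spaced along each
#' chromosome by position rank with fractional stride 1/lowFraction, so the
#' realized subset size tracks \code{lowFraction * nMarkers} to within one
#' marker per chromosome. Deterministic given the map.
#'
#' @param map a \linkS4class{GeneticMap}.
#' @param lowFraction fraction of markers on the low-density array, in (0, 1).
#' @return an \linkS4class{ArrayDesign}.
#' @examples
#' gm <- GeneticMap(paste0("M", 1:10), rep(1L, 10), 1:10)
#' lowSet(designateArrays(gm, 0.5))
#' @export
designateArrays <- function(map, lowFraction) {
  if (!is.numeric(lowFraction) || lowFraction <= 0 || lowFraction >= 1)
    stopf("lowFraction must lie in (0, 1)")
  stride <- 1 / lowFraction
  low <- character(0)
  for (chr in unique(chromosomes(map))) {
    ids <- markerIds(map)[chromosomes(map) == chr]
    ranks <- unique(floor(seq(1, length(ids), by = stride)))
    if (!length(ranks))
      stopf("lowFraction %g yields an empty low set on chromosome %s",
            lowFraction, chr)
    low <- c(low, ids[ranks])
  }
  new("ArrayDesign", highSet = markerIds(map), lowSet = low,
      imputeSet = setdiff(markerIds(map), low))
}

#' Summarise a genotype panel's LD and allele-frequency structure
#'
#' Mean and standard deviation of adjacent-locus r-squared (within
#' chromosomes; pairs with a monomorphic member are skipped and counted) and
#' of the minor allele frequency, plus panel dimensions.
#'
#' @param panel a complete (no missing calls) \linkS4class{GenotypePanel}.
#' @param map the matching \linkS4class{GeneticMap}.
#' @return a list with \code{meanAdjacentR2}, \code{sdAdjacentR2},
#'   \code{meanMaf}, \code{sdMaf}, \code{nLines}, \code{nMarkers},
#'   \code{nAdjacentPairs}, \code{nSkippedPairs}.
#' @export
panelSummary <- function(panel, map) {
  m <- calls(panel)
  if (anyNA(m)) stopf("panelSummary requires a complete panel")
  if (!identical(colnames(m), markerIds(map)))
    stopf("panel markers must match the map")
  r2 <- numeric(0)
  skipped <- 0L
  for (chr in unique(chromosomes(map))) {
    idx <- which(chromosomes(map) == chr)
    if (length(idx) < 2) next
    x <- m[, idx, drop = FALSE]
    v <- apply(x, 2, stats::var)
    a <- seq_len(ncol(x) - 1)
    ok <- v[a] > 0 & v[a + 1] > 0
    skipped <- skipped + sum(!ok)
    if (any(ok)) {
      cc <- vapply(which(ok), function(j)
        stats::cor(x[, j], x[, j + 1])^2, numeric(1))
      r2 <- c(r2, cc)
    }
  }
  maf <- colMaf(m)
  list(meanAdjacentR2 = if (length(r2)) mean(r2) else NA_real_,
       sdAdjacentR2 = if (length(r2) > 1) stats::sd(r2) else NA_real_,
       meanMaf = mean(maf), sdMaf = stats::sd(maf),
       nLines = nrow(m), nMarkers = ncol(m),
       nAdjacentPairs = length(r2), nSkippedPairs = skipped)
}
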
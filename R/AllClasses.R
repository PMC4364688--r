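#' @import methods
NULL

#' GeneticMap: marker positions on a linear genetic map
#'
#' Per-marker chromosome assignment and centimorgan position. The map is the
#' linear-order backbone used by the map-dependent imputation algorithms and
#' by the linkage-disequilibrium stratification of imputation accuracy.
#'
#' @slot markerId character vector of unique marker identifiers.
#' @slot chromosome integer chromosome index per marker.
#' @slot position numeric position in centimorgans, strictly increasing
#'   within each chromosome.
#'
#' @examples
#' gm <- GeneticMap(paste0("M", 1:4), c(1L, 1L, 2L, 2L), c(0, 10, 0, 25))
#' markerIds(gm)
#' @export
setClass("GeneticMap",
  representation(
    markerId = "character",
    chromosome = "integer",
    position = "numeric"
  )
)

setValidity("GeneticMap", function(object) {
  n <- length(object@markerId)
  if (length(object@chromosome) != n || length(object@position) != n)
    return("markerId, chromosome and position must have equal length")
  if (anyDuplicated(object@markerId))
    return("marker ids must be unique")
  if (any(object@position < 0))
    return("positions must be non-negative (cM)")
  if (n > 0 && any(object@chromosome < 1L))
    return("chromosome indices must be >= 1")
  for (chr in unique(object@chromosome)) {
    p <- object@position[object@chromosome == chr]
    if (any(diff(p) <= 0))
      return(sprintf("positions must be strictly increasing within chromosome %d", chr))
  }
  TRUE
})

#' @param markerId character vector of unique marker identifiers.
#' @param chromosome integer chromosome index per marker.
#' @param position numeric centimorgan positions, strictly increasing within
#'   each chromosome.
#' @rdname GeneticMap-class
#' @export
GeneticMap <- function(markerId, chromosome, position) {
  new("GeneticMap",
    markerId = as.character(markerId),
    chromosome = as.integer(chromosome),
    position = as.numeric(position)
  )
}

#' GenotypePanel: biallelic homozygote calls for a panel of inbred lines
#'
#' A lines x markers matrix of haploid-equivalent allele codes. Fully inbred
#' lines carry two identical alleles at every locus, so each genotype is
#' coded 0 or 1 (NA for missing); no heterozygote code exists in this
#' container. Line and marker identifiers live in the dimnames.
#'
#' @slot calls integer matrix over \{0, 1, NA\}, rows = lines, cols = markers.
#'
#' @export
setClass("GenotypePanel", representation(calls = "matrix"))

setValidity("GenotypePanel", function(object) {
  m <- object@calls
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("calls matrix must carry line ids (rownames) and marker ids (colnames)")
  if (anyDuplicated(rownames(m))) return("line ids must be unique")
  if (anyDuplicated(colnames(m))) return("marker ids must be unique")
  v <- m[!is.na(m)]
  if (length(v) && !all(v %in% c(0L, 1L)))
    return("calls must be 0, 1 or NA (inbred homozygote coding)")
  TRUE
})

#' @param calls matrix over \{0, 1, NA\} with line rownames and marker colnames.
#' @rdname GenotypePanel-class
#' @export
GenotypePanel <- function(calls) {
  storage.mode(calls) <- "integer"
  new("GenotypePanel", calls = calls)
}

#' ArrayDesign: nested high- and low-density marker sets
#'
#' Encodes the nesting of a low-density array inside a high-density one:
#' \code{lowSet} (the markers both arrays share) is a subset of
#' \code{highSet}, and \code{imputeSet} is the complement -- the markers that
#' become imputation targets for lines genotyped only at low density.
#'
#' @slot highSet character, all marker ids of the high-density array.
#' @slot lowSet character, marker ids of the nested low-density array.
#' @slot imputeSet character, \code{setdiff(highSet, lowSet)}.
#'
#' @export
setClass("ArrayDesign",
  representation(highSet = "character", lowSet = "character",
                 imputeSet = "character")
)

setValidity("ArrayDesign", function(object) {
  if (!all(object@lowSet %in% object@highSet))
    return("lowSet must be a subset of highSet")
  if (!setequal(object@imputeSet, setdiff(object@highSet, object@lowSet)))
    return("imputeSet must equal highSet minus lowSet")
  if (length(object@lowSet) == 0) return("lowSet must be non-empty")
  TRUE
})

#' MaskedPanel: a genotype panel with an evaluation mask
#'
#' Couples a panel whose masked cells have been set to missing with the
#' cell-level mask distinguishing scenario-masked cells (the evaluation
#' targets) from cells that were missing in the original data, plus the
#' pre-masking truth for the masked cells only. Originally missing cells are
#' never evaluation targets.
#'
#' Mask codes: 0 = observed, 1 = masked (truth retained), 2 = originally
#' missing.
#'
#' @slot panel GenotypePanel with masked cells set to NA.
#' @slot mask integer matrix of mask codes, same dimensions as the panel.
#' @slot truth numeric matrix holding the pre-masking call at masked cells
#'   and NA elsewhere.
#' @slot scenario list describing the masking scenario (kind, refSize or
#'   missingRate, replicate, seed).
#' @slot refLines character, reference-line ids (low-to-high scenario; empty
#'   otherwise).
#' @slot testLines character, test-line ids (low-to-high scenario; empty
#'   otherwise).
#'
#' @export
setClass("MaskedPanel",
  representation(
    panel = "GenotypePanel",
    mask = "matrix",
    truth = "matrix",
    scenario = "list",
    refLines = "character",
    testLines = "character"
  )
)

setValidity("MaskedPanel", function(object) {
  cm <- calls(object@panel)
  if (!identical(dim(object@mask), dim(cm)) ||
      !identical(dim(object@truth), dim(cm)))
    return("mask and truth must have the panel's dimensions")
  if (!all(object@mask %in% c(MASK_OBSERVED, MASK_MASKED, MASK_ORIG_MISSING)))
    return("mask codes must be 0 (observed), 1 (masked) or 2 (orig. missing)")
  if (any(!is.na(cm[object@mask != MASK_OBSERVED])))
    return("masked and originally-missing cells must be NA in the panel")
  if (any(is.na(object@truth[object@mask == MASK_MASKED])))
    return("truth must be defined at every masked cell")
  if (any(!is.na(object@truth[object@mask != MASK_MASKED])))
    return("truth must be NA outside masked cells")
  TRUE
})

#' @name mask-codes
#' @title Mask cell-state codes
#' @description Integer codes used in the \code{mask} slot of a
#'   \linkS4class{MaskedPanel}: observed, scenario-masked (evaluation
#'   target), and originally missing.
#' @export
MASK_OBSERVED <- 0L
#' @rdname mask-codes
#' @export
MASK_MASKED <- 1L
#' @rdname mask-codes
#' @export
MASK_ORIG_MISSING <- 2L

#' ImputedPanel: continuous dosages for the missing cells of a masked panel
#'
#' Holds the full dosage matrix after imputation: observed cells carry their
#' original calls, missing cells (masked or originally missing) carry
#' continuous allele-1 dosages in [0, 1], together with the identity and
#' parameters of the imputer that produced them.
#'
#' @slot dosages numeric matrix in [0, 1], same dimensions as the source panel.
#' @slot imputer character scalar naming the algorithm.
#' @slot params list of algorithm parameters used.
#'
#' @export
setClass("ImputedPanel",
  representation(dosages = "matrix", imputer = "character", params = "list")
)

setValidity("ImputedPanel", function(object) {
  d <- object@dosages
  if (is.null(rownames(d)) || is.null(colnames(d)))
    return("dosages must carry line and marker ids in dimnames")
  v <- d[!is.na(d)]
  if (length(v) && (any(v < 0) || any(v > 1)))
    return("dosages must lie in [0, 1]")
  if (length(object@imputer) != 1L)
    return("imputer must be a single name")
  TRUE
})

#' PhenotypeSim: simulated phenotypes and their generating components
#'
#' Result of the additive phenotype simulations: phenotypes, true genotypic
#' values, per-marker effects, the focal QTL (if any), and the variance
#' components implied by the target heritability.
#'
#' @slot y numeric phenotype per line (named).
#' @slot gTrue numeric true genotypic value per line (named).
#' @slot beta numeric per-marker allele-substitution effects (named).
#' @slot qtlMarker character, the focal QTL's marker id (length 0 when the
#'   architecture is purely polygenic).
#' @slot h2 numeric target heritability.
#' @slot qtlVarFraction numeric fraction of genetic variance assigned to the
#'   QTL (0 for polygenic simulations).
#' @slot sigmaG numeric genetic variance.
#' @slot sigmaE numeric residual variance.
#' @slot seed integer seed used.
#'
#' @export
setClass("PhenotypeSim",
  representation(
    y = "numeric", gTrue = "numeric", beta = "numeric",
    qtlMarker = "character", h2 = "numeric", qtlVarFraction = "numeric",
    sigmaG = "numeric", sigmaE = "numeric", seed = "integer"
  )
)

setValidity("PhenotypeSim", function(object) {
  if (object@h2 <= 0 || object@h2 >= 1) return("h2 must lie in (0, 1)")
  if (object@sigmaG < 0 || object@sigmaE < 0)
    return("variance components must be non-negative")
  if (length(object@y) != length(object@gTrue))
    return("y and gTrue must align")
  TRUE
})
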
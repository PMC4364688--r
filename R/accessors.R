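#' @rdname accessors
#' @export
setMethod("markerIds", "GeneticMap", function(x) x@markerId)

#' @rdname accessors
#' @export
setMethod("markerIds", "GenotypePanel", function(x) colnames(x@calls))

#' @rdname accessors
#' @export
setMethod("markerIds", "MaskedPanel", function(x) colnames(x@panel@calls))

#' @rdname accessors
#' @export
setMethod("markerIds", "ImputedPanel", function(x) colnames(x@dosages))

#' @rdname accessors
#' @export
setMethod("lineIds", "GenotypePanel", function(x) rownames(x@calls))

#' @rdname accessors
#' @export
setMethod("lineIds", "MaskedPanel", function(x) rownames(x@panel@calls))

#' @rdname accessors
#' @export
setMethod("lineIds", "ImputedPanel", function(x) rownames(x@dosages))

#' @rdname accessors
#' @export
setMethod("calls", "GenotypePanel", function(x) x@calls)

#' @rdname accessors
#' @export
setMethod("calls", "MaskedPanel", function(x) x@panel@calls)

#' @rdname accessors
#' @export
setMethod("dosages", "ImputedPanel", function(x) x@dosages)

#' @rdname accessors
#' @export
setMethod("maskStates", "MaskedPanel", function(x) x@mask)

#' @rdname accessors
#' @export
setMethod("truthCalls", "MaskedPanel", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("nLines", "GenotypePanel", function(x) nrow(x@calls))

#' @rdname accessors
#' @export
setMethod("nLines", "MaskedPanel", function(x) nrow(x@panel@calls))

#' @rdname accessors
#' @export
setMethod("nMarkers", "GenotypePanel", function(x) ncol(x@calls))

#' @rdname accessors
#' @export
setMethod("nMarkers", "MaskedPanel", function(x) ncol(x@panel@calls))

#' @rdname accessors
#' @export
setMethod("nMarkers", "GeneticMap", function(x) length(x@markerId))

#' @rdname accessors
#' @export
setMethod("chromosomes", "GeneticMap", function(x) x@chromosome)

#' @rdname accessors
#' @export
setMethod("positions", "GeneticMap", function(x) x@position)

#' @rdname accessors
#' @export
setMethod("highSet", "ArrayDesign", function(x) x@highSet)

#' @rdname accessors
#' @export
setMethod("lowSet", "ArrayDesign", function(x) x@lowSet)

#' @rdname accessors
#' @export
setMethod("imputeSet", "ArrayDesign", function(x) x@imputeSet)

#' @rdname accessors
#' @export
setMethod("refLines", "MaskedPanel", function(x) x@refLines)

#' @rdname accessors
#' @export
setMethod("testLines", "MaskedPanel", function(x) x@testLines)

#' @rdname accessors
#' @export
setMethod("scenario", "MaskedPanel", function(x) x@scenario)

setMethod("show", "GeneticMap", function(object) {
  cat("GeneticMap:", length(object@markerId), "markers on",
      length(unique(object@chromosome)), "chromosomes,",
      sprintf("%.1f cM total\n", sum(tapply(object@position,
                                            object@chromosome, max))))
})

setMethod("show", "GenotypePanel", function(object) {
  m <- object@calls
  cat("GenotypePanel:", nrow(m), "lines x", ncol(m), "markers;",
      sprintf("%.2f%% missing\n", 100 * mean(is.na(m))))
})

setMethod("show", "ArrayDesign", function(object) {
  cat("ArrayDesign: high", length(object@highSet),
      "| low", length(object@lowSet),
      "| impute targets", length(object@imputeSet), "\n")
})

setMethod("show", "MaskedPanel", function(object) {
  sc <- object@scenario
  cat("MaskedPanel [", if (length(sc$kind)) sc$kind else "?", "]: ",
      nrow(object@mask), " lines x ", ncol(object@mask), " markers; ",
      sum(object@mask == MASK_MASKED), " masked cells (",
      sprintf("%.1f%%", 100 * mean(object@mask == MASK_MASKED)), ")\n",
      sep = "")
})

setMethod("show", "ImputedPanel", function(object) {
  cat("ImputedPanel:", object@imputer, "-", nrow(object@dosages), "lines x",
      ncol(object@dosages), "markers\n")
})

setMethod("show", "PhenotypeSim", function(object) {
  cat("PhenotypeSim:", length(object@y), "lines; h2 =", object@h2,
      if (length(object@qtlMarker))
        paste0("; QTL ", object@qtlMarker, " (",
               round(100 * object@qtlVarFraction), "% of genetic variance)")
      else "; polygenic", "\n")
})
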
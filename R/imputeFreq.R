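#' Allele-frequency baseline imputation
#'
#' Fills every missing cell of a masked panel with the marker's observed
#' allele-1 frequency. This is both the weakest benchmark against which the
#' real imputers are compared and the initializer/fallback used by the other
#' algorithms.
#'
#' @param masked a \linkS4class{MaskedPanel}.
#' @return an \linkS4class{ImputedPanel} with dosages equal to per-marker
#'   observed means at all missing cells.
#' @export
imputeFreq <- function(masked) {
  cm <- calls(masked)
  freq <- colMeans(cm, na.rm = TRUE)
  if (anyNA(freq))
    stopf("marker(s) with zero observed calls: %s",
          paste(colnames(cm)[is.na(freq)], collapse = ", "))
  d <- matrix(as.numeric(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  miss <- which(is.na(cm))
  d[miss] <- freq[(miss - 1L) %/% nrow(cm) + 1L]
  new("ImputedPanel", dosages = d, imputer = "freq", params = list())
}
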
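#' Read and write genotype panels, maps and dosages as TSV
#'
#' Plain-text interchange: the genotype TSV has a header row of marker ids
#' and one row per line (line id then 0/1/NA calls); the map TSV has
#' columns marker_id, chrom, pos_cM; the dosage TSV is long-format
#' (line_id, marker_id, dosage). Any genotype value outside \{0, 1, NA\} --
#' e.g. a heterozygote code in real data -- is treated as missing with a
#' warning, since the panel containers are defined for fully inbred lines.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param file path.
#' @return readers return the corresponding object; writers return the file
#'   path invisibly.
#' @name panel-io
NULL

#' @rdname panel-io
#' @export
writeGenotypeTsv <- function(panel, file) {
  m <- calls(panel)
  df <- data.frame(line_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname panel-io
#' @export
readGenotypeTsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  vals <- suppressWarnings(as.numeric(m))
  bad <- !is.na(m) & m != "NA" & !(vals %in% c(0, 1)) & !is.na(vals)
  badTok <- !is.na(m) & m != "NA" & is.na(vals)
  n_bad <- sum(bad | badTok)
  if (n_bad > 0)
    warning(sprintf(
      "%d genotype value(s) outside {0, 1, NA} (heterozygous or malformed) set to missing",
      n_bad))
  out <- matrix(NA_integer_, nrow(m), ncol(m), dimnames = dimnames(m))
  ok <- !is.na(vals) & vals %in% c(0, 1)
  out[ok] <- as.integer(vals[ok])
  GenotypePanel(out)
}

#' @rdname panel-io
#' @param map a \linkS4class{GeneticMap}.
#' @export
writeMapTsv <- function(map, file) {
  utils::write.table(
    data.frame(marker_id = markerIds(map), chrom = chromosomes(map),
               pos_cM = positions(map)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname panel-io
#' @export
readMapTsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  GeneticMap(df$marker_id, df$chrom, df$pos_cM)
}

#' @rdname panel-io
#' @param imputed an \linkS4class{ImputedPanel}.
#' @param masked the \linkS4class{MaskedPanel} it filled (its missing cells
#'   determine which dosages are written).
#' @export
writeDosageTsv <- function(imputed, masked, file) {
  cm <- calls(masked)
  miss <- which(is.na(cm), arr.ind = TRUE)
  df <- data.frame(line_id = rownames(cm)[miss[, 1]],
                   marker_id = colnames(cm)[miss[, 2]],
                   dosage = dosages(imputed)[miss])
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export and import a panel as haploid-coded VCF
#'
#' Fully inbred lines are written as homozygous diploid genotypes (0/0,
#' 1/1, ./.), one contig per chromosome, with the genetic-map position
#' stored in the INFO field CM (POS holds the within-chromosome marker
#' rank). Import converts 0/0 to 0 and 1/1 to 1; heterozygous genotypes
#' become missing with a warning.
#'
#' @param panel a \linkS4class{GenotypePanel}.
#' @param map the matching \linkS4class{GeneticMap}.
#' @param file path to a (plain, uncompressed) VCF.
#' @return \code{readVcfPanel} returns \code{list(panel, map)};
#'   \code{writeVcfPanel} returns the path invisibly.
#' @export
writeVcfPanel <- function(panel, map, file) {
  m <- calls(panel)
  m <- m[, markerIds(map), drop = FALSE]
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=InbredImpute",
               sprintf("##contig=<ID=%s>", unique(chromosomes(map))),
               "##INFO=<ID=CM,Number=1,Type=Float,Description=\"Genetic map position in centimorgans\">",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(m)), collapse = "\t"), con)
  rank <- stats::ave(seq_len(nMarkers(map)), chromosomes(map),
                     FUN = seq_along)
  gtcode <- c("0/0", "1/1")
  for (j in seq_len(ncol(m))) {
    gt <- ifelse(is.na(m[, j]), "./.", gtcode[m[, j] + 1L])
    writeLines(paste(c(chromosomes(map)[j], rank[j], markerIds(map)[j],
                       "A", "B", ".", "PASS",
                       sprintf("CM=%.6f", positions(map)[j]), "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(file)
}

#' @rdname writeVcfPanel
#' @export
readVcfPanel <- function(file) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stopf("readVcfPanel needs the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  conv <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  conv[gt %in% c("0/0", "0|0")] <- 0L
  conv[gt %in% c("1/1", "1|1")] <- 1L
  het <- !is.na(gt) & gt %in% c("0/1", "1/0", "0|1", "1|0")
  if (any(het))
    warning(sprintf("%d heterozygous genotype(s) set to missing", sum(het)))
  cm <- as.numeric(sub(".*CM=([0-9.eE+-]+).*", "\\1", v@fix[, "INFO"]))
  map <- GeneticMap(rownames(gt), as.integer(v@fix[, "CHROM"]), cm)
  list(panel = GenotypePanel(t(conv)), map = map)
}
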
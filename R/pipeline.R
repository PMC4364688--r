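#' Configuration for a full imputation-benchmark experiment
#'
#' Bundles the panel parameters, the masking-scenario grid, the imputer
#' list and the downstream-analysis toggles of
#' \code{\link{runExperiment}}. Per-cell seeds are derived from
#' \code{baseSeed} with \code{\link{stableSeed}}, so every grid cell is
#' reproducible independently of execution order.
#'
#' @param panel a \code{\link{panelParams}} object (its \code{seed} slot is
#'   ignored; the panel seed derives from \code{baseSeed}).
#' @param lowFraction low-density array fraction (default 1573/9926, the
#'   array-nesting ratio the design emulates).
#' @param refSizes low-to-high reference-population sizes (default
#'   \code{c(50, 100, 200, 300)}); NULL skips the scenario.
#' @param gbsRates GBS-like missing-value levels (default NULL = skipped;
#'   the canonical grid is \code{c(0.728, 0.615, 0.388, 0.161)}).
#' @param replicates replicates per scenario point (default 5).
#' @param imputers subset of \code{c("freq", "rf", "window", "lshmm")}.
#' @param rfParams,windowParams,hmmParams imputer parameter objects.
#' @param runRd,runGs toggles for the Rogers'-distance benchmark and the
#'   genomic-selection accuracy comparison.
#' @param h2 heritability of the simulated trait for \code{runGs}.
#' @param baseSeed integer base seed.
#' @param outDir optional directory; per-cell accuracy tables are written
#'   there and reused on re-runs (idempotent grids).
#' @return a list of class \code{experimentConfig}.
#' @export
experimentConfig <- function(panel = panelParams(),
                             lowFraction = 1573 / 9926,
                             refSizes = c(50L, 100L, 200L, 300L),
                             gbsRates = NULL,
                             replicates = 5L,
                             imputers = c("freq", "rf", "window", "lshmm"),
                             rfParams = InbredImpute::rfParams(),
                             windowParams = InbredImpute::windowParams(),
                             hmmParams = InbredImpute::hmmParams(),
                             runRd = FALSE, runGs = FALSE, h2 = 0.91,
                             baseSeed = 1L, outDir = NULL) {
  imputers <- match.arg(imputers, c("freq", "rf", "window", "lshmm"),
                        several.ok = TRUE)
  if (!is.null(refSizes) && any(refSizes >= panel$nLines))
    stopf("refSizes must be smaller than the panel")
  if (replicates < 1L) stopf("need at least one replicate")
  structure(list(panel = panel, lowFraction = lowFraction,
                 refSizes = refSizes, gbsRates = gbsRates,
                 replicates = as.integer(replicates), imputers = imputers,
                 rfParams = rfParams, windowParams = windowParams,
                 hmmParams = hmmParams, runRd = runRd, runGs = runGs,
                 h2 = h2, baseSeed = as.integer(baseSeed), outDir = outDir),
            class = "experimentConfig")
}

#' Read an experiment configuration from YAML
#'
#' Maps a flat YAML document onto \code{\link{experimentConfig}}; keys under
#' \code{panel:} go to \code{\link{panelParams}}, the remaining top-level
#' keys to the config itself.
#'
#' @param file path to a YAML file.
#' @return an \code{experimentConfig}.
#' @export
readExperimentConfig <- function(file) {
  y <- yaml::read_yaml(file)
  pp <- do.call(panelParams, y$panel %||% list())
  y$panel <- NULL
  known <- setdiff(names(formals(experimentConfig)), "panel")
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  do.call(experimentConfig, c(list(panel = pp), y))
}

.imputeByName <- function(name, mk, map, config, seed) {
  switch(name,
    freq = imputeFreq(mk),
    rf = {
      p <- config$rfParams; p$seed <- seed
      imputeRandomForest(mk, p)
    },
    window = imputeWindow(mk, map, config$windowParams),
    lshmm = imputeLsHmm(mk, map, config$hmmParams))
}

.maskCell <- function(config, panel, design, kind, point, rep) {
  seed <- stableSeed(config$baseSeed, "mask", kind, point, rep)
  if (kind == "low2high")
    maskLowToHigh(panel, design, refSize = point, seed = seed,
                  replicate = rep)
  else
    maskGbsLike(panel, missingRate = point, seed = seed, replicate = rep)
}

#' Run the full scenario x imputer x replicate experiment grid
#'
#' Simulates the panel, builds the nested array design, and for every
#' (scenario point, replicate) masks the panel and runs every configured
#' imputer, collecting per-marker accuracy summaries; optionally adds the
#' Rogers'-distance benchmark and the genomic-selection accuracy
#' comparison per cell. Any cell failure is caught, logged in the bundle's
#' \code{failures}, and does not stop the remaining cells. With
#' \code{outDir} set, completed accuracy cells found on disk are reused.
#'
#' @param config an \code{\link{experimentConfig}}.
#' @return a ReportBundle: list with \code{accuracy} (per-cell rows),
#'   \code{table1} (mean accuracy by scenario point x imputer),
#'   \code{rd}, \code{gs} (or NULL), \code{failures}, and
#'   \code{provenance} (base seed, config hash, package version).
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "experimentConfig"))
  pp <- config$panel
  pp$seed <- stableSeed(config$baseSeed, "panel")
  sim <- simulatePanel(pp)
  design <- designateArrays(sim$map, config$lowFraction)
  if (!is.null(config$outDir))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)

  grid <- rbind(
    if (!is.null(config$refSizes))
      expand.grid(kind = "low2high", point = config$refSizes,
                  rep = seq_len(config$replicates),
                  stringsAsFactors = FALSE),
    if (!is.null(config$gbsRates))
      expand.grid(kind = "gbs", point = config$gbsRates,
                  rep = seq_len(config$replicates),
                  stringsAsFactors = FALSE))
  if (is.null(grid) || !nrow(grid)) stopf("empty scenario grid")

  accRows <- list(); rdRows <- list(); gsRows <- list(); failures <- list()
  for (g in seq_len(nrow(grid))) {
    kind <- grid$kind[g]; point <- grid$point[g]; rep <- grid$rep[g]
    cellTag <- sprintf("%s_%s_r%02d", kind, format(point), rep)
    cellFile <- if (!is.null(config$outDir))
      file.path(config$outDir, paste0("acc_", cellTag, ".tsv")) else NULL
    if (!is.null(cellFile) && file.exists(cellFile)) {
      accRows[[cellTag]] <- utils::read.table(cellFile, header = TRUE,
                                              sep = "\t",
                                              stringsAsFactors = FALSE)
      next
    }
    mk <- tryCatch(.maskCell(config, sim$panel, design, kind, point, rep),
                   error = function(e) e)
    if (inherits(mk, "error")) {
      failures[[cellTag]] <- conditionMessage(mk)
      next
    }
    imps <- list()
    rows <- list()
    for (im in config$imputers) {
      cell <- tryCatch({
        ip <- .imputeByName(im, mk, sim$map, config,
                            stableSeed(config$baseSeed, "impute", im,
                                       kind, point, rep))
        s <- attr(perMarkerAccuracy(mk, ip), "summary")
        list(ip = ip,
             row = data.frame(scenario = kind, point = point,
                              replicate = rep, imputer = im,
                              meanCor = s$meanCor,
                              nUndefined = s$nUndefined,
                              nMarkers = s$nMarkers,
                              stringsAsFactors = FALSE))
      }, error = function(e) e)
      if (inherits(cell, "error")) {
        failures[[paste0(cellTag, "_", im)]] <- conditionMessage(cell)
        next
      }
      imps[[im]] <- cell$ip
      rows[[im]] <- cell$row
    }
    if (!length(rows)) next
    res <- list(acc = do.call(rbind, rows), mk = mk, imps = imps)
    accRows[[cellTag]] <- res$acc
    if (!is.null(cellFile))
      utils::write.table(res$acc, cellFile, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    if (config$runRd) {
      rd <- rdBenchmark(sim$panel,
                        if (kind == "low2high") design else NULL,
                        res$mk, res$imps)
      rd$scenario <- kind; rd$point <- point; rd$replicate <- rep
      rdRows[[cellTag]] <- rd
    }
    if (config$runGs && kind == "low2high")
      gsRows[[cellTag]] <- .gsCell(config, sim, design, res, point, rep)
    if (config$runGs && kind == "gbs")
      gsRows[[cellTag]] <- .gsCellGbs(config, sim, res, point, rep)
  }

  accuracy <- do.call(rbind, accRows)
  rownames(accuracy) <- NULL
  table1 <- stats::aggregate(meanCor ~ scenario + point + imputer,
                             data = accuracy, FUN = mean, na.action = NULL)
  table1 <- table1[order(table1$scenario, table1$point, table1$imputer), ]
  rownames(table1) <- NULL
  list(accuracy = accuracy, table1 = table1,
       rd = if (length(rdRows)) {
         r <- do.call(rbind, rdRows); rownames(r) <- NULL; r
       } else NULL,
       gs = if (length(gsRows)) {
         r <- do.call(rbind, gsRows); rownames(r) <- NULL; r
       } else NULL,
       failures = failures,
       provenance = list(baseSeed = config$baseSeed,
                         configHash = stableSeed(0L, utils::capture.output(
                           utils::str(config[setdiff(names(config),
                                                     "outDir")]))),
                         package = as.character(utils::packageVersion(
                           "InbredImpute"))))
}

# GS accuracy cell, low-to-high layout: train RR-BLUP on the reference
# lines, predict the test lines' genotypic values; compare the low-density
# and full arrays against every imputed completion.
.gsCell <- function(config, sim, design, res, point, rep) {
  mk <- res$mk
  ph <- simulatePolygenicPhenotype(
    sim$panel, h2 = config$h2,
    seed = stableSeed(config$baseSeed, "gs-pheno", point, rep))
  ref <- refLines(mk); test <- testLines(mk)
  X <- matrix(as.numeric(calls(sim$panel)), nrow(calls(sim$panel)),
              ncol(calls(sim$panel)), dimnames = dimnames(calls(sim$panel)))
  evalAcc <- function(markers) {
    mod <- fitRrblup(ph@y[ref], markers[ref, , drop = FALSE])
    predictRrblup(mod, markers[test, , drop = FALSE], ph@gTrue)$accuracy
  }
  rows <- data.frame(
    dataset = c("low-density", "full"),
    accuracy = c(evalAcc(X[, lowSet(design), drop = FALSE]), evalAcc(X)),
    stringsAsFactors = FALSE)
  for (im in names(res$imps))
    rows <- rbind(rows, data.frame(dataset = im,
                                   accuracy = evalAcc(dosages(res$imps[[im]]))))
  rows$scenario <- "low2high"; rows$point <- point; rows$replicate <- rep
  rows
}

# GS accuracy cell, GBS layout: GBLUP on the pairwise-complete
# (non-imputed) relationship matrix versus GRMs from each imputed
# completion, training on a random 80% of lines.
.gsCellGbs <- function(config, sim, res, point, rep) {
  ph <- simulatePolygenicPhenotype(
    sim$panel, h2 = config$h2,
    seed = stableSeed(config$baseSeed, "gs-pheno-gbs", point, rep))
  ids <- lineIds(sim$panel)
  train <- withSeed(stableSeed(config$baseSeed, "gs-split", point, rep),
                    sort(sample(ids, round(0.8 * length(ids)))))
  test <- setdiff(ids, train)
  evalAcc <- function(K) {
    mod <- fitGblup(ph@y[train], K)
    pr <- predictGblup(mod, K[test, , drop = FALSE], ph@gTrue)
    pr$accuracy
  }
  rows <- data.frame(
    dataset = "non-imputed pairwise-complete",
    accuracy = evalAcc(buildGrm(res$mk, pairwiseComplete = TRUE)),
    stringsAsFactors = FALSE)
  for (im in names(res$imps))
    rows <- rbind(rows, data.frame(dataset = im,
                                   accuracy = evalAcc(buildGrm(res$imps[[im]]))))
  rows$scenario <- "gbs"; rows$point <- point; rows$replicate <- rep
  rows
}
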
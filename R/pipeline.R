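# End-to-end orchestration: deconvolve -> densities -> CV immunoscore ->
# cut-offs -> stratified survival report. All randomness flows from one
# root seed; per-stage child seeds are derived deterministically.

.logMsg <- function(verbose, ...) if (isTRUE(verbose)) message(...)

.cutoffName <- function(spec) {
  if (cutoffMethod(spec) == "fixed_percentile")
    sprintf("fixed_%g", spec@percentile)
  else "youden"
}

# Per-iteration Harrell C: each iteration's scores are dichotomized at the
# cut-off percentile of that iteration's own score distribution (or used
# directly when cIndexOn = "score") and scored against survival.
.perIterationC <- function(result, percentile, time, event,
                           cIndexOn = c("category", "score")) {
  cIndexOn <- match.arg(cIndexOn)
  per <- perIterationScores(result)
  vapply(seq_len(ncol(per)), function(it) {
    s <- per[, it]
    x <- if (cIndexOn == "score") s else {
      thr <- as.numeric(stats::quantile(s, percentile / 100, names = FALSE))
      as.numeric(s >= thr)
    }
    harrellC(time, event, x)
  }, numeric(1))
}

# Survival statistics for one categorized result.
.cutoffReport <- function(result, spec, time, event, cIndexOn = "category") {
  p <- resolvedPercentile(spec)
  cat <- categories(result)
  nLow <- sum(cat == 0L)
  out <- list(
    method = cutoffMethod(spec),
    percentile = p,
    nLow = nLow,
    pctLow = 100 * nLow / length(cat),
    concordance = summarizeC(.perIterationC(result, p, time, event,
                                            cIndexOn)))
  if (length(unique(cat)) == 2) {
    out$logrank <- logrankTest(time, event, cat)
    out$cox <- coxBinaryHR(time, event, cat)
    out$km <- list(low = kaplanMeier(time[cat == 0L], event[cat == 0L]),
                   high = kaplanMeier(time[cat == 1L], event[cat == 1L]))
  } else {
    out$logrank <- list(statistic = NA_real_, p.value = NA_real_)
    out$cox <- NULL
    out$km <- list(all = kaplanMeier(time, event))
    out$note <- "single immunoscore category; no group comparison"
  }
  out
}

#' Analyze a cohort held in memory
#'
#' The in-memory core of [runPipeline()]: converts the expression matrix to
#' linear TPM, inner-joins patient ids across inputs (dropped ids are
#' reported with a warning), deconvolves every sample, derives CD3/CD8
#' densities, computes the cross-validated immunoscore, and for each
#' requested cut-off reports the low-category count, log-rank test, Cox
#' hazard ratio, CV-aggregated Harrell C-index and per-category
#' Kaplan-Meier curves.
#'
#' @param expression a [BulkExpression-class] (any scale tag).
#' @param signature a [SignatureMatrix-class].
#' @param survivalData data.frame with columns \code{patient_id},
#'   \code{time}, \code{event}.
#' @param scheme a [CVScheme-class].
#' @param cutoffs list of [CutoffSpec-class] objects (default: fixed 25th
#'   percentile and Youden).
#' @param nuGrid nu grid for [deconvolveSample()].
#' @param fractions optional precomputed [CellFractions-class] for these
#'   samples (deconvolution is per-sample, so precomputed fractions subset
#'   exactly); when NULL they are computed here.
#' @param cIndexOn evaluate the C-index on the binary \code{"category"}
#'   (default) or the continuous \code{"score"}.
#' @param stratumLabel label stored in the report ("" = whole cohort).
#' @param verbose emit per-stage progress messages.
#' @return A [CohortReport-class] object.
#' @export
analyzeCohort <- function(expression, signature, survivalData,
                          scheme = CVScheme(),
                          cutoffs = list(CutoffSpec(percentile = 25),
                                         CutoffSpec("youden")),
                          nuGrid = c(0.25, 0.5, 0.75), fractions = NULL,
                          cIndexOn = "category", stratumLabel = "",
                          verbose = FALSE) {
  stopifnot(is(expression, "BulkExpression"), is(signature, "SignatureMatrix"),
            all(c("patient_id", "time", "event") %in% names(survivalData)),
            length(cutoffs) >= 1)
  expression <- toLinearTPM(expression)

  ids <- intersect(sampleIds(expression), survivalData$patient_id)
  dropped <- setdiff(union(sampleIds(expression), survivalData$patient_id),
                     ids)
  if (!length(ids)) stop("empty patient-id join between expression and survival")
  if (length(dropped))
    warning("dropped ", length(dropped), " unmatched patient id(s): ",
            paste(dropped, collapse = ", "))
  surv <- survivalData[match(ids, survivalData$patient_id), ]
  time <- .checkSurvivalInput(surv$time, surv$event)
  event <- surv$event

  .logMsg(verbose, "deconvolution stage: ", length(ids), " samples")
  if (is.null(fractions)) {
    sub <- BulkExpression(exprValues(expression)[, ids, drop = FALSE])
    fractions <- deconvolveCohort(sub, signature, nuGrid)
  } else {
    stopifnot(all(ids %in% sampleIds(fractions)))
    fractions <- new("CellFractions",
                     fractions = fractions(fractions)[ids, , drop = FALSE],
                     fitRMSE = fitRMSE(fractions)[match(ids, sampleIds(fractions))],
                     fitCorr = fitCorr(fractions)[match(ids, sampleIds(fractions))],
                     pValue = pValues(fractions)[match(ids, sampleIds(fractions))])
  }
  dens <- imputeTCellDensities(fractions, signature)

  .logMsg(verbose, "scoring stage: ", scheme@nIterations, " x ",
          scheme@nFolds, "-fold CV")
  result <- cvImmunoscore(dens, scheme, eventLabels = event)

  cutoffResults <- list()
  for (spec in cutoffs) {
    if (cutoffMethod(spec) == "youden")
      spec <- cvYoudenCutoff(dens, event, scheme, result = result)
    categorized <- categorize(result, spec)
    cutoffResults[[.cutoffName(spec)]] <-
      .cutoffReport(categorized, spec, time, event, cIndexOn)
  }

  new("CohortReport", stratum = stratumLabel, nPatients = length(ids),
      droppedIds = as.character(dropped), fractions = fractions,
      densities = dens, immunoscore = result,
      cutoffResults = cutoffResults, strata = list(),
      skippedStrata = character())
}

#' Per-histology stratified report
#'
#' Repeats the scoring, cut-off resolution (including stratum-specific
#' Youden optima) and survival stages independently within each stratum.
#' Cell fractions are deconvolved once for the joined cohort: the
#' deconvolution of a sample depends only on that sample's mixture and the
#' signature, so per-stratum re-deconvolution would be identical. Strata
#' with fewer patients than folds, no events, or (when a Youden cut-off is
#' requested) a single outcome class are skipped with a logged reason.
#'
#' @inheritParams analyzeCohort
#' @param strata per-patient histology labels, either named by patient id
#'   or aligned with \code{survivalData}.
#' @return A [CohortReport-class] whose \code{strata} slot holds one nested
#'   report per analyzable stratum and \code{skippedStrata} the reasons for
#'   the rest. The top level is the whole-cohort report.
#' @export
stratifiedReport <- function(expression, signature, survivalData, strata,
                             scheme = CVScheme(),
                             cutoffs = list(CutoffSpec(percentile = 25),
                                            CutoffSpec("youden")),
                             nuGrid = c(0.25, 0.5, 0.75),
                             cIndexOn = "category", verbose = FALSE) {
  if (is.null(names(strata)))
    names(strata) <- survivalData$patient_id
  whole <- analyzeCohort(expression, signature, survivalData, scheme,
                         cutoffs, nuGrid, cIndexOn = cIndexOn,
                         verbose = verbose)
  # reuse the whole-cohort fractions for every stratum
  frWhole <- whole@fractions
  ids <- patientIds(whole@immunoscore)
  strata <- strata[ids]
  hasYouden <- any(vapply(cutoffs, function(s)
    cutoffMethod(s) == "youden", logical(1)))
  reports <- list()
  skipped <- character()
  surv <- survivalData[match(ids, survivalData$patient_id), ]
  for (lev in unique(strata)) {
    sel <- ids[strata == lev]
    sSurv <- surv[surv$patient_id %in% sel, ]
    reason <- NULL
    if (length(sel) < scheme@nFolds)
      reason <- sprintf("fewer patients (%d) than folds", length(sel))
    else if (sum(sSurv$event) == 0)
      reason <- "no events"
    else if (hasYouden && length(unique(sSurv$event)) < 2)
      reason <- "single outcome class; Youden cut-off undefined"
    if (!is.null(reason)) {
      .logMsg(verbose, "skipping stratum '", lev, "': ", reason)
      skipped[lev] <- reason
      next
    }
    sub <- BulkExpression(exprValues(toLinearTPM(expression))[, sel,
                                                              drop = FALSE])
    reports[[lev]] <- analyzeCohort(sub, signature, sSurv, scheme, cutoffs,
                                    nuGrid, fractions = frWhole,
                                    cIndexOn = cIndexOn, stratumLabel = lev,
                                    verbose = verbose)
  }
  whole@strata <- reports
  whole@skippedStrata <- skipped
  whole
}

#' Run the full pipeline from files
#'
#' Reads the expression, signature and survival tables named in
#' \code{config}, executes [analyzeCohort()] (or [stratifiedReport()] when
#' a cancer-type table is given), and optionally writes the report JSON,
#' immunoscore and cell-fraction TSVs and per-category KM exports to
#' \code{config$outputDir}.
#'
#' @param config a named list (or the result of [readPipelineConfig()])
#'   with entries \code{expression}, \code{signature}, \code{survival}
#'   (file paths), \code{tCellTypes}, \code{cd8Type}, and optionally
#'   \code{cancerType} (path), \code{delimiter}, \code{nIterations},
#'   \code{nFolds}, \code{seed}, \code{stratifyOnEvent}, \code{cutoffs}
#'   (list of \code{list(method=, percentile=)}), \code{cIndexOn},
#'   \code{outputDir}, \code{verbose}.
#' @return A [CohortReport-class] object (invisibly when writing output).
#' @export
runPipeline <- function(config) {
  req <- c("expression", "signature", "survival", "tCellTypes", "cd8Type")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("pipeline config lacks: ", paste(missing, collapse = ", "))
  for (f in c("expression", "signature", "survival"))
    if (!file.exists(config[[f]])) stop("input file not found: ", config[[f]])
  delim <- config$delimiter %||% "\t"
  verbose <- isTRUE(config$verbose)

  expr <- readExpressionMatrix(config$expression, delim)
  sig <- readSignatureMatrix(config$signature, config$tCellTypes,
                             config$cd8Type, delim)
  surv <- utils::read.delim(config$survival, sep = delim)
  scheme <- CVScheme(nIterations = config$nIterations %||% 20L,
                     nFolds = config$nFolds %||% 5L,
                     seed = config$seed %||% 1L,
                     stratifyOnEvent = config$stratifyOnEvent %||% TRUE)
  cutoffs <- if (is.null(config$cutoffs))
    list(CutoffSpec(percentile = 25), CutoffSpec("youden"))
  else lapply(config$cutoffs, function(cc)
    CutoffSpec(cc$method %||% "fixed_percentile",
               percentile = cc$percentile %||% 25))
  cIndexOn <- config$cIndexOn %||% "category"

  report <- if (!is.null(config$cancerType)) {
    ct <- utils::read.delim(config$cancerType, sep = delim)
    stratifiedReport(expr, sig, surv,
                     stats::setNames(ct$cancer_type, ct$patient_id),
                     scheme, cutoffs, cIndexOn = cIndexOn, verbose = verbose)
  } else {
    analyzeCohort(expr, sig, surv, scheme, cutoffs, cIndexOn = cIndexOn,
                  verbose = verbose)
  }
  if (!is.null(config$outputDir)) {
    writeCohortReport(report, config$outputDir)
    return(invisible(report))
  }
  report
}

#' Read a pipeline configuration file
#'
#' YAML (when the yaml package is available) or JSON, holding the fields
#' documented in [runPipeline()]. Relative paths are resolved against the
#' config file's directory.
#'
#' @param path config file path (.yaml/.yml or .json).
#' @return A named list usable as the \code{config} of [runPipeline()].
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  config <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  base <- dirname(normalizePath(path))
  for (f in c("expression", "signature", "survival", "cancerType",
              "outputDir"))
    if (!is.null(config[[f]]) && !grepl("^(/|[A-Za-z]:)", config[[f]]))
      config[[f]] <- file.path(base, config[[f]])
  config
}

# nested report -> plain list for JSON serialization
.reportToList <- function(report) {
  kmToDf <- function(km) data.frame(time = km@time, survival = km@surv,
                                    ci_lower = km@lower, ci_upper = km@upper,
                                    n_at_risk = km@nRisk)
  crToList <- function(cr) {
    out <- list(method = cr$method, percentile = cr$percentile,
                n_low = cr$nLow, pct_low = cr$pctLow,
                logrank_chisq = unname(cr$logrank$statistic),
                logrank_p = cr$logrank$p.value,
                c_index_mean = cr$concordance$mean,
                c_index_ci = c(cr$concordance$ciLower,
                               cr$concordance$ciUpper))
    if (!is.null(cr$cox))
      out$cox <- cr$cox[c("logHR", "hr", "se", "ciLower", "ciUpper",
                          "p.value", "flagged")]
    if (!is.null(cr$note)) out$note <- cr$note
    out$km <- lapply(cr$km, kmToDf)
    out
  }
  list(stratum = report@stratum, n_patients = report@nPatients,
       dropped_ids = report@droppedIds,
       cutoffs = lapply(report@cutoffResults, crToList),
       skipped_strata = as.list(report@skippedStrata),
       strata = lapply(report@strata, .reportToList))
}

#' Write a cohort report to disk
#'
#' Emits \code{report.json} (the full nested report), \code{immunoscore.tsv}
#' and per-cut-off, per-category KM TSV exports; nested strata go to
#' subdirectories.
#'
#' @param report a [CohortReport-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, the report JSON path.
#' @export
writeCohortReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonPath <- file.path(dir, "report.json")
  jsonlite::write_json(.reportToList(report), jsonPath, auto_unbox = TRUE,
                       digits = 10, dataframe = "columns", pretty = TRUE)
  writeImmunoscoreResult(report@immunoscore,
                         file.path(dir, "immunoscore.tsv"))
  for (nm in names(report@cutoffResults)) {
    km <- report@cutoffResults[[nm]]$km
    for (g in names(km))
      writeKMCurve(km[[g]], file.path(dir, sprintf("km_%s_%s.tsv", nm, g)))
  }
  for (lev in names(report@strata))
    writeCohortReport(report@strata[[lev]],
                      file.path(dir, paste0("stratum_", gsub("\\W+", "_", lev))))
  invisible(jsonPath)
}
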
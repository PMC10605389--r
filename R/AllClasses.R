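#' @import methods
NULL

.EXPR_SCALES <- c("linear", "log2p1")

#' Bulk expression matrix (genes x samples)
#'
#' Container for a gene-by-sample abundance matrix. The deconvolution stage
#' requires linear-scale TPM; matrices encoded as log2(TPM+1) carry the
#' \code{"log2p1"} scale tag and are inverted by [toLinearTPM()].
#'
#' @slot values numeric matrix, genes in rows (unique rownames), samples in
#'   columns (unique colnames); non-negative when the scale tag is
#'   \code{"linear"}.
#' @slot scaleTag either \code{"linear"} or \code{"log2p1"}.
#'
#' @seealso [readExpressionMatrix()], [toLinearTPM()]
#' @exportClass BulkExpression
setClass("BulkExpression",
  representation(values = "matrix", scaleTag = "character"))

setValidity("BulkExpression", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have gene rownames and sample colnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate sample ids")
  }
  if (length(object@scaleTag) != 1L || !object@scaleTag %in% .EXPR_SCALES)
    msg <- c(msg, sprintf("scaleTag must be one of %s",
                          paste(.EXPR_SCALES, collapse = ", ")))
  if (is.numeric(v)) {
    if (anyNA(v) || any(!is.finite(v))) msg <- c(msg, "values must be finite")
    else if (identical(object@scaleTag, "linear") && any(v < 0))
      msg <- c(msg, "linear-scale values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a BulkExpression object
#'
#' @param values numeric gene-by-sample matrix with dimnames.
#' @param scaleTag \code{"linear"} (default) or \code{"log2p1"}.
#' @return A [BulkExpression-class] object.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' BulkExpression(m)
#' @export
BulkExpression <- function(values, scaleTag = "linear") {
  storage.mode(values) <- "double"
  new("BulkExpression", values = values, scaleTag = scaleTag)
}

#' Leukocyte signature matrix (genes x cell types)
#'
#' Reference expression profiles per immune cell type in LM22 layout,
#' together with the declared pan-T subsets (CD3+) and the single CD8+
#' subset used to derive T-cell densities.
#'
#' @slot values non-negative numeric matrix, genes in rows, cell types in
#'   columns.
#' @slot tCellTypes character, the cell types that constitute CD3+ T cells.
#' @slot cd8Type length-1 character, the CD8+ T-cell column; must be one of
#'   \code{tCellTypes}.
#'
#' @seealso [readSignatureMatrix()], [makeSignature()]
#' @exportClass SignatureMatrix
setClass("SignatureMatrix",
  representation(values = "matrix", tCellTypes = "character",
                 cd8Type = "character"))

setValidity("SignatureMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must have gene rownames and cell-type colnames")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate cell types")
    bad <- setdiff(object@tCellTypes, colnames(v))
    if (length(bad))
      msg <- c(msg, sprintf("declared T-cell types not in columns: %s",
                            paste(bad, collapse = ", ")))
  }
  if (length(object@cd8Type) != 1L)
    msg <- c(msg, "cd8Type must be a single cell type")
  else if (!object@cd8Type %in% object@tCellTypes)
    msg <- c(msg, "cd8Type must be one of the declared T-cell types")
  if (is.numeric(v) && (anyNA(v) || any(!is.finite(v)) || any(v < 0)))
    msg <- c(msg, "values must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureMatrix object
#'
#' @param values non-negative numeric gene-by-cell-type matrix with dimnames.
#' @param tCellTypes character vector of pan-T (CD3+) cell-type columns.
#' @param cd8Type the CD8+ T-cell column (must be in \code{tCellTypes}).
#' @return A [SignatureMatrix-class] object.
#' @export
SignatureMatrix <- function(values, tCellTypes, cd8Type) {
  storage.mode(values) <- "double"
  new("SignatureMatrix", values = values,
      tCellTypes = as.character(tCellTypes), cd8Type = as.character(cd8Type))
}

#' Deconvolved immune cell fractions
#'
#' Per-sample cell-type proportions estimated by [deconvolveCohort()],
#' with the goodness-of-fit statistics of the selected nu-SVR fit and
#' (optionally) gene-permutation p-values.
#'
#' @slot fractions numeric matrix, samples in rows (rownames = sample ids),
#'   cell types in columns; each row is non-negative and sums to 1.
#' @slot fitRMSE per-sample root-mean-square residual of the reconstructed
#'   standardized mixture.
#' @slot fitCorr per-sample Pearson correlation between reconstructed and
#'   observed standardized mixture.
#' @slot pValue per-sample permutation p-value (NA when not computed).
#'
#' @exportClass CellFractions
setClass("CellFractions",
  representation(fractions = "matrix", fitRMSE = "numeric",
                 fitCorr = "numeric", pValue = "numeric"))

setValidity("CellFractions", function(object) {
  f <- object@fractions
  msg <- character()
  n <- nrow(f)
  if (is.null(rownames(f)) || is.null(colnames(f)))
    msg <- c(msg, "fractions must have sample rownames and cell-type colnames")
  if (any(f < -1e-12)) msg <- c(msg, "fractions must be non-negative")
  if (n > 0 && any(abs(rowSums(f) - 1) > 1e-9))
    msg <- c(msg, "each fraction row must sum to 1 within 1e-9")
  for (s in c("fitRMSE", "fitCorr", "pValue"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("%s must have one entry per sample", s))
  cc <- object@fitCorr
  if (any(!is.na(cc) & (cc < -1 - 1e-12 | cc > 1 + 1e-12)))
    msg <- c(msg, "fitCorr must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Derived CD3+/CD8+ T-cell densities
#'
#' CD3 density is the summed fraction of the signature's declared pan-T
#' subsets; CD8 density is the fraction of the declared CD8+ subset, so
#' 0 <= cd8 <= cd3 <= 1 holds for every sample.
#'
#' @slot sampleIds character sample identifiers.
#' @slot cd3 numeric in [0, 1].
#' @slot cd8 numeric in [0, 1].
#'
#' @seealso [imputeTCellDensities()]
#' @exportClass TCellDensities
setClass("TCellDensities",
  representation(sampleIds = "character", cd3 = "numeric", cd8 = "numeric"))

setValidity("TCellDensities", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (length(object@cd3) != n || length(object@cd8) != n)
    msg <- c(msg, "sampleIds, cd3 and cd8 must have equal length")
  if (anyDuplicated(object@sampleIds)) msg <- c(msg, "duplicate sample ids")
  tol <- 1e-9
  if (any(object@cd8 < -tol) || any(object@cd3 > 1 + tol) ||
      any(object@cd8 > object@cd3 + tol))
    msg <- c(msg, "densities must satisfy 0 <= cd8 <= cd3 <= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a TCellDensities object
#' @param sampleIds character sample identifiers.
#' @param cd3,cd8 numeric densities in [0, 1] with \code{cd8 <= cd3}.
#' @return A [TCellDensities-class] object.
#' @export
TCellDensities <- function(sampleIds, cd3, cd8) {
  new("TCellDensities", sampleIds = as.character(sampleIds),
      cd3 = as.numeric(cd3), cd8 = as.numeric(cd8))
}

#' Cross-validation scheme for the immunoscore
#'
#' @slot nIterations number of repeated cross-validation iterations
#'   (default 20).
#' @slot nFolds number of folds per iteration (default 5, must be >= 2).
#' @slot seed integer seed for fold assignment.
#' @slot stratifyOnEvent when TRUE, fold assignment is stratified by the
#'   event indicator so every training split contains both classes.
#'
#' @exportClass CVScheme
setClass("CVScheme",
  representation(nIterations = "integer", nFolds = "integer",
                 seed = "integer", stratifyOnEvent = "logical"))

setValidity("CVScheme", function(object) {
  msg <- character()
  if (object@nIterations < 1L) msg <- c(msg, "nIterations must be >= 1")
  if (object@nFolds < 2L) msg <- c(msg, "nFolds must be >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct a CVScheme
#' @param nIterations repeated CV iterations (default 20).
#' @param nFolds folds per iteration (default 5).
#' @param seed integer fold-assignment seed.
#' @param stratifyOnEvent stratify folds by event indicator (default TRUE).
#' @return A [CVScheme-class] object.
#' @examples
#' CVScheme(seed = 7)
#' @export
CVScheme <- function(nIterations = 20L, nFolds = 5L, seed = 1L,
                     stratifyOnEvent = TRUE) {
  new("CVScheme", nIterations = as.integer(nIterations),
      nFolds = as.integer(nFolds), seed = as.integer(seed),
      stratifyOnEvent = isTRUE(stratifyOnEvent))
}

#' Immunoscore dichotomization cut-off
#'
#' Either a fixed percentile (default 25, the classical lower-quartile rule)
#' or a Youden-J-optimized percentile resolved by [cvYoudenCutoff()].
#'
#' @slot method \code{"fixed_percentile"} or \code{"youden"}.
#' @slot percentile requested percentile for the fixed method, in (0, 100).
#' @slot resolvedPercentile operative percentile; equals \code{percentile}
#'   for the fixed method, and the cross-validation-averaged Youden optimum
#'   once resolved (NA before resolution).
#'
#' @exportClass CutoffSpec
setClass("CutoffSpec",
  representation(method = "character", percentile = "numeric",
                 resolvedPercentile = "numeric"))

setValidity("CutoffSpec", function(object) {
  msg <- character()
  if (!object@method %in% c("fixed_percentile", "youden"))
    msg <- c(msg, "method must be 'fixed_percentile' or 'youden'")
  p <- object@percentile
  if (identical(object@method, "fixed_percentile") &&
      (is.na(p) || p <= 0 || p >= 100))
    msg <- c(msg, "percentile must lie strictly inside (0, 100)")
  r <- object@resolvedPercentile
  if (!is.na(r) && (r <= 0 || r >= 100))
    msg <- c(msg, "resolvedPercentile must lie strictly inside (0, 100)")
  if (length(msg)) msg else TRUE
})

#' Construct a CutoffSpec
#' @param method \code{"fixed_percentile"} (default) or \code{"youden"}.
#' @param percentile fixed percentile in (0, 100); default 25.
#' @return A [CutoffSpec-class] object.
#' @examples
#' CutoffSpec()                  # fixed 25th percentile
#' CutoffSpec("youden")          # to be resolved by cvYoudenCutoff()
#' @export
CutoffSpec <- function(method = c("fixed_percentile", "youden"),
                       percentile = 25) {
  method <- match.arg(method)
  resolved <- if (method == "fixed_percentile") as.numeric(percentile)
              else NA_real_
  new("CutoffSpec", method = method, percentile = as.numeric(percentile),
      resolvedPercentile = resolved)
}

#' Cross-validated immunoscore result
#'
#' @slot patientIds character patient identifiers.
#' @slot score final immunoscore in [0, 100], the mean of the per-iteration
#'   scores.
#' @slot perIterationScores patients x iterations matrix of fold-held-out
#'   percentile scores.
#' @slot category integer 0 (low) / 1 (intermediate-high); NA before
#'   [categorize()] is applied.
#' @slot cutoffUsed the [CutoffSpec-class] applied by [categorize()], or
#'   NULL.
#'
#' @exportClass ImmunoscoreResult
setClass("ImmunoscoreResult",
  representation(patientIds = "character", score = "numeric",
                 perIterationScores = "matrix", category = "integer",
                 cutoffUsed = "ANY"))

setValidity("ImmunoscoreResult", function(object) {
  msg <- character()
  n <- length(object@patientIds)
  if (length(object@score) != n || nrow(object@perIterationScores) != n ||
      length(object@category) != n)
    msg <- c(msg, "per-patient fields must have equal length")
  s <- object@score
  if (any(s < -1e-9 | s > 100 + 1e-9)) msg <- c(msg, "scores must lie in [0, 100]")
  if (n > 0 && any(abs(s - rowMeans(object@perIterationScores)) > 1e-9))
    msg <- c(msg, "score must equal the row mean of perIterationScores")
  cat <- object@category
  if (any(!is.na(cat) & !cat %in% c(0L, 1L)))
    msg <- c(msg, "category must be 0, 1 or NA")
  if (length(msg)) msg else TRUE
})

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood-variance 95% confidence bands on
#' the log(-log) scale, clamped to [0, 1].
#'
#' @slot time increasing follow-up times (months).
#' @slot surv non-increasing survival probabilities starting from 1.
#' @slot lower,upper 95% confidence band.
#' @slot nRisk number at risk just before each time.
#' @slot nEvent number of deaths at each time.
#'
#' @seealso [kaplanMeier()], [kmMedian()]
#' @exportClass KMCurve
setClass("KMCurve",
  representation(time = "numeric", surv = "numeric", lower = "numeric",
                 upper = "numeric", nRisk = "numeric", nEvent = "numeric"))

setValidity("KMCurve", function(object) {
  msg <- character()
  k <- length(object@time)
  for (s in c("surv", "lower", "upper", "nRisk", "nEvent"))
    if (length(slot(object, s)) != k)
      msg <- c(msg, sprintf("%s must match the number of time points", s))
  if (is.unsorted(object@time)) msg <- c(msg, "time must be increasing")
  sv <- object@surv
  if (any(sv < -1e-12 | sv > 1 + 1e-12)) msg <- c(msg, "survival must lie in [0, 1]")
  if (k > 1 && any(diff(sv) > 1e-12)) msg <- c(msg, "survival must be non-increasing")
  if (any(object@lower > sv + 1e-9) || any(object@upper < sv - 1e-9))
    msg <- c(msg, "confidence band must bracket the survival estimate")
  if (length(msg)) msg else TRUE
})

#' Synthetic cohort generator configuration
#'
#' Defines the ground-truth study conditions for [simulateCohort()]: an
#' LM22-sized signature, Dirichlet cell fractions, multiplicative log-normal
#' expression noise, and exponential survival whose hazard decreases with
#' CD3 T-cell abundance.
#'
#' @slot nGenes,nCellTypes,nTCellTypes signature dimensions (defaults
#'   547 x 22 with 7 T subsets).
#' @slot nPatients cohort size.
#' @slot dirichletConcentration Dirichlet concentration per cell type
#'   (recycled; default 2).
#' @slot noiseSd sd of the multiplicative log-normal expression noise.
#' @slot baselineHazard events/month at the mean CD3 density.
#' @slot logHrPerUnitCd3 log hazard ratio per unit CD3 fraction (negative =
#'   protective).
#' @slot censoringRate probability a record is right-censored.
#' @slot nCancerTypes number of round-robin-assigned histology labels.
#' @slot seed integer generator seed.
#'
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(nGenes = "integer", nCellTypes = "integer",
                 nTCellTypes = "integer", nPatients = "integer",
                 dirichletConcentration = "numeric", noiseSd = "numeric",
                 baselineHazard = "numeric", logHrPerUnitCd3 = "numeric",
                 censoringRate = "numeric", nCancerTypes = "integer",
                 seed = "integer"))

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nGenes < 1L || object@nCellTypes < 1L || object@nPatients < 1L ||
      object@nTCellTypes < 1L || object@nCancerTypes < 1L)
    msg <- c(msg, "all counts must be positive")
  if (object@nTCellTypes >= object@nCellTypes)
    msg <- c(msg, "nTCellTypes must be smaller than nCellTypes")
  if (any(object@dirichletConcentration <= 0))
    msg <- c(msg, "dirichletConcentration must be positive")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
  if (object@censoringRate < 0 || object@censoringRate >= 1)
    msg <- c(msg, "censoringRate must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticConfig
#'
#' Defaults encode the emulated study conditions: a 547 x 22 signature with
#' seven T subsets, symmetric Dirichlet(2) fractions (mean CD3 content
#' ~7/22), noise sd 0.3, baseline hazard log(2)/10.5 per month (10.5-month
#' median at the mean CD3), a protective CD3 effect, and 47% censoring.
#'
#' @param nPatients cohort size (required).
#' @param nGenes,nCellTypes,nTCellTypes signature dimensions.
#' @param dirichletConcentration per-type Dirichlet concentration (recycled).
#' @param noiseSd multiplicative log-normal expression noise sd.
#' @param baselineHazard events/month at mean CD3 density.
#' @param logHrPerUnitCd3 log hazard ratio per unit CD3 fraction.
#' @param censoringRate right-censoring probability in [0, 1).
#' @param nCancerTypes number of histology strata (round-robin).
#' @param seed integer seed.
#' @return A [SyntheticConfig-class] object.
#' @examples
#' SyntheticConfig(nPatients = 100, seed = 1)
#' @export
SyntheticConfig <- function(nPatients, nGenes = 547L, nCellTypes = 22L,
                            nTCellTypes = 7L, dirichletConcentration = 2,
                            noiseSd = 0.3,
                            baselineHazard = log(2) / 10.5,
                            logHrPerUnitCd3 = -8,
                            censoringRate = 0.47, nCancerTypes = 4L,
                            seed = 1L) {
  new("SyntheticConfig", nGenes = as.integer(nGenes),
      nCellTypes = as.integer(nCellTypes),
      nTCellTypes = as.integer(nTCellTypes),
      nPatients = as.integer(nPatients),
      dirichletConcentration = as.numeric(dirichletConcentration),
      noiseSd = as.numeric(noiseSd),
      baselineHazard = as.numeric(baselineHazard),
      logHrPerUnitCd3 = as.numeric(logHrPerUnitCd3),
      censoringRate = as.numeric(censoringRate),
      nCancerTypes = as.integer(nCancerTypes), seed = as.integer(seed))
}

#' Synthetic cohort with known ground truth
#'
#' @slot signature the generating [SignatureMatrix-class].
#' @slot trueFractions patients x cell types matrix of true Dirichlet
#'   fractions (rows sum to 1).
#' @slot expression the noisy bulk [BulkExpression-class] mixture
#'   (TPM-scaled columns).
#' @slot survival data.frame with columns patient_id, time (months), event.
#' @slot cancerType per-patient histology label.
#'
#' @seealso [simulateCohort()]
#' @exportClass SyntheticCohort
setClass("SyntheticCohort",
  representation(signature = "SignatureMatrix", trueFractions = "matrix",
                 expression = "BulkExpression", survival = "data.frame",
                 cancerType = "character"))

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  n <- nrow(object@trueFractions)
  if (ncol(object@expression@values) != n ||
      nrow(object@survival) != n || length(object@cancerType) != n)
    msg <- c(msg, "per-patient components must have consistent dimensions")
  if (n > 0 && any(abs(rowSums(object@trueFractions) - 1) > 1e-9))
    msg <- c(msg, "true fraction rows must sum to 1")
  if (!all(c("patient_id", "time", "event") %in% names(object@survival)))
    msg <- c(msg, "survival must have patient_id, time, event columns")
  if (length(msg)) msg else TRUE
})

#' Whole-cohort or per-stratum analysis report
#'
#' Mirrors the layout of a stratified immunoscore report: for each cut-off,
#' the low-category count and percentage, log-rank test, Cox hazard ratio,
#' CV-aggregated Harrell C-index and Kaplan-Meier curves per category;
#' optionally one nested report per histology stratum.
#'
#' @slot stratum label of the stratum ("" for the whole cohort).
#' @slot nPatients number of analyzed patients after the id join.
#' @slot droppedIds ids present in only some inputs, dropped by the join.
#' @slot fractions the deconvolved [CellFractions-class].
#' @slot densities the [TCellDensities-class] used for scoring.
#' @slot immunoscore the uncategorized [ImmunoscoreResult-class].
#' @slot cutoffResults named list, one entry per cut-off (see
#'   [runPipeline()]).
#' @slot strata named list of per-stratum CohortReport objects (empty for
#'   plain whole-cohort runs).
#' @slot skippedStrata named character of skip reasons for strata that were
#'   too small or degenerate.
#'
#' @exportClass CohortReport
setClass("CohortReport",
  representation(stratum = "character", nPatients = "integer",
                 droppedIds = "character", fractions = "ANY",
                 densities = "ANY", immunoscore = "ANY",
                 cutoffResults = "list", strata = "list",
                 skippedStrata = "character"))
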
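# Generics and accessors. Slot access from user code goes through these.

#' @name accessors
#' @title Accessors for immunoscoreTx classes
#' @description Small accessor generics: expression values, identifiers,
#'   declared T-cell subsets, deconvolved fractions and fit statistics,
#'   densities, scores and categories.
#' @param x an immunoscoreTx object.
#' @return The corresponding slot content (see the class documentation).
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A","B","C"), c("s1","s2")))
#' be <- BulkExpression(m)
#' geneIds(be); sampleIds(be); scaleTag(be)
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("scaleTag", function(x) standardGeneric("scaleTag"))
#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname accessors
#' @export
setGeneric("tCellTypes", function(x) standardGeneric("tCellTypes"))
#' @rdname accessors
#' @export
setGeneric("cd8Type", function(x) standardGeneric("cd8Type"))
#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))
#' @rdname accessors
#' @export
setGeneric("fitRMSE", function(x) standardGeneric("fitRMSE"))
#' @rdname accessors
#' @export
setGeneric("fitCorr", function(x) standardGeneric("fitCorr"))
#' @rdname accessors
#' @export
setGeneric("pValues", function(x) standardGeneric("pValues"))
#' @rdname accessors
#' @export
setGeneric("cd3", function(x) standardGeneric("cd3"))
#' @rdname accessors
#' @export
setGeneric("cd8", function(x) standardGeneric("cd8"))
#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("perIterationScores",
           function(x) standardGeneric("perIterationScores"))
#' @rdname accessors
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))
#' @rdname accessors
#' @export
setGeneric("cutoffUsed", function(x) standardGeneric("cutoffUsed"))
#' @rdname accessors
#' @export
setGeneric("resolvedPercentile",
           function(x) standardGeneric("resolvedPercentile"))
#' @rdname accessors
#' @export
setGeneric("cutoffMethod", function(x) standardGeneric("cutoffMethod"))
#' @rdname accessors
#' @export
setGeneric("trueFractions", function(x) standardGeneric("trueFractions"))
#' @rdname accessors
#' @export
setGeneric("survivalRecords", function(x) standardGeneric("survivalRecords"))
#' @rdname accessors
#' @export
setGeneric("cancerTypes", function(x) standardGeneric("cancerTypes"))
#' @rdname accessors
#' @export
setGeneric("signatureMatrix", function(x) standardGeneric("signatureMatrix"))

#' @describeIn accessors gene-by-sample matrix of a BulkExpression.
setMethod("exprValues", "BulkExpression", function(x) x@values)
#' @describeIn accessors gene ids of a BulkExpression.
setMethod("geneIds", "BulkExpression", function(x) rownames(x@values))
#' @describeIn accessors sample ids of a BulkExpression.
setMethod("sampleIds", "BulkExpression", function(x) colnames(x@values))
#' @describeIn accessors scale tag ("linear" or "log2p1").
setMethod("scaleTag", "BulkExpression", function(x) x@scaleTag)

#' @describeIn accessors gene-by-cell-type matrix of a SignatureMatrix.
setMethod("exprValues", "SignatureMatrix", function(x) x@values)
#' @describeIn accessors gene ids of a SignatureMatrix.
setMethod("geneIds", "SignatureMatrix", function(x) rownames(x@values))
#' @describeIn accessors all cell types of a SignatureMatrix.
setMethod("cellTypes", "SignatureMatrix", function(x) colnames(x@values))
#' @describeIn accessors declared pan-T (CD3+) subsets.
setMethod("tCellTypes", "SignatureMatrix", function(x) x@tCellTypes)
#' @describeIn accessors declared CD8+ subset.
setMethod("cd8Type", "SignatureMatrix", function(x) x@cd8Type)

#' @describeIn accessors samples x cell-types fraction matrix.
setMethod("fractions", "CellFractions", function(x) x@fractions)
#' @describeIn accessors sample ids of a CellFractions.
setMethod("sampleIds", "CellFractions", function(x) rownames(x@fractions))
#' @describeIn accessors cell types of a CellFractions.
setMethod("cellTypes", "CellFractions", function(x) colnames(x@fractions))
#' @describeIn accessors per-sample RMSE of the selected fit.
setMethod("fitRMSE", "CellFractions", function(x) x@fitRMSE)
#' @describeIn accessors per-sample correlation of the selected fit.
setMethod("fitCorr", "CellFractions", function(x) x@fitCorr)
#' @describeIn accessors per-sample permutation p-values (NA if not run).
setMethod("pValues", "CellFractions", function(x) x@pValue)

#' @describeIn accessors sample ids of a TCellDensities.
setMethod("sampleIds", "TCellDensities", function(x) x@sampleIds)
#' @describeIn accessors CD3+ (pan-T) density per sample.
setMethod("cd3", "TCellDensities", function(x) x@cd3)
#' @describeIn accessors CD8+ density per sample.
setMethod("cd8", "TCellDensities", function(x) x@cd8)

#' @describeIn accessors patient ids of an ImmunoscoreResult.
setMethod("patientIds", "ImmunoscoreResult", function(x) x@patientIds)
#' @describeIn accessors final CV-averaged immunoscores in [0, 100].
setMethod("scores", "ImmunoscoreResult", function(x) x@score)
#' @describeIn accessors patients x iterations score matrix.
setMethod("perIterationScores", "ImmunoscoreResult",
          function(x) x@perIterationScores)
#' @describeIn accessors 0/1 categories (NA before categorize()).
setMethod("categories", "ImmunoscoreResult", function(x) x@category)
#' @describeIn accessors CutoffSpec applied by categorize(), or NULL.
setMethod("cutoffUsed", "ImmunoscoreResult", function(x) x@cutoffUsed)

#' @describeIn accessors operative percentile of a CutoffSpec.
setMethod("resolvedPercentile", "CutoffSpec",
          function(x) x@resolvedPercentile)
#' @describeIn accessors cut-off method name.
setMethod("cutoffMethod", "CutoffSpec", function(x) x@method)

#' @describeIn accessors generating signature of a SyntheticCohort.
setMethod("signatureMatrix", "SyntheticCohort", function(x) x@signature)
#' @describeIn accessors ground-truth fraction matrix.
setMethod("trueFractions", "SyntheticCohort", function(x) x@trueFractions)
#' @describeIn accessors noisy bulk expression of a SyntheticCohort.
setMethod("exprValues", "SyntheticCohort",
          function(x) x@expression@values)
#' @describeIn accessors survival data.frame (patient_id, time, event).
setMethod("survivalRecords", "SyntheticCohort", function(x) x@survival)
#' @describeIn accessors per-patient histology labels.
setMethod("cancerTypes", "SyntheticCohort", function(x) x@cancerType)

setMethod("show", "BulkExpression", function(object) {
  v <- object@values
  cat(sprintf("BulkExpression: %d genes x %d samples (%s scale)\n",
              nrow(v), ncol(v), object@scaleTag))
})

setMethod("show", "SignatureMatrix", function(object) {
  v <- object@values
  cat(sprintf("SignatureMatrix: %d genes x %d cell types\n", nrow(v), ncol(v)))
  cat(sprintf("  CD3+ subsets (%d): %s\n", length(object@tCellTypes),
              paste(object@tCellTypes, collapse = ", ")))
  cat(sprintf("  CD8+ subset: %s\n", object@cd8Type))
})

setMethod("show", "CellFractions", function(object) {
  f <- object@fractions
  cat(sprintf("CellFractions: %d samples x %d cell types\n", nrow(f), ncol(f)))
  cat(sprintf("  fit correlation: median %.3f | permutation p: %s\n",
              stats::median(object@fitCorr),
              if (all(is.na(object@pValue))) "not computed"
              else sprintf("%d/%d < 0.05", sum(object@pValue < 0.05),
                           length(object@pValue))))
})

setMethod("show", "TCellDensities", function(object) {
  cat(sprintf("TCellDensities: %d samples | mean CD3 %.3f, mean CD8 %.3f\n",
              length(object@sampleIds), mean(object@cd3), mean(object@cd8)))
})

setMethod("show", "CVScheme", function(object) {
  cat(sprintf("CVScheme: %d iterations x %d folds (seed %d%s)\n",
              object@nIterations, object@nFolds, object@seed,
              if (object@stratifyOnEvent) ", event-stratified" else ""))
})

setMethod("show", "CutoffSpec", function(object) {
  cat(sprintf("CutoffSpec: %s at percentile %s\n", object@method,
              if (is.na(object@resolvedPercentile)) "<unresolved>"
              else format(object@resolvedPercentile)))
})

setMethod("show", "ImmunoscoreResult", function(object) {
  cat(sprintf("ImmunoscoreResult: %d patients, %d CV iterations\n",
              length(object@patientIds), ncol(object@perIterationScores)))
  if (!all(is.na(object@category)))
    cat(sprintf("  low (0): %d | intermediate-high (1): %d\n",
                sum(object@category == 0L), sum(object@category == 1L)))
})

setMethod("show", "KMCurve", function(object) {
  med <- kmMedian(object)
  cat(sprintf("KMCurve: %d time points, %d events, median %s\n",
              length(object@time), sum(object@nEvent),
              if (is.na(med)) "not reached" else sprintf("%.2f months", med)))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf("SyntheticCohort: %d patients, %d genes, %d cell types\n",
              nrow(object@trueFractions), nrow(object@signature@values),
              ncol(object@trueFractions)))
  cat(sprintf("  events: %d | strata: %s\n", sum(object@survival$event),
              paste(unique(object@cancerType), collapse = ", ")))
})

setMethod("show", "CohortReport", function(object) {
  lab <- if (nzchar(object@stratum)) object@stratum else "whole cohort"
  cat(sprintf("CohortReport [%s]: %d patients\n", lab, object@nPatients))
  for (nm in names(object@cutoffResults)) {
    cr <- object@cutoffResults[[nm]]
    cat(sprintf(
      "  %-16s pct %5.1f | low %3d (%4.1f%%) | C %.4f (%.4f, %.4f) | log-rank p %.3g\n",
      nm, cr$percentile, cr$nLow, cr$pctLow, cr$concordance$mean,
      cr$concordance$ciLower, cr$concordance$ciUpper, cr$logrank$p.value))
  }
  if (length(object@strata))
    cat(sprintf("  strata: %s\n", paste(names(object@strata), collapse = ", ")))
  if (length(object@skippedStrata))
    cat(sprintf("  skipped: %s\n",
                paste(names(object@skippedStrata), collapse = ", ")))
})
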
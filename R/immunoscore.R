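# Cross-validated percentile immunoscore.
# Each patient's score is the mean of the empirical percentiles of their
# CD3 and CD8 densities among a training population; repeated k-fold
# cross-validation keeps every patient's percentile out-of-fold, and the
# final score averages the iteration scores.

#' Mid-rank empirical percentile
#'
#' Percentile of \code{query} among \code{training} under the mid-rank
#' convention: \code{100 * (#\{t < q\} + 0.5 * #\{t = q\}) / n}. Ties are
#' split symmetrically, so a query equal to every training value sits at 50.
#'
#' @param training non-empty numeric training values.
#' @param query numeric vector of query values.
#' @return Percentiles in [0, 100], one per query.
#' @examples
#' empiricalPercentile(c(10, 20, 30, 40), 25)  # 50
#' empiricalPercentile(c(5, 5, 5, 5), 5)       # 50
#' @export
empiricalPercentile <- function(training, query) {
  if (!length(training)) stop("training values must be non-empty")
  st <- sort(training)
  n <- length(st)
  less <- findInterval(query, st, left.open = TRUE)  # #{t < q}
  leq <- findInterval(query, st)                     # #{t <= q}
  100 * (less + 0.5 * (leq - less)) / n
}

#' Combine CD3 and CD8 percentiles into one score
#'
#' The immunoscore of a patient in a given training context is the
#' arithmetic mean of the CD3 and CD8 density percentiles.
#'
#' @param cd3Percentile,cd8Percentile percentiles in [0, 100] (vectorized).
#' @return The mean of the two, in [0, 100].
#' @examples
#' pairPercentileScore(80, 40)  # 60
#' @export
pairPercentileScore <- function(cd3Percentile, cd8Percentile) {
  if (any(cd3Percentile < 0 | cd3Percentile > 100) ||
      any(cd8Percentile < 0 | cd8Percentile > 100))
    stop("percentiles must lie in [0, 100]")
  (cd3Percentile + cd8Percentile) / 2
}

# Fold assignments for every iteration: n x nIterations integer matrix.
# Balanced shuffled assignment, optionally stratified so each stratum is
# spread evenly over folds. One RNG stream seeded once => deterministic.
.foldMatrix <- function(n, scheme, strata = NULL) {
  if (n < scheme@nFolds) stop("fewer patients (", n, ") than folds (",
                              scheme@nFolds, ")")
  set.seed(scheme@seed)
  k <- scheme@nFolds
  out <- matrix(NA_integer_, n, scheme@nIterations)
  groups <- if (is.null(strata)) list(seq_len(n))
            else split(seq_len(n), strata)
  for (it in seq_len(scheme@nIterations))
    for (idx in groups)
      out[idx, it] <- sample(rep_len(seq_len(k), length(idx)))
  out
}

# Scores of every patient for one iteration's fold assignment: each fold is
# scored against the percentile functions of the remaining folds.
.iterationScores <- function(cd3v, cd8v, folds) {
  s <- numeric(length(cd3v))
  for (f in unique(folds)) {
    te <- folds == f
    tr <- !te
    s[te] <- pairPercentileScore(empiricalPercentile(cd3v[tr], cd3v[te]),
                                 empiricalPercentile(cd8v[tr], cd8v[te]))
  }
  s
}

#' Cross-validated percentile immunoscore
#'
#' For each of \code{nIterations} repeated partitions into
#' \code{nFolds} folds, the patients of every held-out fold are scored with
#' [pairPercentileScore()] against the percentile functions defined by the
#' remaining folds; the final immunoscore is the mean of the per-iteration
#' scores. Deterministic given the scheme's seed.
#'
#' @param densities a [TCellDensities-class].
#' @param scheme a [CVScheme-class]; with \code{stratifyOnEvent = TRUE} and
#'   \code{eventLabels} supplied, folds are stratified by event status.
#' @param eventLabels optional binary event indicator used only for fold
#'   stratification.
#' @return An [ImmunoscoreResult-class] with categories unset.
#' @export
cvImmunoscore <- function(densities, scheme = CVScheme(), eventLabels = NULL) {
  stopifnot(is(densities, "TCellDensities"), is(scheme, "CVScheme"))
  n <- length(sampleIds(densities))
  strata <- if (scheme@stratifyOnEvent && !is.null(eventLabels)) {
    stopifnot(length(eventLabels) == n)
    eventLabels
  } else NULL
  folds <- .foldMatrix(n, scheme, strata)
  per <- vapply(seq_len(scheme@nIterations), function(it)
    .iterationScores(cd3(densities), cd8(densities), folds[, it]),
    numeric(n))
  per <- matrix(per, nrow = n,
                dimnames = list(sampleIds(densities),
                                paste0("iter", seq_len(scheme@nIterations))))
  new("ImmunoscoreResult", patientIds = sampleIds(densities),
      score = rowMeans(per), perIterationScores = per,
      category = rep(NA_integer_, n), cutoffUsed = NULL)
}

#' Youden-J-optimal cut-off on a score
#'
#' Treats label 1 (death) as the positive class and "score < c" as test
#' positive, scans candidate thresholds and returns the one maximizing
#' Youden's J = sensitivity + specificity - 1. Default candidates are the
#' midpoints between consecutive distinct sorted scores plus one sentinel
#' below the minimum and one above the maximum, so every possible
#' dichotomization is scanned; ties in J break toward the smallest cut-off.
#'
#' @param scores numeric scores (higher = more protective).
#' @param labels binary outcome labels (1 = death).
#' @param candidates optional explicit candidate thresholds.
#' @return A list with \code{cutoff} and \code{J}.
#' @examples
#' youdenCutoff(c(1, 2, 3, 4), c(1, 1, 0, 0))  # cutoff 2.5, J = 1
#' @export
youdenCutoff <- function(scores, labels, candidates = NULL) {
  stopifnot(length(scores) == length(labels))
  if (length(unique(labels)) < 2)
    stop("both outcome classes must be present")
  if (is.null(candidates)) {
    ds <- sort(unique(scores))
    mids <- if (length(ds) > 1) (ds[-1] + ds[-length(ds)]) / 2 else numeric()
    candidates <- c(ds[1] - 1, mids, ds[length(ds)] + 1)
  }
  candidates <- sort(candidates)
  pos <- labels == 1
  J <- vapply(candidates, function(cc) {
    testPos <- scores < cc
    mean(testPos[pos]) + mean(!testPos[!pos]) - 1
  }, numeric(1))
  # smallest candidate on ties; 1e-9 absorbs float noise between
  # mathematically equal J values (true J differences are >= 1/n^2)
  best <- which(J >= max(J) - 1e-9)[1]
  list(cutoff = candidates[best], J = J[best])
}

#' Cross-validation-averaged Youden cut-off percentile
#'
#' For every CV iteration, computes the Youden-optimal cut-off on that
#' iteration's immunoscores against the event labels, expresses it as a
#' mid-rank percentile of that iteration's score distribution, and averages
#' the per-iteration percentiles into the resolved cut-off.
#'
#' @param densities a [TCellDensities-class].
#' @param eventLabels binary event indicator (1 = death), one per patient.
#' @param scheme a [CVScheme-class]; the same scheme (and labels, when
#'   stratifying) as used for [cvImmunoscore()] reproduces the same folds.
#' @param result optional precomputed [ImmunoscoreResult-class] from
#'   [cvImmunoscore()] under the same scheme, to avoid re-scoring.
#' @return A resolved [CutoffSpec-class] with method \code{"youden"}.
#' @export
cvYoudenCutoff <- function(densities, eventLabels, scheme = CVScheme(),
                           result = NULL) {
  stopifnot(is(densities, "TCellDensities"))
  n <- length(sampleIds(densities))
  stopifnot(length(eventLabels) == n)
  if (length(unique(eventLabels)) < 2)
    stop("both outcome classes must be present")
  if (is.null(result))
    result <- cvImmunoscore(densities, scheme, eventLabels)
  per <- perIterationScores(result)
  pcts <- vapply(seq_len(ncol(per)), function(it) {
    s <- per[, it]
    cut <- youdenCutoff(s, eventLabels)$cutoff
    empiricalPercentile(s, cut)
  }, numeric(1))
  new("CutoffSpec", method = "youden", percentile = NA_real_,
      resolvedPercentile = mean(pcts))
}

#' Assign low / intermediate-high immunoscore categories
#'
#' The threshold is the cut-off percentile of \code{referenceScores}
#' (default: the cohort's own final scores); patients strictly below it are
#' category 0 ("low"), all others — including exact ties — category 1
#' ("intermediate-high").
#'
#' @param result an [ImmunoscoreResult-class].
#' @param cutoff a resolved [CutoffSpec-class].
#' @param referenceScores scores defining the threshold quantile.
#' @return The [ImmunoscoreResult-class] with categories and
#'   \code{cutoffUsed} set.
#' @export
categorize <- function(result, cutoff = CutoffSpec(),
                       referenceScores = scores(result)) {
  stopifnot(is(result, "ImmunoscoreResult"), is(cutoff, "CutoffSpec"))
  p <- resolvedPercentile(cutoff)
  if (is.na(p)) stop("cut-off is unresolved; run cvYoudenCutoff() first")
  thr <- as.numeric(stats::quantile(referenceScores, p / 100, names = FALSE))
  result@category <- as.integer(scores(result) >= thr)
  result@cutoffUsed <- cutoff
  validObject(result)
  result
}

#' Write an immunoscore result as TSV
#'
#' @param x an [ImmunoscoreResult-class].
#' @param path output path.
#' @param perIteration include the per-iteration score columns.
#' @return Invisibly, \code{path}.
#' @export
writeImmunoscoreResult <- function(x, path, perIteration = FALSE) {
  df <- data.frame(patient_id = patientIds(x), score = scores(x),
                   category = categories(x))
  if (perIteration) df <- cbind(df, perIterationScores(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
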
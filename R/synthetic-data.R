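# Ground-truth cohort generator. Every downstream stage (deconvolution,
# scoring, survival) can be exercised against known cell fractions and a
# known protective T-cell effect without any external data.

.LM22_TYPE_NAMES <- c(
  "T cells CD8", "T cells CD4 naive", "T cells CD4 memory resting",
  "T cells CD4 memory activated", "T cells follicular helper",
  "T cells regulatory (Tregs)", "T cells gamma delta",
  "B cells naive", "B cells memory", "Plasma cells",
  "NK cells resting", "NK cells activated", "Monocytes",
  "Macrophages M0", "Macrophages M1", "Macrophages M2",
  "Dendritic cells resting", "Dendritic cells activated",
  "Mast cells resting", "Mast cells activated", "Eosinophils", "Neutrophils")

#' Generate a well-conditioned synthetic signature matrix
#'
#' Draws log-normal baseline profiles and assigns each cell type a disjoint
#' block of marker genes with a strong (~12-fold) expression increase, which
#' keeps the globally standardized matrix well conditioned. The first
#' \code{nTCellTypes} types are declared as the pan-T (CD3+) subsets and
#' the first of them as the CD8+ subset. With the default 22 types the
#' columns carry LM22-style leukocyte names.
#'
#' @param nGenes number of genes (default 547; must be at least
#'   \code{2 * nCellTypes} so every type gets >= 2 markers).
#' @param nCellTypes number of cell types (default 22).
#' @param nTCellTypes number of declared T subsets (default 7).
#' @param seed integer seed; the same seed reproduces the matrix bitwise.
#' @return A [SignatureMatrix-class] object.
#' @examples
#' makeSignature(nGenes = 60, nCellTypes = 4, nTCellTypes = 2, seed = 1)
#' @export
makeSignature <- function(nGenes = 547L, nCellTypes = 22L, nTCellTypes = 7L,
                          seed = 1L) {
  if (nTCellTypes >= nCellTypes)
    stop("nTCellTypes must be smaller than nCellTypes")
  if (nGenes < 2L * nCellTypes)
    stop("infeasible marker allocation: need nGenes >= 2 * nCellTypes")
  set.seed(seed)
  types <- if (nCellTypes <= length(.LM22_TYPE_NAMES) && nTCellTypes <= 7L)
    .LM22_TYPE_NAMES[c(seq_len(nTCellTypes),
                       seq.int(8L, length.out = nCellTypes - nTCellTypes))]
  else c(sprintf("T type %02d", seq_len(nTCellTypes)),
         sprintf("Cell type %02d", seq_len(nCellTypes - nTCellTypes)))
  genes <- sprintf("G%04d", seq_len(nGenes))
  S <- matrix(stats::rlnorm(nGenes * nCellTypes, meanlog = log(3),
                            sdlog = 0.6),
              nGenes, nCellTypes, dimnames = list(genes, types))
  block <- nGenes %/% nCellTypes
  for (j in seq_len(nCellTypes)) {
    idx <- seq.int((j - 1L) * block + 1L, j * block)
    S[idx, j] <- S[idx, j] * stats::rlnorm(block, meanlog = log(12),
                                           sdlog = 0.25)
  }
  SignatureMatrix(S, tCellTypes = types[seq_len(nTCellTypes)],
                  cd8Type = types[1L])
}

#' Simulate a cohort with known ground truth
#'
#' Cell fractions are drawn from a Dirichlet distribution; bulk expression
#' is the signature-weighted mixture with multiplicative log-normal noise,
#' rescaled per sample to TPM totals; survival times are exponential with
#' hazard \code{baselineHazard * exp(logHrPerUnitCd3 * (cd3 - mean(cd3)))},
#' so a negative coefficient makes T-cell infiltration protective; with
#' probability \code{censoringRate} a record is administratively censored
#' at a uniform fraction of its event time; histology labels are assigned
#' round-robin. Bitwise deterministic given the config seed.
#'
#' @param config a [SyntheticConfig-class].
#' @param signature optional [SignatureMatrix-class] to mix from (its
#'   dimensions override the config's signature fields); by default a
#'   signature is generated from the config seed. Supplying one shared
#'   signature lets several simulated strata live in one expression matrix.
#' @return A [SyntheticCohort-class] object.
#' @examples
#' sc <- simulateCohort(SyntheticConfig(nPatients = 30, nGenes = 60,
#'                                      nCellTypes = 4, nTCellTypes = 2,
#'                                      nCancerTypes = 2, seed = 1))
#' sc
#' @export
simulateCohort <- function(config, signature = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  sig <- if (is.null(signature))
    makeSignature(config@nGenes, config@nCellTypes, config@nTCellTypes,
                  seed = .childSeed(config@seed, 1L))
  else signature
  set.seed(.childSeed(config@seed, 2L))
  n <- config@nPatients
  K <- length(cellTypes(sig))
  alpha <- rep_len(config@dirichletConcentration, K)
  ids <- sprintf("P%04d", seq_len(n))

  # Dirichlet via normalized gamma draws
  G <- matrix(stats::rgamma(n * K, shape = rep(alpha, each = n)), n, K)
  F <- G / rowSums(G)
  dimnames(F) <- list(ids, cellTypes(sig))

  M <- exprValues(sig) %*% t(F)
  if (config@noiseSd > 0)
    M <- M * exp(matrix(stats::rnorm(length(M), 0, config@noiseSd),
                        nrow(M), ncol(M)))
  M <- sweep(M, 2, colSums(M), "/") * 1e6   # TPM-style column totals
  dimnames(M) <- list(geneIds(sig), ids)

  cd3True <- rowSums(F[, tCellTypes(sig), drop = FALSE])
  hazard <- config@baselineHazard *
    exp(config@logHrPerUnitCd3 * (cd3True - mean(cd3True)))
  eventTime <- stats::rexp(n, rate = hazard)
  censored <- stats::runif(n) < config@censoringRate
  time <- ifelse(censored, eventTime * stats::runif(n), eventTime)
  surv <- data.frame(patient_id = ids, time = time,
                     event = as.integer(!censored))

  labels <- if (config@nCancerTypes == 4L)
    c("melanoma", "head_and_neck", "nsclc", "rcc")
  else sprintf("cancer%02d", seq_len(config@nCancerTypes))
  cancer <- rep_len(labels, n)

  new("SyntheticCohort", signature = sig, trueFractions = F,
      expression = BulkExpression(M), survival = surv, cancerType = cancer)
}

#' Write a synthetic cohort to a directory
#'
#' Emits expression.tsv, signature.tsv, survival.tsv, cancer_type.tsv and
#' true_fractions.tsv in the same delimited dialects the pipeline reads, so
#' a full run needs no other input.
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if missing).
#' @return Invisibly, a named character vector of the written paths.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "SyntheticCohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    signature = file.path(dir, "signature.tsv"),
    survival = file.path(dir, "survival.tsv"),
    cancer_type = file.path(dir, "cancer_type.tsv"),
    true_fractions = file.path(dir, "true_fractions.tsv"))
  writeMatrixTSV(cohort@expression, paths["expression"])
  writeMatrixTSV(cohort@signature, paths["signature"],
                 geneColumn = "Gene symbol")
  utils::write.table(cohort@survival, paths["survival"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(patient_id = cohort@survival$patient_id,
               cancer_type = cohort@cancerType),
    paths["cancer_type"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(patient_id = rownames(cohort@trueFractions),
               cohort@trueFractions, check.names = FALSE),
    paths["true_fractions"], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
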
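# Signature-regression deconvolution: the CIBERSORT-style core.
# A bulk mixture is regressed on the signature profiles with linear-kernel
# nu-SVR over a small nu grid; the best-RMSE fit is kept, negative
# coefficients are truncated and the rest renormalized to proportions.

#' Deconvolve one bulk mixture into cell-type fractions
#'
#' Intersects the mixture's genes with the signature genes (at least half of
#' the signature genes must be present), standardizes the signature matrix
#' globally (overall mean/sd) and the mixture by its own mean/sd, fits a
#' linear-kernel nu-support-vector regression for each value of
#' \code{nuGrid}, keeps the fit with the lowest root-mean-square residual
#' between reconstructed and observed standardized mixture, truncates
#' negative coefficients to zero and renormalizes to sum to one.
#'
#' @param mixture named numeric vector of linear-scale per-gene abundances.
#' @param signature a [SignatureMatrix-class].
#' @param nuGrid nu values to try (default \code{c(0.25, 0.5, 0.75)}).
#' @return A list with elements \code{fractions} (named, non-negative,
#'   sums to 1), \code{rmse}, \code{corr}, \code{nu} (the selected value)
#'   and \code{nGenes} (shared genes used).
#' @examples
#' sig <- makeSignature(nGenes = 60, nCellTypes = 4, nTCellTypes = 2, seed = 1)
#' mix <- exprValues(sig) %*% c(0.3, 0.7, 0, 0)
#' deconvolveSample(setNames(as.vector(mix), geneIds(sig)), sig)$fractions
#' @export
deconvolveSample <- function(mixture, signature, nuGrid = c(0.25, 0.5, 0.75)) {
  stopifnot(is(signature, "SignatureMatrix"), length(nuGrid) >= 1)
  if (is.null(names(mixture))) stop("mixture must be a named gene vector")
  S <- exprValues(signature)
  shared <- intersect(rownames(S), names(mixture))
  if (!length(shared)) stop("empty gene intersection with the signature")
  if (length(shared) < 0.5 * nrow(S))
    stop(sprintf("only %d of %d signature genes present in the mixture ",
                 length(shared), nrow(S)),
         "(at least 50% required)")
  y <- as.numeric(mixture[shared])
  X <- S[shared, , drop = FALSE]
  if (stats::sd(y) == 0)
    stop("mixture has zero variance over the signature genes; ",
         "standardization undefined")
  ys <- (y - mean(y)) / stats::sd(y)
  Xs <- (X - mean(X)) / stats::sd(as.vector(X))

  best <- NULL
  for (nu in nuGrid) {
    fit <- e1071::svm(Xs, ys, type = "nu-regression", kernel = "linear",
                      nu = nu, scale = FALSE)
    w <- as.vector(crossprod(fit$coefs, fit$SV))
    w[w < 0] <- 0
    tot <- sum(w)
    if (tot <= 0) next
    w <- w / tot
    recon <- as.vector(Xs %*% w)
    rmse <- sqrt(mean((recon - ys)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(fractions = stats::setNames(w, colnames(S)),
                   rmse = rmse,
                   corr = stats::cor(recon, ys),
                   nu = nu, nGenes = length(shared))
  }
  if (is.null(best))
    stop("degenerate mixture: all regression coefficients non-positive ",
         "for every nu")
  best
}

#' Deconvolve a cohort of bulk expression profiles
#'
#' Applies [deconvolveSample()] to every column of a linear-scale
#' expression matrix and optionally attaches gene-permutation p-values for
#' the selected-fit correlation. Deterministic given \code{seed}.
#'
#' @param x a [BulkExpression-class] on linear scale (see [toLinearTPM()]).
#' @param signature a [SignatureMatrix-class].
#' @param nuGrid nu values passed to [deconvolveSample()].
#' @param nPermutations number of gene permutations for per-sample
#'   significance (0 = skip; minimum 10 otherwise).
#' @param seed integer seed for the permutation null.
#' @return A [CellFractions-class] object.
#' @export
deconvolveCohort <- function(x, signature, nuGrid = c(0.25, 0.5, 0.75),
                             nPermutations = 0L, seed = 1L) {
  stopifnot(is(x, "BulkExpression"))
  if (!identical(scaleTag(x), "linear"))
    stop("expression must be on linear scale; apply toLinearTPM() first")
  v <- exprValues(x)
  K <- length(cellTypes(signature))
  n <- ncol(v)
  fr <- matrix(NA_real_, n, K, dimnames = list(colnames(v),
                                               cellTypes(signature)))
  rmse <- corr <- pval <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    mix <- stats::setNames(v[, i], rownames(v))
    res <- tryCatch(deconvolveSample(mix, signature, nuGrid),
                    error = function(e)
                      stop("sample '", colnames(v)[i], "': ",
                           conditionMessage(e), call. = FALSE))
    fr[i, ] <- res$fractions
    rmse[i] <- res$rmse
    corr[i] <- res$corr
    if (nPermutations > 0)
      pval[i] <- permutationSignificance(mix, signature,
                                         nPermutations = nPermutations,
                                         seed = .childSeed(seed, i),
                                         nuGrid = nuGrid,
                                         observedCorr = res$corr)
  }
  new("CellFractions", fractions = fr, fitRMSE = rmse, fitCorr = corr,
      pValue = pval)
}

#' Gene-permutation significance of a deconvolution fit
#'
#' Builds a null distribution of the selected-fit correlation by shuffling
#' the mixture values across genes and re-running [deconvolveSample()],
#' then returns the add-one permutation p-value
#' \eqn{(1 + \#\{corr_{null} \ge corr_{obs}\}) / (n + 1)}.
#'
#' @param mixture named numeric vector of linear-scale abundances.
#' @param signature a [SignatureMatrix-class].
#' @param nPermutations number of shuffles (>= 10).
#' @param seed integer seed.
#' @param nuGrid nu grid for the refits.
#' @param observedCorr the observed selected-fit correlation; computed from
#'   \code{mixture} when NULL.
#' @return A p-value in (0, 1].
#' @export
permutationSignificance <- function(mixture, signature, nPermutations = 100L,
                                    seed = 1L, nuGrid = c(0.25, 0.5, 0.75),
                                    observedCorr = NULL) {
  if (nPermutations < 10) stop("nPermutations must be at least 10")
  # degenerate fits (all coefficients truncated) carry correlation -Inf so
  # the statistic is total and a degenerate observed mixture gets p ~ 1
  if (is.null(observedCorr))
    observedCorr <- tryCatch(
      deconvolveSample(mixture, signature, nuGrid)$corr,
      error = function(e) -Inf)
  vals <- as.numeric(mixture)
  set.seed(seed)
  nulls <- vapply(seq_len(nPermutations), function(k) {
    shuffled <- stats::setNames(sample(vals), names(mixture))
    tryCatch(deconvolveSample(shuffled, signature, nuGrid)$corr,
             error = function(e) -Inf)
  }, numeric(1))
  (1 + sum(nulls >= observedCorr)) / (nPermutations + 1)
}

#' Derive CD3+/CD8+ T-cell densities from cell fractions
#'
#' CD3 density = summed fraction over the signature's declared pan-T
#' subsets; CD8 density = fraction of the declared CD8+ subset.
#'
#' @param x a [CellFractions-class].
#' @param signature the [SignatureMatrix-class] whose declarations to use.
#' @return A [TCellDensities-class] object.
#' @export
imputeTCellDensities <- function(x, signature) {
  stopifnot(is(x, "CellFractions"), is(signature, "SignatureMatrix"))
  fr <- fractions(x)
  missing <- setdiff(tCellTypes(signature), colnames(fr))
  if (length(missing))
    stop("declared T-cell type(s) absent from fractions: ",
         paste(missing, collapse = ", "))
  TCellDensities(sampleIds = rownames(fr),
                 cd3 = rowSums(fr[, tCellTypes(signature), drop = FALSE]),
                 cd8 = fr[, cd8Type(signature)])
}

#' Write cell fractions as TSV
#'
#' Sample rows, one column per cell type, plus RMSE, correlation and
#' p-value columns (CIBERSORT-style output layout).
#'
#' @param x a [CellFractions-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeCellFractions <- function(x, path) {
  df <- data.frame(sample_id = sampleIds(x), fractions(x),
                   RMSE = fitRMSE(x), Correlation = fitCorr(x),
                   P.value = pValues(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# deterministic child seeds below 2^31
.childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483629)
}
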
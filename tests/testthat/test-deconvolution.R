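sig <- tinySignature()

test_that("a pure population mixture yields fraction 1 for its type", {
  for (j in c(1, 3)) {
    f <- replace(numeric(4), j, 1)
    res <- deconvolveSample(mixFrom(sig, f), sig)
    expect_gt(res$fractions[j], 0.99)
    expect_lt(max(res$fractions[-j]), 0.01)
    expect_gt(res$corr, 0.99)
  }
})

test_that("noiseless two-type mixtures match truth and the NNLS oracle", {
  skip_if_not_installed("pracma")
  mixes <- list(c(0.3, 0.7, 0, 0), c(0.1, 0.2, 0.3, 0.4), c(0.5, 0, 0.5, 0))
  for (f in mixes) {
    mix <- mixFrom(sig, f)
    est <- deconvolveSample(mix, sig)$fractions
    expect_lt(max(abs(est - f)), 0.02)
    expect_lt(max(abs(est - nnlsOracle(mix, sig))), 0.02)
  }
})

test_that("degenerate mixtures raise explicit errors", {
  flat <- stats::setNames(rep(5, length(geneIds(sig))), geneIds(sig))
  expect_error(deconvolveSample(flat, sig), "zero variance")
  few <- mixFrom(sig, c(0.5, 0.5, 0, 0))[1:10]   # < 50% of signature genes
  expect_error(deconvolveSample(few, sig), "50%")
  none <- stats::setNames(1:5, paste0("X", 1:5))
  expect_error(deconvolveSample(none, sig), "intersection")
  expect_error(deconvolveSample(unname(mixFrom(sig, c(1, 0, 0, 0))), sig),
               "named")
})

test_that("cohort deconvolution is normalized, deterministic and accurate", {
  cfg <- SyntheticConfig(nPatients = 20, nGenes = 60, nCellTypes = 4,
                         nTCellTypes = 2, noiseSd = 0, seed = 11)
  sc <- simulateCohort(cfg)
  cf1 <- deconvolveCohort(sc@expression, signatureMatrix(sc), seed = 4)
  cf2 <- deconvolveCohort(sc@expression, signatureMatrix(sc), seed = 4)
  expect_identical(fractions(cf1), fractions(cf2))       # bitwise
  expect_equal(nrow(fractions(cf1)), 20L)
  expect_lt(max(abs(rowSums(fractions(cf1)) - 1)), 1e-9)
  expect_true(all(fractions(cf1) >= 0))
  mae <- mean(abs(fractions(cf1) - trueFractions(sc)))
  expect_lt(mae, 0.02)
  # per-sample errors carry the sample id
  bad <- sc@expression
  bad@values[, 3] <- 1
  expect_error(deconvolveCohort(bad, signatureMatrix(sc)), "P0003")
  expect_error(deconvolveCohort(BulkExpression(
    matrix(1, 1, 1, dimnames = list("A", "s")), "log2p1"), sig), "linear")
})

test_that("estimated CD8 fraction increases along a noiseless CD8 gradient", {
  grad <- seq(0.05, 0.50, length.out = 8)
  est <- vapply(grad, function(g) {
    f <- c(g, (1 - g) * c(0.4, 0.3, 0.3))
    deconvolveSample(mixFrom(sig, f), sig)$fractions[1]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("T-cell densities sum the declared subsets", {
  fr <- matrix(c(0.10, 0.05, 0.25, 0.60,
                 0.00, 0.00, 0.50, 0.50), 2, 4, byrow = TRUE,
               dimnames = list(c("s1", "s2"), cellTypes(sig)))
  cf <- new("CellFractions", fractions = fr, fitRMSE = c(0, 0),
            fitCorr = c(1, 1), pValue = c(NA_real_, NA_real_))
  d <- imputeTCellDensities(cf, sig)
  expect_equal(cd3(d), c(0.15, 0))   # sum of the two declared T subsets
  expect_equal(cd8(d), c(0.10, 0))   # first declared subset is CD8
  # property: cd8 <= cd3 for random valid fraction rows
  set.seed(8)
  for (k in 1:1000) {
    row <- rgamma(4, 1)
    row <- matrix(row / sum(row), 1, dimnames = list("s", cellTypes(sig)))
    cfk <- new("CellFractions", fractions = row, fitRMSE = 0, fitCorr = 1,
               pValue = NA_real_)
    dk <- imputeTCellDensities(cfk, sig)
    expect_true(cd8(dk) <= cd3(dk) + 1e-12)
  }
  # missing declared type
  fr2 <- fr[, -1]
  cf2 <- new("CellFractions", fractions = fr2 / rowSums(fr2),
             fitRMSE = c(0, 0), fitCorr = c(1, 1),
             pValue = c(NA_real_, NA_real_))
  expect_error(imputeTCellDensities(cf2, sig), "absent")
})

test_that("permutation significance separates signal from noise", {
  smallSig <- tinySignature(seed = 21)
  genuine <- mixFrom(smallSig, c(0.3, 0.7, 0, 0))
  expect_lte(permutationSignificance(genuine, smallSig,
                                     nPermutations = 100, seed = 1), 0.05)
  expect_error(permutationSignificance(genuine, smallSig, nPermutations = 5),
               "at least 10")
  # a mixture that IS a shuffle draw gets a roughly uniform p-value
  set.seed(33)
  ps <- vapply(1:50, function(r) {
    shuffled <- stats::setNames(sample(as.numeric(genuine)), names(genuine))
    permutationSignificance(shuffled, smallSig, nPermutations = 19, seed = r)
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("null permutation p-values are approximately uniform", {
  smallSig <- tinySignature(seed = 22)
  base <- mixFrom(smallSig, c(0.2, 0.3, 0.3, 0.2))
  set.seed(44)
  ps <- vapply(1:200, function(r) {
    shuffled <- stats::setNames(sample(as.numeric(base)), names(base))
    permutationSignificance(shuffled, smallSig, nPermutations = 19,
                            seed = 1000 + r)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("cell fractions export in CIBERSORT-style layout", {
  cfg <- SyntheticConfig(nPatients = 3, nGenes = 60, nCellTypes = 4,
                         nTCellTypes = 2, noiseSd = 0, seed = 2)
  sc <- simulateCohort(cfg)
  cf <- deconvolveCohort(sc@expression, signatureMatrix(sc))
  f <- tempfile(fileext = ".tsv")
  writeCellFractions(cf, f)
  back <- utils::read.delim(f, check.names = FALSE)
  expect_identical(names(back)[1], "sample_id")
  expect_true(all(c("RMSE", "Correlation", "P.value") %in% names(back)))
  expect_equal(as.matrix(back[, cellTypes(signatureMatrix(sc))]),
               fractions(cf), ignore_attr = TRUE)
})
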
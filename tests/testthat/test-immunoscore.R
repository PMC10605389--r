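test_that("empirical percentile follows the mid-rank convention", {
  expect_equal(empiricalPercentile(c(10, 20, 30, 40), 25), 50)
  expect_equal(empiricalPercentile(c(5, 5, 5, 5), 5), 50)
  expect_equal(empiricalPercentile(c(1, 2, 3, 4), 10), 100)
  expect_equal(empiricalPercentile(c(1, 2, 3, 4), 0), 0)
  expect_error(empiricalPercentile(numeric(), 1), "non-empty")
  # counting-oracle agreement on random instances with ties
  set.seed(61)
  for (k in 1:200) {
    tr <- sample(1:8, sample(2:30, 1), replace = TRUE)
    q <- sample(0:9, 5, replace = TRUE)
    expect_equal(empiricalPercentile(tr, q), percentileOracle(tr, q))
  }
})

test_that("pair percentile score is the arithmetic mean", {
  expect_equal(pairPercentileScore(80, 40), 60)
  expect_equal(pairPercentileScore(0, 0), 0)
  expect_equal(pairPercentileScore(100, 100), 100)
  expect_error(pairPercentileScore(101, 0), "0, 100")
})

test_that("cross-validated immunoscore honours ties, ranks and the seed", {
  # all-tied cohort: every held-out percentile is the mid-rank 50
  tied <- TCellDensities(sprintf("P%02d", 1:20), cd3 = rep(0.3, 20),
                         cd8 = rep(0.1, 20))
  res <- cvImmunoscore(tied, CVScheme(nIterations = 5, seed = 1))
  expect_equal(scores(res), rep(50, 20), ignore_attr = TRUE)

  # the patient dominating everyone in both densities scores highest
  dens <- randomDensities(100, seed = 9)
  top <- which.max(cd3(dens) + cd8(dens))
  dens@cd3[top] <- max(cd3(dens)) + 0.01
  dens@cd8[top] <- dens@cd3[top]
  res <- cvImmunoscore(dens, CVScheme(seed = 3))
  expect_true(all(scores(res)[top] > scores(res)[-top]))

  # determinism and the score = mean(iteration scores) invariant
  res2 <- cvImmunoscore(dens, CVScheme(seed = 3))
  expect_identical(perIterationScores(res), perIterationScores(res2))
  expect_equal(scores(res), rowMeans(perIterationScores(res)))
  expect_true(all(scores(res) >= 0 & scores(res) <= 100))

  expect_error(cvImmunoscore(randomDensities(3, 1), CVScheme(nFolds = 5)),
               "fewer patients")
})

test_that("score ranking respects density dominance", {
  dens <- randomDensities(60, seed = 12)
  res <- cvImmunoscore(dens, CVScheme(seed = 5))
  s <- scores(res)
  for (i in 1:59) for (j in (i + 1):60) {
    if (cd3(dens)[i] > cd3(dens)[j] && cd8(dens)[i] > cd8(dens)[j])
      expect_gte(s[i], s[j])
    if (cd3(dens)[i] < cd3(dens)[j] && cd8(dens)[i] < cd8(dens)[j])
      expect_lte(s[i], s[j])
  }
})

test_that("Youden cut-off maximizes J with smallest-cut-off tie-breaking", {
  perfect <- youdenCutoff(c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(perfect$cutoff, 2.5)
  expect_equal(perfect$J, 1)

  tied <- youdenCutoff(c(1, 2, 3, 4), c(1, 0, 1, 0))
  expect_equal(tied$J, 0.5)
  expect_equal(tied$cutoff, 1.5)  # 1.5 and 3.5 tie at J = 0.5

  expect_error(youdenCutoff(1:4, c(1, 1, 1, 1)), "both outcome classes")

  # exhaustive-scan oracle agreement on random instances
  set.seed(71)
  for (k in 1:300) {
    n <- sample(4:30, 1)
    s <- sample(seq(0, 2, by = 0.1), n, replace = TRUE)
    l <- rbinom(n, 1, 0.5)
    if (length(unique(l)) < 2) next
    got <- youdenCutoff(s, l)
    want <- youdenOracle(s, l)
    expect_identical(got$cutoff, want$cutoff)
    expect_equal(got$J, want$J)
  }
})

test_that("independent labels give small maximal J", {
  set.seed(81)
  jmax <- vapply(1:100, function(k) {
    s <- runif(200)
    l <- rbinom(200, 1, 0.5)
    youdenCutoff(s, l)$J
  }, numeric(1))
  expect_lt(mean(jmax), 0.25)
})

test_that("CV-averaged Youden cut-off recovers a known threshold", {
  dens <- randomDensities(300, seed = 14)
  labels <- as.integer(truthScore(dens) < 40)
  spec <- cvYoudenCutoff(dens, labels, CVScheme(seed = 2))
  expect_s4_class(spec, "CutoffSpec")
  expect_identical(cutoffMethod(spec), "youden")
  expect_lt(abs(resolvedPercentile(spec) - 40), 5)

  # labels independent of densities: only the range invariant holds
  set.seed(15)
  rnd <- cvYoudenCutoff(dens, rbinom(300, 1, 0.5), CVScheme(seed = 7))
  expect_gt(resolvedPercentile(rnd), 0)
  expect_lt(resolvedPercentile(rnd), 100)

  expect_error(cvYoudenCutoff(dens, rep(1L, 300), CVScheme(seed = 1)),
               "both outcome classes")
})

test_that("categorization covers the expected lower tail and keeps ties high", {
  dens <- randomDensities(522, seed = 16)
  res <- cvImmunoscore(dens, CVScheme(seed = 4))
  cat25 <- categorize(res, CutoffSpec(percentile = 25))
  frac <- mean(categories(cat25) == 0L)
  expect_lt(abs(frac - 0.25), 0.04)
  expect_s4_class(cutoffUsed(cat25), "CutoffSpec")

  # a score exactly at the threshold lands in category 1
  resTie <- new("ImmunoscoreResult", patientIds = c("a", "b", "c", "d"),
                score = c(10, 20, 30, 40),
                perIterationScores = matrix(c(10, 20, 30, 40), 4, 1),
                category = rep(NA_integer_, 4), cutoffUsed = NULL)
  # percentile 100/3 puts the threshold exactly on the score 20
  catTie <- categorize(resTie, CutoffSpec(percentile = 100 / 3),
                       referenceScores = c(10, 20, 30, 40))
  expect_identical(categories(catTie), c(0L, 1L, 1L, 1L))

  # coverage at the 43.5th percentile on uniform scores
  set.seed(17)
  u <- runif(1000)
  resU <- new("ImmunoscoreResult", patientIds = sprintf("P%04d", 1:1000),
              score = u * 100, perIterationScores = matrix(u * 100, 1000, 1),
              category = rep(NA_integer_, 1000), cutoffUsed = NULL)
  catU <- categorize(resU, CutoffSpec(percentile = 43.5))
  expect_lt(abs(mean(categories(catU) == 0L) - 0.435), 0.04)

  expect_error(categorize(res, CutoffSpec("youden")), "unresolved")
})

test_that("immunoscore results export to TSV", {
  dens <- randomDensities(20, seed = 19)
  res <- categorize(cvImmunoscore(dens, CVScheme(nIterations = 3, seed = 1)),
                    CutoffSpec(percentile = 25))
  f <- tempfile(fileext = ".tsv")
  writeImmunoscoreResult(res, f, perIteration = TRUE)
  back <- utils::read.delim(f)
  expect_identical(nrow(back), 20L)
  expect_true(all(c("patient_id", "score", "category", "iter1") %in%
                    names(back)))
  expect_equal(back$score, unname(scores(res)))
})
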
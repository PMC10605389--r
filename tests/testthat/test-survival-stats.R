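test_that("Kaplan-Meier matches hand product-limit computations", {
  # all censored: survival stays at 1
  km <- kaplanMeier(c(2, 4, 6, 8, 10), rep(0, 5))
  expect_true(all(km@surv == 1))
  expect_true(is.na(kmMedian(km)))

  # (1, death), (2, censored), (3, death): S(1) = 2/3, S(3) = 0
  km <- kaplanMeier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km@surv[km@time == 1], 2 / 3)
  expect_equal(km@surv[km@time == 3], 0)
  expect_equal(kmMedian(km), 3)

  # with no censoring the KM equals the empirical survival function
  set.seed(31)
  t <- rexp(200, 0.2)
  km <- kaplanMeier(t, rep(1, 200))
  emp <- vapply(km@time, function(x) mean(t > x), numeric(1))
  expect_equal(km@surv, emp, tolerance = 1e-12)
  expect_true(all(diff(km@surv) <= 1e-12))
  expect_true(all(km@lower <= km@surv + 1e-9 & km@surv <= km@upper + 1e-9))
  expect_true(all(km@lower >= 0 & km@upper <= 1))

  # zero times are shifted with a warning, negatives rejected
  expect_warning(kaplanMeier(c(0, 1, 2), c(1, 1, 0)), "shifted")
  expect_error(kaplanMeier(c(-1, 1), c(1, 1)), "positive")
  expect_error(kaplanMeier(numeric(), numeric()), "no survival records")
})

test_that("log-rank test matches the O-E/V oracle and its invariances", {
  # identical groups: statistic 0, p = 1
  t <- c(1, 3, 5, 7)
  e <- c(1, 0, 1, 1)
  lr <- logrankTest(c(t, t), c(e, e), rep(0:1, each = 4))
  expect_equal(unname(lr$statistic), 0)
  expect_equal(lr$p.value, 1)

  # fixed 6-record instances against the textbook formula
  instances <- list(
    list(t = c(1, 2, 3, 4, 5, 6), e = c(1, 1, 0, 1, 1, 0),
         g = c(0, 1, 0, 1, 0, 1)),
    list(t = c(2, 2, 4, 5, 7, 9), e = c(1, 1, 1, 0, 1, 1),
         g = c(0, 0, 1, 1, 1, 0)),
    list(t = c(1, 1, 2, 3, 3, 8), e = c(1, 0, 1, 1, 1, 1),
         g = c(1, 0, 0, 1, 0, 1)))
  for (inst in instances) {
    got <- unname(logrankTest(inst$t, inst$e, inst$g)$statistic)
    expect_equal(got, logrankOracle(inst$t, inst$e, inst$g),
                 tolerance = 1e-9)
  }

  # invariant to label swap and to adding a constant to all times
  set.seed(41)
  t <- rexp(60, 0.1); e <- rbinom(60, 1, 0.7); g <- rep(0:1, 30)
  s1 <- unname(logrankTest(t, e, g)$statistic)
  expect_equal(unname(logrankTest(t, e, 1 - g)$statistic), s1)
  expect_equal(unname(logrankTest(t + 5, e, g)$statistic), s1)

  expect_error(logrankTest(t, e, rep(1, 60)), "two non-empty groups")

  # power at hazard ratio 2 with 300 per group
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    tt <- c(rexp(300, 0.1), rexp(300, 0.2))
    logrankTest(tt, rep(1, 600), rep(0:1, each = 300))$p.value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("Harrell's C matches the pair-enumeration oracle", {
  expect_equal(harrellC(c(2, 4, 6), c(1, 1, 1), c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(harrellC(c(2, 4, 6), c(1, 1, 1), c(0.1, 0.5, 0.9)), 1)
  expect_equal(harrellC(c(2, 4, 6), c(1, 1, 1), c(0.9, 0.5, 0.1)), 0)
  expect_error(harrellC(c(1, 2), c(0, 0), c(1, 2)), "no comparable pairs")

  set.seed(51)
  for (k in 1:200) {
    inst <- randomSurvivalInstance(5000 + k)
    if (sum(inst$event) == 0) next
    got <- try(harrellC(inst$time, inst$event, inst$score), silent = TRUE)
    if (inherits(got, "try-error")) next
    expect_equal(got, harrellCOracle(inst$time, inst$event, inst$score))
  }

  # independent cross-check against survival::concordance
  set.seed(52)
  t <- rexp(100, 0.1); e <- rbinom(100, 1, 0.6); s <- runif(100)
  ref <- survival::concordance(survival::Surv(t, e) ~ s)$concordance
  expect_equal(harrellC(t, e, s), unname(ref), tolerance = 1e-12)

  # antisymmetry when no score ties exist
  expect_equal(harrellC(t, e, s) + harrellC(t, e, -s), 1)
})

test_that("C-index aggregation uses the normal approximation", {
  z <- summarizeC(c(0.6, 0.6, 0.6))
  expect_equal(z$mean, 0.6)
  expect_equal(z$ciLower, 0.6)
  expect_equal(z$ciUpper, 0.6)

  z <- summarizeC(c(0.5, 0.7))
  half <- 1.96 * stats::sd(c(0.5, 0.7)) / sqrt(2)
  expect_equal(z$mean, 0.6)
  expect_equal(z$ciLower, 0.6 - half)
  expect_equal(z$ciUpper, 0.6 + half)

  expect_error(summarizeC(0.5), "at least two")
})

test_that("Cox regression recovers hazard ratios with a tight gradient", {
  set.seed(55)
  t <- c(rexp(400, 0.1), rexp(400, 0.2))
  e <- rbinom(800, 1, 0.7)
  t[e == 0] <- t[e == 0] * runif(sum(e == 0))
  g <- rep(0:1, each = 400)
  fit <- coxBinaryHR(t, e, g)
  expect_equal(fit$hr, exp(fit$logHR))
  expect_gt(fit$hr, 1.5)
  expect_lt(fit$hr, 2.6)
  expect_true(fit$ciLower < fit$hr && fit$hr < fit$ciUpper)
  expect_lt(fit$p.value, 0.01)
  expect_false(fit$flagged)

  # Breslow partial-likelihood gradient at the estimate is < 1e-8
  score <- function(b) {
    s <- 0
    for (i in which(e == 1)) {
      risk <- t >= t[i]
      w <- exp(b * g[risk])
      s <- s + g[i] - sum(w * g[risk]) / sum(w)
    }
    s
  }
  expect_lt(abs(score(fit$logHR)), 1e-8)

  expect_error(coxBinaryHR(t, e, rep(0, 800)), "two non-empty groups")
  expect_error(coxBinaryHR(c(1, 2), c(0, 0), c(0, 1)), "no events")
  expect_warning(coxBinaryHR(c(1, 2, 3, 4), c(1, 1, 0, 0), c(0, 0, 1, 1)),
                 "flagged")
})

test_that("KM curves export as TSV", {
  km <- kaplanMeier(c(1, 2, 3, 4), c(1, 0, 1, 1))
  f <- tempfile(fileext = ".tsv")
  writeKMCurve(km, f)
  back <- utils::read.delim(f)
  expect_identical(names(back),
                   c("time", "survival", "ci_lower", "ci_upper",
                     "n_at_risk", "n_events"))
  expect_equal(back$survival, km@surv)
})
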
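# Survival stratification statistics. The estimators stand on the survival
# package (product-limit fit with log(-log) Greenwood bands, log-rank via
# survdiff, Cox partial likelihood with Breslow ties via coxph); Harrell's
# concordance is computed here with an explicit comparable-pair definition.

# time > 0 contract: exact zeros are shifted by 1e-6 with a warning,
# negatives are an error.
.checkSurvivalInput <- function(time, event) {
  stopifnot(length(time) == length(event))
  if (any(!event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  if (any(time < 0)) stop("survival times must be positive")
  if (any(time == 0)) {
    warning("survival time 0 shifted to 1e-6")
    time[time == 0] <- 1e-6
  }
  time
}

#' Kaplan-Meier curve with Greenwood 95% bands
#'
#' Product-limit estimator with 95% pointwise confidence bands from the
#' Greenwood variance on the log(-log) scale, clamped to [0, 1]. Where the
#' transform is undefined (survival 1 or 0) the band collapses onto the
#' estimate (or 0 for the lower bound at survival 0).
#'
#' @param time positive follow-up times (months).
#' @param event 1 = death, 0 = right-censored.
#' @return A [KMCurve-class] object.
#' @examples
#' km <- kaplanMeier(c(1, 2, 3), c(1, 0, 1))
#' kmMedian(km)
#' @export
kaplanMeier <- function(time, event) {
  if (!length(time)) stop("no survival records")
  time <- .checkSurvivalInput(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = 0.95)
  lower <- fit$lower
  upper <- fit$upper
  lower[is.na(lower)] <- ifelse(fit$surv[is.na(lower)] > 0,
                                fit$surv[is.na(lower)], 0)
  upper[is.na(upper)] <- fit$surv[is.na(upper)]
  new("KMCurve", time = fit$time, surv = fit$surv,
      lower = pmin(lower, fit$surv), upper = pmax(upper, fit$surv),
      nRisk = as.numeric(fit$n.risk), nEvent = as.numeric(fit$n.event))
}

#' Median survival time of a KM curve
#'
#' @param curve a [KMCurve-class].
#' @return The smallest time at which survival drops to 0.5 or below, or NA
#'   when the curve never reaches 0.5.
#' @export
kmMedian <- function(curve) {
  stopifnot(is(curve, "KMCurve"))
  idx <- which(curve@surv <= 0.5)
  if (!length(idx)) NA_real_ else curve@time[min(idx)]
}

#' Export a KM curve as TSV
#'
#' @param curve a [KMCurve-class].
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeKMCurve <- function(curve, path) {
  df <- data.frame(time = curve@time, survival = curve@surv,
                   ci_lower = curve@lower, ci_upper = curve@upper,
                   n_at_risk = curve@nRisk, n_events = curve@nEvent)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with hypergeometric
#' variance; the p-value comes from a chi-square distribution with one
#' degree of freedom.
#'
#' @param time positive follow-up times.
#' @param event 1 = death, 0 = censored.
#' @param group binary group labels (two non-empty groups required).
#' @return An object of class \code{"htest"} with \code{statistic}
#'   (chi-square), \code{parameter} (df = 1) and \code{p.value}.
#' @export
logrankTest <- function(time, event, group) {
  time <- .checkSurvivalInput(time, event)
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two non-empty groups are required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  stat <- sd$chisq
  structure(list(statistic = c(`chi-square` = stat), parameter = c(df = 1),
                 p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
                 method = "Two-group log-rank test",
                 data.name = "survival by immunoscore category"),
            class = "htest")
}

#' Harrell's concordance index for a protective score
#'
#' Over all comparable pairs — the earlier time is an observed death, or
#' the times are tied with exactly one death, in which case the censored
#' patient counts as the longer survivor — a pair is concordant when the
#' longer-surviving patient has the higher score; tied scores contribute
#' 0.5. Orientation: higher score, longer survival; values above 0.5 mean
#' the score is protective.
#'
#' @param time positive follow-up times.
#' @param event 1 = death, 0 = censored.
#' @param score numeric risk/protective score, one per patient.
#' @return Concordant weight divided by the number of comparable pairs.
#' @examples
#' harrellC(c(2, 4, 6), c(1, 1, 1), c(0.1, 0.5, 0.9))  # 1
#' @export
harrellC <- function(time, event, score) {
  time <- .checkSurvivalInput(time, event)
  stopifnot(length(score) == length(time))
  n <- length(time)
  dT <- outer(time, time, "<")                       # t_i < t_j
  tie <- outer(time, time, "==")
  ev <- matrix(event == 1, n, n)                     # e_i by row
  comparable <- (dT & ev) | (tie & ev & t(!ev))
  diag(comparable) <- FALSE
  higher <- outer(score, score, "<")                 # s_j > s_i
  tieS <- outer(score, score, "==")
  num <- sum(comparable & higher) + 0.5 * sum(comparable & tieS)
  den <- sum(comparable)
  if (den == 0) stop("no comparable pairs")
  num / den
}

#' Aggregate per-iteration C-indices
#'
#' Mean across the cross-validation iterations with a normal-approximation
#' 95% confidence interval, mean +/- 1.96 * sd / sqrt(k).
#'
#' @param perIterationC numeric vector of per-iteration C-indices (k >= 2).
#' @return A list with \code{mean}, \code{ciLower}, \code{ciUpper} and
#'   \code{perIteration}.
#' @examples
#' summarizeC(c(0.5, 0.7))
#' @export
summarizeC <- function(perIterationC) {
  k <- length(perIterationC)
  if (k < 2) stop("at least two iteration values are required")
  m <- mean(perIterationC)
  half <- 1.96 * stats::sd(perIterationC) / sqrt(k)
  list(mean = m, ciLower = m - half, ciUpper = m + half,
       perIteration = perIterationC)
}

#' Univariate Cox hazard ratio for a binary group
#'
#' Maximizes the Cox partial likelihood (Breslow tie handling, convergence
#' tolerance 1e-9, at most 100 iterations) for a single binary covariate
#' and reports the Wald confidence interval and p-value. The hazard ratio
#' is for group 1 relative to group 0. A group without any events yields a
#' monotone partial likelihood; the estimate is returned flagged.
#'
#' @param time positive follow-up times.
#' @param event 1 = death, 0 = censored.
#' @param group binary group labels (0/1 or a two-level factor).
#' @return A list with \code{logHR}, \code{hr}, \code{se}, \code{ciLower},
#'   \code{ciUpper}, \code{p.value} and \code{flagged}.
#' @export
coxBinaryHR <- function(time, event, group) {
  time <- .checkSurvivalInput(time, event)
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two non-empty groups are required")
  if (sum(event) == 0) stop("no events in the data")
  x <- as.numeric(g) - 1
  flagged <- any(tapply(event, x, sum) == 0)
  if (flagged)
    warning("a group has no events: monotone partial likelihood, ",
            "estimate flagged")
  fitCall <- quote(survival::coxph(
    survival::Surv(time, event) ~ x, ties = "breslow",
    control = survival::coxph.control(eps = 1e-9, iter.max = 100)))
  # the explicit flag above supersedes coxph's own convergence warning
  fit <- if (flagged) suppressWarnings(eval(fitCall)) else eval(fitCall)
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  list(logHR = beta, hr = exp(beta), se = se,
       ciLower = exp(beta - 1.96 * se), ciUpper = exp(beta + 1.96 * se),
       p.value = 2 * stats::pnorm(-abs(beta / se)), flagged = flagged)
}
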
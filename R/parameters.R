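#' Log-Gaussian marker distribution for one group
#'
#' @param marker Marker name.
#' @param group `"affected"` or `"unaffected"`.
#' @param mean Mean of log10 MoM.
#' @param sd SD of log10 MoM; must be positive.
#' @param truncation MoM truncation limits `c(low, high)`, 0 < low < high.
#' @return An object of class `marker_distribution`.
#' @export
marker_distribution <- function(marker, group = c("affected", "unaffected"),
                                mean, sd, truncation = c(0.4, 2.5)) {
  group <- match.arg(group)
  assert_that(sd > 0, "sd must be positive")
  assert_that(truncation[1] > 0 && truncation[1] < truncation[2],
              "truncation limits must satisfy 0 < low < high")
  structure(list(marker = marker, group = group, mean = mean, sd = sd,
                 truncation = truncation),
            class = "marker_distribution")
}

#' Regress affected median MoM on gestational age
#'
#' Groups affected pregnancies into gestational-age categories (2-day
#' categories in the first trimester; weekly categories in the second, with
#' 19 to 22 weeks pooled into one category because few affected pregnancies
#' are sampled that late), then regresses the log10 category median MoM on
#' the category median gestational age, weighted by category counts.
#' Regressed medians are reported at each completed week, evaluated at
#' week + 3 days, with delta-method confidence intervals on the log scale.
#'
#' @param moms Adjusted MoM values of affected pregnancies.
#' @param ga_days Gestational ages (days), same length.
#' @param trimester `"first"` or `"second"`.
#' @param weeks Completed weeks at which to report regressed medians;
#'   defaults to the weeks spanned by the data.
#' @param conf Confidence level for the intervals.
#' @return A data frame with one row per requested week: `week`, `n`
#'   (affected pregnancies in that week), `observed_median`,
#'   `regressed_median`, `ci_lower`, `ci_upper`. The fitted weekly ratio is
#'   attached as attribute `weekly_ratio`.
#' @export
regress_affected_medians <- function(moms, ga_days,
                                     trimester = c("first", "second"),
                                     weeks = NULL, conf = 0.95) {
  trimester <- match.arg(trimester)
  assert_that(length(moms) == length(ga_days), "lengths differ")
  assert_that(all(moms > 0), "MoM values must be positive")
  width <- if (trimester == "first") 2L else 7L
  cat_id <- floor(ga_days / width)
  if (trimester == "second") {
    cat_id[ga_days >= 19 * 7] <- floor(19 * 7 / 7)  # pool 19-22 weeks
  }
  tab <- do.call(rbind, lapply(split(seq_along(cat_id), cat_id), function(ix) {
    data.frame(ga_mid = category_median(ga_days[ix]),
               n = length(ix),
               median_mom = category_median(moms[ix]))
  }))
  assert_that(nrow(tab) >= 3, "need at least 3 non-empty categories")
  fit <- stats::lm(log10(median_mom) ~ ga_mid, data = tab, weights = tab$n)

  if (is.null(weeks)) {
    weeks <- seq(floor(min(ga_days) / 7), floor(max(ga_days) / 7))
  }
  eval_days <- weeks * 7 + 3
  pred <- stats::predict(fit, newdata = data.frame(ga_mid = eval_days),
                         se.fit = TRUE)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  week_of <- floor(ga_days / 7)
  obs <- vapply(weeks, function(w) {
    ix <- week_of == w
    if (!any(ix)) NA_real_ else category_median(moms[ix])
  }, numeric(1))
  n_w <- vapply(weeks, function(w) sum(week_of == w), numeric(1))
  empty <- n_w == 0
  if (any(empty)) warning("no affected pregnancies at week(s) ",
                          paste(weeks[empty], collapse = ", "))
  out <- data.frame(week = weeks,
                    n = n_w,
                    observed_median = obs,
                    regressed_median = 10^pred$fit,
                    ci_lower = 10^(pred$fit - z * pred$se.fit),
                    ci_upper = 10^(pred$fit + z * pred$se.fit))
  rownames(out) <- NULL
  attr(out, "weekly_ratio") <- unname(10^(7 * stats::coef(fit)[2]))
  out
}

#' Estimate a log10 SD from the probability plot
#'
#' Plots the order statistics of the log10 MoM sample against Gaussian
#' quantiles using the (i - 0.5)/n plotting positions and returns the
#' unweighted least-squares slope over the points whose empirical centile
#' lies between the 10th and 90th centiles. Compared with the raw sample
#' SD, this estimate ignores the distribution tails and so resists
#' occasional gross outliers.
#'
#' @param log_moms Numeric vector of log10 MoM values, n >= 20.
#' @return The estimated SD (log10 MoM).
#' @export
estimate_sd_probability_plot <- function(log_moms) {
  n <- length(log_moms)
  assert_that(n >= 20, "need at least 20 observations")
  x <- sort(log_moms)
  p <- (seq_len(n) - 0.5) / n
  keep <- p >= 0.10 & p <= 0.90
  z <- stats::qnorm(p[keep])
  unname(stats::coef(stats::lm(x[keep] ~ z))[2])
}

#' Pearson correlation with 3.5-SD outlier exclusion
#'
#' Computes the Pearson correlation of two log10 MoM series after excluding,
#' in a single pass, every pair in which either coordinate lies more than
#' 3.5 standard deviations from its mean. The SDs used for the exclusion
#' rule are the probability-plot estimates of each series.
#'
#' @param x_log_moms,y_log_moms Paired numeric vectors, n >= 20.
#' @return The correlation coefficient; the number of excluded pairs is
#'   attached as attribute `n_excluded`.
#' @export
estimate_correlation <- function(x_log_moms, y_log_moms) {
  assert_that(length(x_log_moms) == length(y_log_moms), "lengths differ")
  assert_that(length(x_log_moms) >= 20, "need at least 20 pairs")
  sx <- estimate_sd_probability_plot(x_log_moms)
  sy <- estimate_sd_probability_plot(y_log_moms)
  keep <- abs(x_log_moms - mean(x_log_moms)) <= 3.5 * sx &
    abs(y_log_moms - mean(y_log_moms)) <= 3.5 * sy
  assert_that(sum(keep) >= 10, "fewer than 10 pairs remain after exclusion")
  r <- stats::cor(x_log_moms[keep], y_log_moms[keep])
  attr(r, "n_excluded") <- sum(!keep)
  r
}

#' Point of risk reversal of a univariate log-Gaussian likelihood ratio
#'
#' When the affected and unaffected SDs differ, the Gaussian density ratio
#' is not monotone over the whole line; it is stationary at
#' \deqn{x^* = \frac{\mu_a \sigma_u^2 - \mu_u \sigma_a^2}{\sigma_u^2 - \sigma_a^2}.}
#' Truncation limits must keep marker values on the monotone side of
#' \eqn{x^*} so that risk is a monotone function of the marker value.
#'
#' @param affected,unaffected [marker_distribution()] objects (or lists with
#'   `mean` and `sd`).
#' @return The stationary point on the log10 MoM scale. With equal SDs the
#'   ratio is monotone everywhere and a signed infinity is returned (+Inf
#'   when the affected mean exceeds the unaffected mean, -Inf otherwise).
#' @export
risk_reversal_point <- function(affected, unaffected) {
  mu_a <- affected$mean; sd_a <- affected$sd
  mu_u <- unaffected$mean; sd_u <- unaffected$sd
  if (isTRUE(all.equal(sd_a, sd_u))) {
    return(if (mu_a >= mu_u) Inf else -Inf)
  }
  (mu_a * sd_u^2 - mu_u * sd_a^2) / (sd_u^2 - sd_a^2)
}

#' Cap truncation limits at the point of risk reversal
#'
#' When the reversal point of [risk_reversal_point()] falls inside a
#' marker's truncation limits, the likelihood ratio would not be monotone
#' over the truncated range. This helper tightens the limit on the
#' reversal side: the upper limit for a marker lowered in affected
#' pregnancies, the lower limit for a raised marker. Limits are unchanged
#' when the reversal lies outside them or the group means coincide.
#'
#' @param truncation Length-2 numeric, MoM scale `c(low, high)`.
#' @param affected,unaffected Lists (or [marker_distribution()]s) with
#'   `mean` and `sd` on the log10 MoM scale.
#' @return The capped `c(low, high)` limits.
#' @export
cap_truncation_at_reversal <- function(truncation, affected, unaffected) {
  if (isTRUE(all.equal(affected$mean, unaffected$mean))) return(truncation)
  x_star <- risk_reversal_point(affected, unaffected)
  if (!is.finite(x_star)) return(truncation)
  rev_mom <- 10^x_star
  if (affected$mean < unaffected$mean) {
    if (rev_mom < truncation[2] && rev_mom > truncation[1]) {
      truncation[2] <- rev_mom
    }
  } else {
    if (rev_mom > truncation[1] && rev_mom < truncation[2]) {
      truncation[1] <- rev_mom
    }
  }
  truncation
}

#' Multivariate test parameters for a screening test
#'
#' Holds the per-group log10 MoM means, SDs, correlation matrices and MoM
#' truncation limits for an ordered set of markers, plus the gestational
#' weeks at which first- and second-trimester markers are measured.
#'
#' @param test Test name (e.g. `"combined"`, `"quadruple"`,
#'   `"serum_integrated"`, `"integrated"`, or any label).
#' @param markers Character vector of marker names (order fixes all other
#'   arguments).
#' @param means,sds Lists with named numeric vectors `affected` and
#'   `unaffected` of length `length(markers)`.
#' @param correlations List with matrices `affected` and `unaffected`.
#' @param truncation Numeric matrix with rows `low`/`high` and one column
#'   per marker, on the MoM scale.
#' @param week_first,week_second Completed weeks of measurement (NA when the
#'   test has no markers in that trimester).
#' @return An object of class `test_parameters`.
#' @export
test_parameters <- function(test, markers, means, sds, correlations,
                            truncation, week_first = NA, week_second = NA) {
  m <- length(markers)
  for (g in c("affected", "unaffected")) {
    assert_that(length(means[[g]]) == m && length(sds[[g]]) == m,
                sprintf("means/sds for group '%s' must match marker count", g))
    assert_that(all(sds[[g]] > 0), "SDs must be positive")
    check_correlation_matrix(correlations[[g]],
                             sprintf("%s correlation matrix", g))
    assert_that(nrow(correlations[[g]]) == m,
                sprintf("%s correlation matrix dimension must match markers", g))
  }
  assert_that(is.matrix(truncation) && ncol(truncation) == m &&
                nrow(truncation) == 2,
              "truncation must be a 2 x n_markers matrix (rows low, high)")
  assert_that(all(truncation[1, ] > 0) && all(truncation[1, ] < truncation[2, ]),
              "truncation limits must satisfy 0 < low < high per marker")
  dimnames(truncation) <- list(c("low", "high"), markers)
  for (g in c("affected", "unaffected")) {
    names(means[[g]]) <- markers
    names(sds[[g]]) <- markers
    dimnames(correlations[[g]]) <- list(markers, markers)
  }
  structure(list(test = test, markers = markers, means = means, sds = sds,
                 correlations = correlations, truncation = truncation,
                 week_first = week_first, week_second = week_second),
            class = "test_parameters")
}

#' @export
print.test_parameters <- function(x, ...) {
  cat(sprintf("Screening test parameters: %s (%d markers: %s)\n",
              x$test, length(x$markers), paste(x$markers, collapse = ", ")))
  wk <- c(first = x$week_first, second = x$week_second)
  wk <- wk[!is.na(wk)]
  if (length(wk)) cat("  measured at completed week(s): ",
                      paste(sprintf("%s=%s", names(wk), wk), collapse = ", "),
                      "\n", sep = "")
  tab <- rbind(`affected mean` = x$means$affected,
               `unaffected mean` = x$means$unaffected,
               `affected sd` = x$sds$affected,
               `unaffected sd` = x$sds$unaffected)
  print(round(tab, 4))
  invisible(x)
}

#' Write / read test parameters as JSON
#'
#' @param x A [test_parameters()] object.
#' @param path File path.
#' @return `read_test_parameters()` returns a `test_parameters` object;
#'   `write_test_parameters()` returns `path` invisibly.
#' @export
write_test_parameters <- function(x, path) {
  stopifnot(inherits(x, "test_parameters"))
  obj <- list(test = x$test, markers = x$markers,
              means = x$means, sds = x$sds,
              correlations = lapply(x$correlations, function(M) unclass(M)),
              truncation = x$truncation,
              week_first = x$week_first, week_second = x$week_second)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_test_parameters
#' @export
read_test_parameters <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  test_parameters(test = obj$test,
                  markers = obj$markers,
                  means = lapply(obj$means, as.numeric),
                  sds = lapply(obj$sds, as.numeric),
                  correlations = lapply(obj$correlations, as.matrix),
                  truncation = as.matrix(obj$truncation),
                  week_first = obj$week_first %||% NA,
                  week_second = obj$week_second %||% NA)
}
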
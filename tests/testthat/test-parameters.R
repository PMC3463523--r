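test_that("probability-plot SD is exact on a noise-free quantile grid", {
  n <- 200
  x <- qnorm((seq_len(n) - 0.5) / n, mean = 0, sd = 0.1556)
  expect_equal(estimate_sd_probability_plot(x), 0.1556, tolerance = 1e-10)
  # location invariance
  expect_equal(estimate_sd_probability_plot(x + 3.7),
               estimate_sd_probability_plot(x), tolerance = 1e-12)
  expect_error(estimate_sd_probability_plot(x[1:10]), "at least 20")
})

test_that("probability-plot SD recovers a simulated log-Gaussian SD", {
  set.seed(101)
  x <- rnorm(500, -0.07, 0.1705)
  expect_lt(abs(estimate_sd_probability_plot(x) - 0.1705), 0.015)
})

test_that("probability-plot SD resists tail outliers better than the raw SD", {
  set.seed(102)
  wins <- 0
  for (i in 1:20) {
    x <- rnorm(475, 0, 0.15)
    contaminated <- c(x, rep(c(-1, 1), length.out = 25))
    pp <- estimate_sd_probability_plot(contaminated)
    raw <- sd(contaminated)
    if (abs(pp - 0.15) < abs(raw - 0.15)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("correlation estimation excludes >3.5 SD pairs once", {
  set.seed(103)
  n <- 10000
  z <- matrix(rnorm(2 * n), ncol = 2) %*% chol(matrix(c(1, 0.3, 0.3, 1), 2))
  r <- estimate_correlation(0.2 * z[, 1], 0.2 * z[, 2])
  expect_lt(abs(as.numeric(r) - 0.3), 0.02)

  x <- rnorm(200, 0, 0.1)
  expect_equal(as.numeric(estimate_correlation(x, x)), 1.0)

  # uncorrelated data with one 10-SD pair: the rule removes it
  set.seed(104)
  x0 <- rnorm(500, 0, 0.1); y0 <- rnorm(500, 0, 0.1)
  x1 <- c(x0, 1.0); y1 <- c(y0, 1.0)   # joint outlier at 10 SD
  r1 <- estimate_correlation(x1, y1)
  expect_gte(attr(r1, "n_excluded"), 1)
  expect_lt(abs(as.numeric(r1)), 0.1)
  # without exclusion the outlier would have induced visible correlation
  expect_gt(cor(x1, y1), as.numeric(r1) + 0.05)
})

test_that("risk reversal point matches the stationarity of the density ratio", {
  aff <- marker_distribution("PlGF", "affected", mean = log10(0.61), sd = 0.1705)
  un <- marker_distribution("PlGF", "unaffected", mean = 0, sd = 0.1556)
  x_star <- risk_reversal_point(aff, un)
  expect_equal(x_star, 1.07, tolerance = 0.005)
  expect_gt(10^x_star, 2.5)  # far above the upper truncation limit

  # independent oracle: the log density ratio has zero derivative at x*
  dratio <- function(x) {
    h <- 1e-6
    f <- function(v) dnorm(v, aff$mean, aff$sd, log = TRUE) -
      dnorm(v, un$mean, un$sd, log = TRUE)
    (f(x + h) - f(x - h)) / (2 * h)
  }
  expect_equal(dratio(x_star), 0, tolerance = 1e-6)

  # equal means: stationary at the common mean
  aff2 <- marker_distribution("m", "affected", mean = 0.1, sd = 0.2)
  un2 <- marker_distribution("m", "unaffected", mean = 0.1, sd = 0.15)
  expect_equal(risk_reversal_point(aff2, un2), 0.1)

  # the stationary point is symmetric in the two distributions
  a3 <- list(mean = -0.2, sd = 0.17); u3 <- list(mean = 0, sd = 0.15)
  expect_equal(risk_reversal_point(a3, u3), risk_reversal_point(u3, a3))

  # equal SDs: monotone everywhere, signed sentinel
  a4 <- list(mean = -0.2, sd = 0.15); u4 <- list(mean = 0, sd = 0.15)
  expect_identical(risk_reversal_point(a4, u4), -Inf)
  expect_identical(risk_reversal_point(u4, a4), Inf)
})

test_that("affected-median regression handles flat and trending data", {
  # constant MoM 0.7: slope 0, every regressed median 0.70
  set.seed(105)
  ga <- sample(77:97, 400, replace = TRUE)
  out <- regress_affected_medians(rep(0.7, 400), ga, "first", weeks = 11:13)
  expect_equal(out$regressed_median, rep(0.7, 3), tolerance = 1e-10)
  expect_equal(attr(out, "weekly_ratio"), 1, tolerance = 1e-10)

  # geometric interpolation: medians 0.85 -> 0.61 over two weeks imply
  # a 15%/week decrease
  expect_equal(1 - (0.61 / 0.85)^(1 / 2), 0.153, tolerance = 0.001)

  # unaffected-style data (median 1 MoM) regress to ~1 every week
  set.seed(106)
  mom <- 10^rnorm(5000, 0, 0.1556)
  ga <- sample(77:97, 5000, replace = TRUE)
  out1 <- regress_affected_medians(mom, ga, "first", weeks = 11:13)
  expect_equal(out1$regressed_median, rep(1, 3), tolerance = 0.02)
})

test_that("second-trimester regression pools weeks 19-22 into one category", {
  set.seed(107)
  ga <- c(sample(98:132, 300, replace = TRUE), sample(133:160, 24, replace = TRUE))
  mom <- 10^rnorm(length(ga), 0, 0.2)
  out <- regress_affected_medians(mom, ga, "second", weeks = 14:18)
  expect_equal(nrow(out), 5)
  expect_true(all(is.finite(out$regressed_median)))
})

test_that("full pipeline recovers generator parameters within MC error", {
  # covariate-free generator: group divisors are exercised elsewhere, and
  # including them here would confound the recovery check with the small
  # re-centring they impose on the cohort median
  cc <- plgf_cohort_config(n_cases = 5000, n_controls_per_case = 1, seed = 11L,
                           smoking_prevalence = 0,
                           afro_caribbean_multiplier = 1)
  cohort <- generate_cohort(cc)
  un <- cohort$outcome == "unaffected"
  fit <- fit_median_regression(cohort, "PlGF", "first")
  mom <- compute_mom(cohort$PlGF, cohort$ga_days, fit)
  wfit <- fit_weight_adjustment(mom[un], cohort$weight_kg[un])
  adj <- adjust_mom(mom, cohort$weight_kg, cohort$smoker, cohort$ethnicity,
                    covariate_adjustment(weight = wfit))
  sd_u <- estimate_sd_probability_plot(log10(adj[un]))
  expect_lt(abs(sd_u - 0.1556), 0.01)
  # affected dispersion is estimated about the gestational median trend
  resid_a <- log10(adj[!un]) -
    log10(0.85 * 0.85^((cohort$ga_days[!un] - 80) / 7))
  sd_a <- estimate_sd_probability_plot(resid_a)
  expect_lt(abs(sd_a - 0.1705), 0.01)
  med <- regress_affected_medians(adj[!un], cohort$ga_days[!un], "first",
                                  weeks = 11:13)
  expect_equal(med$regressed_median, c(0.85, 0.7225, 0.6141), tolerance = 0.03)
})

test_that("test parameters survive a JSON round trip", {
  tp <- standard_test_parameters("combined", week_first = 12, plgf = "first")
  path <- tempfile(fileext = ".json")
  write_test_parameters(tp, path)
  back <- read_test_parameters(path)
  expect_equal(back$markers, tp$markers)
  expect_equal(back$means, tp$means)
  expect_equal(back$correlations, tp$correlations)
  expect_equal(back$truncation, tp$truncation)
  # PlGF affected mean tracks the measurement week
  tp13 <- standard_test_parameters("combined", week_first = 13, plgf = "first")
  expect_equal(unname(tp$means$affected["PlGF_1"]), log10(0.72))
  expect_equal(unname(tp13$means$affected["PlGF_1"]), log10(0.61))
})

test_that("malformed parameter inputs are refused", {
  bad <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(test_parameters("x", c("a", "b"),
                               means = list(affected = c(0, 0), unaffected = c(0, 0)),
                               sds = list(affected = c(0.1, 0.1), unaffected = c(0.1, 0.1)),
                               correlations = list(affected = bad, unaffected = diag(2)),
                               truncation = rbind(c(0.4, 0.4), c(2.5, 2.5))),
               "positive semi-definite")
  expect_error(marker_distribution("m", "affected", 0, sd = -1), "positive")
})
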
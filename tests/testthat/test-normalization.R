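test_that("median regression recovers the gestational-age trends", {
  # first trimester: +31%/week means slope log10(1.31)/7 per day
  cohort <- generate_cohort(plgf_cohort_config(n_cases = 100,
                                               n_controls_per_case = 100,
                                               seed = 2L))
  fit <- fit_median_regression(cohort, "PlGF", "first")
  expect_equal(fit$slope, log10(1.31) / 7, tolerance = 0.02)

  # second trimester: weekly ratio of predicted medians = 1.19
  cohort2 <- generate_cohort(plgf_cohort_config(n_cases = 100,
                                                n_controls_per_case = 100,
                                                trimester = "second", seed = 2L))
  fit2 <- fit_median_regression(cohort2, "PlGF", "second")
  expect_equal(10^(7 * fit2$slope), 1.19, tolerance = 0.02)
})

test_that("constant concentrations give zero slope and MoM = conc/median", {
  records <- data.frame(ga_days = rep(77:97, 3), PlGF = 5)
  fit <- fit_median_regression(records, "PlGF", "first")
  expect_equal(fit$slope, 0, tolerance = 1e-12)
  expect_equal(compute_mom(c(5, 10, 2.5), c(80, 85, 90), fit), c(1, 2, 0.5),
               tolerance = 1e-12)
})

test_that("MoM algebra follows the fitted log-linear model", {
  fit <- structure(list(marker = "PlGF", trimester = "first", width_days = 2L,
                        intercept = log10(30) - log10(1.31) / 7 * 87,
                        slope = log10(1.31) / 7,
                        categories = NULL, ga_range = c(77, 97)),
                   class = "median_regression")
  med87 <- 10^(fit$intercept + fit$slope * 87)
  expect_equal(compute_mom(med87, 87, fit), 1)
  expect_equal(compute_mom(2 * med87, 87, fit), 2)
  # fixed concentration one week later: MoM falls by the weekly growth factor
  expect_equal(compute_mom(med87, 94, fit), 1 / 1.31, tolerance = 1e-12)
  expect_error(compute_mom(-1, 87, fit), "positive")
  expect_warning(compute_mom(med87, 160, fit), "extrapolation")
})

test_that("weight regression recovers the configured per-5kg effect", {
  for (case in list(list(tri = "first", eff = -0.013, name = "-1.3%"),
                    list(tri = "second", eff = -0.031, name = "-3.1%"))) {
    cc <- plgf_cohort_config(n_cases = 100, n_controls_per_case = 100,
                             trimester = case$tri, seed = 4L,
                             weight_per5kg = case$eff,
                             smoking_multiplier = 1,
                             afro_caribbean_multiplier = 1)
    cohort <- generate_cohort(cc)
    un <- cohort[cohort$outcome == "unaffected", ]
    fit <- fit_median_regression(un, "PlGF", case$tri)
    mom <- compute_mom(un$PlGF, un$ga_days, fit)
    wfit <- fit_weight_adjustment(mom, un$weight_kg)
    expect_equal(100 * wfit$per5kg, 100 * case$eff, tolerance = 0.5)
    # the recovered slope is insensitive to the bin-width choice
    for (bw in c(4, 6)) {
      alt <- fit_weight_adjustment(mom, un$weight_kg, bin_width = bw)
      expect_lt(abs(100 * alt$per5kg - 100 * wfit$per5kg), 0.2)
    }
  }
})

test_that("weight-independent data yield a near-zero weight slope", {
  cc <- plgf_cohort_config(n_cases = 100, n_controls_per_case = 100,
                           seed = 4L, weight_per5kg = 0,
                           smoking_multiplier = 1, afro_caribbean_multiplier = 1)
  cohort <- generate_cohort(cc)
  un <- cohort[cohort$outcome == "unaffected", ]
  mom <- compute_mom(un$PlGF, un$ga_days,
                     fit_median_regression(un, "PlGF", "first"))
  wfit <- fit_weight_adjustment(mom, un$weight_kg)
  expect_lt(abs(100 * wfit$per5kg), 0.5)
})

test_that("covariate divisors normalise the flagged groups to 1 MoM", {
  m1 <- covariate_adjustment(smoking_divisor = 1.32,
                             ethnicity_divisors = c(afro_caribbean = 1.18))
  expect_equal(adjust_mom(1.32, 66, TRUE, "white", m1), 1.0)
  m2 <- covariate_adjustment(smoking_divisor = 1.36,
                             ethnicity_divisors = c(afro_caribbean = 1.30))
  expect_equal(adjust_mom(1.30, 66, FALSE, "afro_caribbean", m2), 1.0)
  # non-smoking white woman: unchanged
  expect_equal(adjust_mom(0.9, 66, FALSE, "white", m1), 0.9)
  # unknown label: no adjustment, reported
  expect_message(out <- adjust_mom(1.5, 66, FALSE, "unknown_group", m1),
                 "unrecognised")
  expect_equal(out, 1.5)
})

test_that("group factor estimation brackets the configured multiplier", {
  set.seed(31)
  ref <- 10^rnorm(1000, 0, 0.18)
  grp <- 1.36 * 10^rnorm(1000, 0, 0.18)
  est <- estimate_group_factor(c(grp, ref), c(rep(TRUE, 1000), rep(FALSE, 1000)))
  expect_equal(est$estimate, 1.36, tolerance = 0.05 / 1.36)
  expect_true(est$ci[1] < 1.36 && 1.36 < est$ci[2])
  expect_true(est$reliable)

  same <- estimate_group_factor(c(ref, ref), c(rep(TRUE, 1000), rep(FALSE, 1000)))
  expect_equal(same$estimate, 1.0, tolerance = 0.05)
  expect_true(same$ci[1] <= 1 && 1 <= same$ci[2])

  tiny <- estimate_group_factor(ref[1:30], c(rep(TRUE, 5), rep(FALSE, 25)))
  expect_false(tiny$reliable)
})

test_that("MoM computation is invariant to uniform rescaling of units", {
  cohort <- generate_cohort(plgf_cohort_config(n_cases = 50, seed = 6L))
  fit1 <- fit_median_regression(cohort, "PlGF", "first")
  mom1 <- compute_mom(cohort$PlGF, cohort$ga_days, fit1)
  cohort$PlGF <- cohort$PlGF * 1000   # e.g. pg/mL -> ng/L
  fit2 <- fit_median_regression(cohort, "PlGF", "first")
  mom2 <- compute_mom(cohort$PlGF, cohort$ga_days, fit2)
  expect_equal(mom1, mom2, tolerance = 1e-10)
})

test_that("weight adjustment is idempotent: re-fit on adjusted MoMs is flat", {
  cc <- plgf_cohort_config(n_cases = 100, n_controls_per_case = 50, seed = 8L)
  cohort <- generate_cohort(cc)
  un <- cohort[cohort$outcome == "unaffected", ]
  mom <- compute_mom(un$PlGF, un$ga_days,
                     fit_median_regression(un, "PlGF", "first"))
  wfit <- fit_weight_adjustment(mom, un$weight_kg)
  adj <- adjust_mom(mom, un$weight_kg, rep(FALSE, nrow(un)),
                    rep("white", nrow(un)), covariate_adjustment(weight = wfit))
  refit <- fit_weight_adjustment(adj, un$weight_kg)
  expect_lt(abs(100 * refit$per5kg), 0.3)
  # and the adjusted median is ~1 in every gestational-age category
  for (cat in split(adj, floor(un$ga_days / 2))) {
    se <- 1.2533 * 0.1556 / sqrt(length(cat))
    expect_lt(abs(log10(median(cat))), 4 * se)
  }
})
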
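#' Simulate posterior risks for affected and unaffected pregnancies
#'
#' Monte Carlo engine behind the screening-performance tables: draws
#' hypothetical cohorts of affected and unaffected pregnancies (default
#' 250,000 each), assigns each a maternal age — unaffected pregnancies from
#' the maternity age histogram, affected pregnancies from the histogram
#' re-weighted by the age-specific mid-trimester odds — draws a log10 MoM
#' profile from the group's multivariate Gaussian, truncates it, and
#' computes the posterior risk.
#'
#' @param params A [test_parameters()] object.
#' @param n_affected,n_unaffected Simulated pregnancies per group.
#' @param age_dist A [maternal_age_distribution()].
#' @param age_model An [age_risk_model()].
#' @param seed Integer seed; results are fully reproducible from it.
#' @return A list of class `simulated_risks` with numeric vectors
#'   `affected` and `unaffected` of posterior risks, plus the simulation
#'   metadata.
#' @export
simulate_risks <- function(params, n_affected = 250000, n_unaffected = 250000,
                           age_dist = maternal_age_distribution(),
                           age_model = age_risk_model(), seed = 1L) {
  stopifnot(inherits(params, "test_parameters"))
  assert_that(n_affected > 0 && n_unaffected > 0, "n must be positive")
  set.seed(seed)
  aff_ages <- affected_age_distribution(age_dist, age_model)
  m <- length(params$markers)
  draw <- function(n, group, ages_dist) {
    age <- sample(ages_dist$age, n, replace = TRUE, prob = ages_dist$prob)
    sig <- make_covariance(params$sds[[group]], params$correlations[[group]])
    x <- rmvnorm_chol(n, params$means[[group]], sig)
    lr <- likelihood_ratio(x, params)
    odds <- midtrimester_prior_odds(age, age_model) * lr
    odds / (1 + odds)
  }
  structure(list(affected = draw(n_affected, "affected", aff_ages),
                 unaffected = draw(n_unaffected, "unaffected", age_dist),
                 test = params$test,
                 week_first = params$week_first,
                 week_second = params$week_second,
                 n = c(affected = n_affected, unaffected = n_unaffected),
                 seed = seed),
            class = "simulated_risks")
}

#' Detection rate at a fixed false-positive rate
#'
#' The risk cutoff is the empirical (1 - fpr) quantile of the unaffected
#' risks (higher-interpolation convention, so the realised FPR never
#' exceeds the target), and the detection rate is the proportion of
#' affected risks greater than or equal to that cutoff — ties at the cutoff
#' count as screen positive.
#'
#' @param risks_affected,risks_unaffected Numeric vectors of posterior
#'   risks (or any monotone score).
#' @param fpr Target false-positive rate as a proportion in (0, 1].
#' @return Detection rate in percent.
#' @export
dr_for_fpr <- function(risks_affected, risks_unaffected, fpr) {
  assert_that(length(risks_affected) > 0 && length(risks_unaffected) > 0,
              "risk arrays must be non-empty")
  assert_that(fpr > 0 && fpr <= 1, "fpr must be in (0, 1]")
  if (fpr == 1) return(100)
  cutoff <- stats::quantile(risks_unaffected, 1 - fpr, type = 1, names = FALSE)
  100 * mean(risks_affected >= cutoff)
}

#' False-positive rate at a fixed detection rate
#'
#' Mirror of [dr_for_fpr()]: the cutoff is the empirical (1 - dr) quantile
#' of the affected risks; the FPR is the proportion of unaffected risks at
#' or above it.
#'
#' @inheritParams dr_for_fpr
#' @param dr Target detection rate as a proportion in (0, 1].
#' @return False-positive rate in percent.
#' @export
fpr_for_dr <- function(risks_affected, risks_unaffected, dr) {
  assert_that(length(risks_affected) > 0 && length(risks_unaffected) > 0,
              "risk arrays must be non-empty")
  assert_that(dr > 0 && dr <= 1, "dr must be in (0, 1]")
  cutoff <- stats::quantile(risks_affected, 1 - dr, type = 1, names = FALSE)
  100 * mean(risks_unaffected >= cutoff)
}

#' Detection and false-positive rate at a risk cutoff, with OAPR
#'
#' Classifies both groups as screen positive at a fixed risk cutoff
#' (inclusive, "greater than or equal to") and reports the odds of being
#' affected given a positive result: OAPR = (DR x p) : (FPR x (1 - p))
#' where p is the mid-trimester prevalence implied by the maternity age
#' distribution and the age-risk model.
#'
#' @inheritParams dr_for_fpr
#' @param cutoff Risk cutoff as a probability (e.g. 1/150).
#' @param prevalence Mid-trimester prevalence p; see [implied_prevalence()].
#' @return A list with `dr` and `fpr` (percent), `oapr_n` (the N in 1:N,
#'   `Inf` when no unaffected pregnancy screens positive, and capped in the
#'   printed form at 1:>10,000) and `oapr` (the formatted string).
#' @export
rates_at_cutoff <- function(risks_affected, risks_unaffected, cutoff,
                            prevalence) {
  dr <- 100 * mean(risks_affected >= cutoff)
  fpr <- 100 * mean(risks_unaffected >= cutoff)
  num <- dr * prevalence
  den <- fpr * (1 - prevalence)
  oapr_n <- if (num <= 0) Inf else den / num
  oapr <- if (!is.finite(oapr_n) || oapr_n > 10000) "1:>10,000"
          else sprintf("1:%d", round(oapr_n))
  list(dr = dr, fpr = fpr, oapr_n = oapr_n, oapr = oapr)
}

#' Screening performance summary for a simulated test
#'
#' Produces the standard performance grids from simulated risks: DR at
#' target FPRs (default 1, 3, 5%), FPR at target DRs (default 85, 90, 95%),
#' and DR/FPR/OAPR at fixed risk cutoffs (default 1 in 100, 150, 200).
#' Binomial Monte Carlo standard errors accompany every rate.
#'
#' @param sim A [simulate_risks()] result.
#' @param fprs,drs Target rates, as proportions.
#' @param cutoffs Risk cutoffs as probabilities.
#' @param prevalence Mid-trimester prevalence used for the OAPR; defaults
#'   to the prevalence implied by the packaged age distribution and default
#'   age model.
#' @return An object of class `performance_summary` with data frames
#'   `dr_for_fpr`, `fpr_for_dr` and `at_cutoff`, plus metadata.
#' @export
screening_performance <- function(sim,
                                  fprs = c(0.01, 0.03, 0.05),
                                  drs = c(0.85, 0.90, 0.95),
                                  cutoffs = c(1 / 100, 1 / 150, 1 / 200),
                                  prevalence = NULL) {
  stopifnot(inherits(sim, "simulated_risks"))
  if (is.null(prevalence)) {
    prevalence <- implied_prevalence(maternal_age_distribution(), age_risk_model())
  }
  n_a <- length(sim$affected)
  n_u <- length(sim$unaffected)
  se <- function(p, n) 100 * sqrt(p * (1 - p) / n)

  dr_grid <- data.frame(fpr_target = 100 * fprs,
                        dr = vapply(fprs, function(f)
                          dr_for_fpr(sim$affected, sim$unaffected, f), numeric(1)))
  dr_grid$dr_se <- se(dr_grid$dr / 100, n_a)

  fpr_grid <- data.frame(dr_target = 100 * drs,
                         fpr = vapply(drs, function(d)
                           fpr_for_dr(sim$affected, sim$unaffected, d), numeric(1)))
  fpr_grid$fpr_se <- se(fpr_grid$fpr / 100, n_u)

  at_cut <- do.call(rbind, lapply(cutoffs, function(ct) {
    r <- rates_at_cutoff(sim$affected, sim$unaffected, ct, prevalence)
    data.frame(cutoff_one_in = round(1 / ct), dr = r$dr, fpr = r$fpr,
               oapr = r$oapr, stringsAsFactors = FALSE)
  }))

  structure(list(test = sim$test,
                 week_first = sim$week_first,
                 week_second = sim$week_second,
                 n = sim$n, seed = sim$seed,
                 prevalence = prevalence,
                 dr_for_fpr = dr_grid,
                 fpr_for_dr = fpr_grid,
                 at_cutoff = at_cut),
            class = "performance_summary")
}

#' @export
print.performance_summary <- function(x, ...) {
  cat(sprintf("Screening performance: %s (n = %s + %s, seed %s)\n", x$test,
              format(x$n[1], big.mark = ","), format(x$n[2], big.mark = ","),
              x$seed))
  if (!is.na(x$week_first)) cat("  first-trimester markers at", x$week_first,
                                "completed weeks\n")
  cat("  DR (%) for FPR of:  ",
      paste(sprintf("%g%%: %.1f", x$dr_for_fpr$fpr_target, x$dr_for_fpr$dr),
            collapse = "   "), "\n")
  cat("  FPR (%) for DR of:  ",
      paste(sprintf("%g%%: %.1f", x$fpr_for_dr$dr_target, x$fpr_for_dr$fpr),
            collapse = "   "), "\n")
  cat("  At risk cutoffs:    ",
      paste(sprintf("1/%d: DR %.0f FPR %.1f OAPR %s", x$at_cutoff$cutoff_one_in,
                    x$at_cutoff$dr, x$at_cutoff$fpr, x$at_cutoff$oapr),
            collapse = "   "), "\n")
  invisible(x)
}

#' Average weekly performance summaries
#'
#' Combines the summaries obtained with first-trimester markers measured at
#' 11, 12 and 13 completed weeks into a single overall summary by taking
#' the arithmetic mean of each DR and FPR cell, corresponding to equal
#' numbers of women screened at each week.
#'
#' @param summaries List of [screening_performance()] summaries for the
#'   same test at different weeks (typically three: weeks 11, 12, 13).
#' @return A `performance_summary` whose grids are cell-wise means.
#' @export
average_over_weeks <- function(summaries) {
  assert_that(length(summaries) >= 2, "need at least two weekly summaries")
  tests <- vapply(summaries, function(s) s$test, character(1))
  assert_that(length(unique(tests)) == 1,
              sprintf("summaries are for different tests: %s",
                      paste(unique(tests), collapse = ", ")))
  out <- summaries[[1]]
  for (f in c("dr_for_fpr", "fpr_for_dr")) {
    for (col in setdiff(names(out[[f]]), c("fpr_target", "dr_target"))) {
      out[[f]][[col]] <- rowMeans(vapply(summaries, function(s) s[[f]][[col]],
                                         numeric(nrow(out[[f]]))))
    }
  }
  for (col in c("dr", "fpr")) {
    out$at_cutoff[[col]] <- rowMeans(vapply(summaries,
                                            function(s) s$at_cutoff[[col]],
                                            numeric(nrow(out$at_cutoff))))
  }
  num <- out$at_cutoff$dr * out$prevalence
  den <- out$at_cutoff$fpr * (1 - out$prevalence)
  out$at_cutoff$oapr <- ifelse(num <= 0 | den / num > 10000, "1:>10,000",
                               sprintf("1:%d", round(den / num)))
  out$week_first <- NA
  out$test <- paste0(out$test, " (averaged over weeks ",
                     paste(vapply(summaries, function(s) as.character(s$week_first),
                                  character(1)), collapse = ", "), ")")
  out
}

#' Closed-form univariate detection rate at a fixed FPR
#'
#' Analytic oracle for a single log-Gaussian marker: with the affected mean
#' below the unaffected mean the screen-positive region at a given FPR is
#' the lower tail of the unaffected distribution (upper tail when the
#' affected mean is higher), and
#' \deqn{DR = \Phi\left(\frac{\sigma_u \Phi^{-1}(fpr)}{\sigma_a} +
#'   \frac{|\mu_a - \mu_u|}{\sigma_a}\right) \times 100.}
#'
#' @param mean_a Affected mean (log10 MoM).
#' @param sd_a,sd_u Affected / unaffected SDs (log10 MoM).
#' @param fpr Target FPR as a proportion.
#' @param mean_u Unaffected mean (default 0).
#' @return Detection rate in percent.
#' @export
dr_for_fpr_univariate <- function(mean_a, sd_a, sd_u, fpr, mean_u = 0) {
  assert_that(fpr > 0 && fpr < 1, "fpr must be in (0, 1)")
  if (mean_a <= mean_u) {
    cutoff <- mean_u + sd_u * stats::qnorm(fpr)
    100 * stats::pnorm((cutoff - mean_a) / sd_a)
  } else {
    cutoff <- mean_u + sd_u * stats::qnorm(1 - fpr)
    100 * stats::pnorm((mean_a - cutoff) / sd_a)
  }
}

#' Monte Carlo univariate detection rate at a fixed FPR
#'
#' Marker-only Monte Carlo companion to [dr_for_fpr_univariate()]: draws
#' log10 MoM values for both groups, ranks them by the univariate
#' likelihood ratio within truncation limits, and applies [dr_for_fpr()].
#'
#' @param affected,unaffected [marker_distribution()] objects.
#' @param fpr Target FPR as a proportion.
#' @param n Simulated pregnancies per group.
#' @param seed Integer seed.
#' @return Detection rate in percent.
#' @export
dr_for_fpr_univariate_mc <- function(affected, unaffected, fpr,
                                     n = 250000, seed = 1L) {
  params <- test_parameters(
    test = affected$marker, markers = affected$marker,
    means = list(affected = affected$mean, unaffected = unaffected$mean),
    sds = list(affected = affected$sd, unaffected = unaffected$sd),
    correlations = list(affected = diag(1), unaffected = diag(1)),
    truncation = matrix(affected$truncation, ncol = 1))
  set.seed(seed)
  x_a <- matrix(stats::rnorm(n, affected$mean, affected$sd), ncol = 1)
  x_u <- matrix(stats::rnorm(n, unaffected$mean, unaffected$sd), ncol = 1)
  dr_for_fpr(likelihood_ratio(x_a, params), likelihood_ratio(x_u, params), fpr)
}
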
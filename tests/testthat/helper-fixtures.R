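# Shared fixtures: cohort configurations reproducing the study conditions,
# and small parameter-building shortcuts.

# PlGF-only cohort config. Defaults reproduce the first-trimester study
# arm: affected median 0.85 MoM at 11 completed weeks falling 15%/week,
# unaffected median rising 31%/week, probability-plot SDs 0.1705/0.1556,
# -1.3%/5 kg weight effect, smokers 32% higher, Afro-Caribbean women 18%
# higher.
plgf_cohort_config <- function(n_cases = 289, n_controls_per_case = 2,
                               trimester = c("first", "second"),
                               seed = 1L, sd_affected = NULL,
                               sd_unaffected = NULL, weight_per5kg = NULL,
                               smoking_multiplier = NULL,
                               afro_caribbean_multiplier = NULL,
                               smoking_prevalence = 0.077, ...) {
  trimester <- match.arg(trimester)
  if (trimester == "first") {
    marker <- list(PlGF = list(
      ref_median = 30, weekly_growth = 0.31, ref_day = 87,
      affected_mom = 0.85, affected_weekly_ratio = 0.85,
      weight_per5kg = weight_per5kg %||% -0.013,
      smoking_multiplier = smoking_multiplier %||% 1.32,
      ethnicity_multipliers = c(afro_caribbean = afro_caribbean_multiplier %||% 1.18)))
    sds <- list(affected = sd_affected %||% 0.1705,
                unaffected = sd_unaffected %||% 0.1556)
    ga <- c(77, 97)
    anchor <- 11
  } else {
    marker <- list(PlGF = list(
      ref_median = 150, weekly_growth = 0.19, ref_day = 115,
      affected_mom = 0.69, affected_weekly_ratio = 1.11,
      weight_per5kg = weight_per5kg %||% -0.031,
      smoking_multiplier = smoking_multiplier %||% 1.36,
      ethnicity_multipliers = c(afro_caribbean = afro_caribbean_multiplier %||% 1.30)))
    sds <- list(affected = sd_affected %||% 0.2243,
                unaffected = sd_unaffected %||% 0.1786)
    ga <- c(98, 125)
    anchor <- 14
  }
  cohort_config(n_cases = n_cases, n_controls_per_case = n_controls_per_case,
                ga_range = ga, markers = marker, sd_log10 = sds,
                affected_anchor_week = anchor,
                smoking_prevalence = smoking_prevalence, seed = seed, ...)
}

# Noise-free, covariate-free config: every generated concentration sits
# exactly on the gestational-age median.
degenerate_config <- function(n_cases = 5, seed = 1L) {
  cohort_config(
    n_cases = n_cases, n_controls_per_case = 2, ga_range = c(77, 97),
    markers = list(PlGF = list(ref_median = 30, weekly_growth = 0.31,
                               ref_day = 87)),
    sd_log10 = list(affected = 0, unaffected = 0),
    smoking_prevalence = 0, seed = seed)
}

# Univariate test_parameters from an affected/unaffected distribution pair.
univariate_params <- function(affected, unaffected) {
  test_parameters(
    test = affected$marker, markers = affected$marker,
    means = list(affected = affected$mean, unaffected = unaffected$mean),
    sds = list(affected = affected$sd, unaffected = unaffected$sd),
    correlations = list(affected = diag(1), unaffected = diag(1)),
    truncation = matrix(affected$truncation, ncol = 1))
}

# True unaffected PlGF median of the first-trimester fixture at a GA.
plgf_true_median_t1 <- function(ga_days) 30 * 1.31^((ga_days - 87) / 7)
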
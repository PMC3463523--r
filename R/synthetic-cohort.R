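#' Configuration for a synthetic nested case-control cohort
#'
#' Describes the generative model for a screening cohort: marker medians
#' follow log-linear gestational-age trends in unaffected pregnancies,
#' affected pregnancies have a configurable median MoM trend, individual
#' log10 MoM deviations are multivariate Gaussian, and maternal covariates
#' (weight, smoking, ethnicity) act multiplicatively on concentrations.
#'
#' Marker blocks are named lists with elements:
#' \describe{
#'   \item{ref_median}{median concentration in unaffected pregnancies at
#'     `ref_day` (arbitrary units).}
#'   \item{weekly_growth}{fractional change of the unaffected median per
#'     week of gestation (e.g. 0.31 for +31\%/week).}
#'   \item{ref_day}{gestational age (days) at which `ref_median` applies.}
#'   \item{affected_mom}{median MoM in affected pregnancies at
#'     `affected_anchor_week` completed weeks (evaluated at week + 3 days).}
#'   \item{affected_weekly_ratio}{multiplicative change of the affected
#'     median MoM per week (e.g. 0.85 for -15\%/week).}
#'   \item{weight_per5kg}{fractional change in MoM per 5 kg of maternal
#'     weight (e.g. -0.013).}
#'   \item{smoking_multiplier}{multiplier applied to smokers' levels.}
#'   \item{ethnicity_multipliers}{named numeric vector of multipliers, e.g.
#'     `c(afro_caribbean = 1.18)`; unnamed groups are unaffected.}
#' }
#'
#' @param n_cases Number of affected pregnancies.
#' @param n_controls_per_case Unaffected pregnancies generated per case.
#' @param ga_range Gestational-age range sampled (days, inclusive); days are
#'   drawn uniformly, the default for a cohort whose day-level mix is not
#'   otherwise specified.
#' @param markers Named list of marker blocks (see Details).
#' @param sd_log10 List with numeric vectors `affected` and `unaffected`:
#'   per-marker SDs of log10 MoM.
#' @param correlation List with correlation matrices `affected` and
#'   `unaffected` (marker order as in `markers`); defaults to identity.
#' @param affected_anchor_week Completed week anchoring `affected_mom`.
#' @param age_distribution A [maternal_age_distribution()] for sampling
#'   maternal age.
#' @param weight_median_kg,weight_sd_log10 Log-normal maternal weight model
#'   (median 66 kg and a log10 SD of 0.07 give the interquartile spread seen
#'   in routine screening populations).
#' @param smoking_prevalence Probability of being a smoker.
#' @param ethnicity_proportions Named probabilities over
#'   afro_caribbean/white/south_asian/oriental/other.
#' @param storage_range_months Uniform range of sample storage duration.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `cohort_config`.
#' @seealso [generate_cohort()], [match_controls()]
#' @export
cohort_config <- function(n_cases,
                          n_controls_per_case = 2,
                          ga_range = c(77, 97),
                          markers,
                          sd_log10,
                          correlation = NULL,
                          affected_anchor_week = 11,
                          age_distribution = maternal_age_distribution(),
                          weight_median_kg = 66,
                          weight_sd_log10 = 0.07,
                          smoking_prevalence = 0.077,
                          ethnicity_proportions = c(afro_caribbean = 0.10,
                                                    white = 0.73,
                                                    south_asian = 0.057,
                                                    oriental = 0.033,
                                                    other = 0.08),
                          storage_range_months = c(0, 60),
                          seed = 1L) {
  assert_that(length(markers) >= 1 && !is.null(names(markers)),
              "at least one named marker block is required")
  m <- length(markers)
  if (is.null(correlation)) {
    correlation <- list(affected = diag(m), unaffected = diag(m))
  }
  for (g in c("affected", "unaffected")) {
    assert_that(length(sd_log10[[g]]) == m,
                sprintf("sd_log10$%s must have one SD per marker", g))
    assert_that(all(sd_log10[[g]] >= 0), "SDs must be non-negative")
    check_correlation_matrix(correlation[[g]],
                             sprintf("%s correlation matrix", g))
    assert_that(nrow(correlation[[g]]) == m,
                sprintf("%s correlation matrix dimension must match markers", g))
  }
  for (nm in names(markers)) {
    mk <- markers[[nm]]
    assert_that(mk$ref_median > 0, sprintf("marker %s: ref_median must be > 0", nm))
    mults <- c(mk$smoking_multiplier %||% 1, mk$ethnicity_multipliers %||% numeric(0))
    assert_that(all(mults > 0), sprintf("marker %s: multipliers must be > 0", nm))
  }
  assert_that(ga_range[1] >= 77 && ga_range[2] <= 160 && ga_range[1] <= ga_range[2],
              "ga_range must lie within [77, 160] days")
  ethnicity_proportions <- ethnicity_proportions / sum(ethnicity_proportions)
  structure(list(n_cases = n_cases,
                 n_controls_per_case = n_controls_per_case,
                 ga_range = ga_range,
                 markers = markers,
                 sd_log10 = sd_log10,
                 correlation = correlation,
                 affected_anchor_week = affected_anchor_week,
                 age_distribution = age_distribution,
                 weight_median_kg = weight_median_kg,
                 weight_sd_log10 = weight_sd_log10,
                 smoking_prevalence = smoking_prevalence,
                 ethnicity_proportions = ethnicity_proportions,
                 storage_range_months = storage_range_months,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Expected median concentration for one marker given group and covariates.
marker_median <- function(mk, group, ga_days, weight_kg, smoker, ethnicity,
                          weight_median_kg, anchor_week) {
  med <- mk$ref_median * (1 + mk$weekly_growth)^((ga_days - mk$ref_day) / 7)
  w5 <- mk$weight_per5kg %||% 0
  med <- med * (1 + w5)^((weight_kg - weight_median_kg) / 5)
  sm <- mk$smoking_multiplier %||% 1
  med <- med * ifelse(smoker, sm, 1)
  em <- mk$ethnicity_multipliers %||% numeric(0)
  if (length(em)) {
    f <- ifelse(ethnicity %in% names(em), em[ethnicity], 1)
    med <- med * unname(f)
  }
  if (group == "affected") {
    anchor_day <- anchor_week * 7 + 3
    mom <- (mk$affected_mom %||% 1) *
      (mk$affected_weekly_ratio %||% 1)^((ga_days - anchor_day) / 7)
    med <- med * mom
  }
  med
}

#' Generate a synthetic screening cohort
#'
#' Draws affected and unaffected pregnancy records from the generative model
#' in a [cohort_config()]: covariates are sampled from their configured
#' distributions, each marker's concentration is log-Gaussian around a
#' gestational-age- and covariate-dependent median, and log10 deviations are
#' correlated across markers within a pregnancy.
#'
#' @param config A [cohort_config()].
#' @return A data frame with one row per pregnancy: `id`, `outcome`,
#'   `ga_days`, `maternal_age_edd`, `weight_kg`, `smoker`, `ethnicity`,
#'   `storage_months`, and one concentration column per marker.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_aff <- config$n_cases
  n_un <- config$n_cases * config$n_controls_per_case
  n <- n_aff + n_un
  outcome <- rep(c("affected", "unaffected"), c(n_aff, n_un))

  ga_days <- sample(seq(config$ga_range[1], config$ga_range[2]), n, replace = TRUE)
  age <- sample(config$age_distribution$age, n, replace = TRUE,
                prob = config$age_distribution$prob)
  weight <- config$weight_median_kg *
    10^(stats::rnorm(n, 0, config$weight_sd_log10))
  smoker <- stats::runif(n) < config$smoking_prevalence
  ethnicity <- sample(names(config$ethnicity_proportions), n, replace = TRUE,
                      prob = config$ethnicity_proportions)
  storage <- stats::runif(n, config$storage_range_months[1],
                          config$storage_range_months[2])

  out <- data.frame(id = sprintf("P%05d", seq_len(n)),
                    outcome = outcome,
                    ga_days = ga_days,
                    maternal_age_edd = age,
                    weight_kg = weight,
                    smoker = smoker,
                    ethnicity = ethnicity,
                    storage_months = round(storage, 1),
                    stringsAsFactors = FALSE)

  mnames <- names(config$markers)
  for (g in c("affected", "unaffected")) {
    idx <- which(outcome == g)
    sig <- make_covariance(config$sd_log10[[g]], config$correlation[[g]])
    eps <- rmvnorm_chol(length(idx), rep(0, length(mnames)), sig)
    for (j in seq_along(mnames)) {
      mk <- config$markers[[j]]
      med <- marker_median(mk, g, ga_days[idx], weight[idx], smoker[idx],
                           ethnicity[idx], config$weight_median_kg,
                           config$affected_anchor_week)
      out[idx, mnames[j]] <- med * 10^eps[, j]
    }
  }
  out
}

# Banding rules used for matched-control selection: 5-year maternal age
# bands anchored at multiples of 5, 6-month storage bands anchored at 0.
age_band <- function(age) floor(age / 5) * 5
storage_band <- function(months) floor(months / 6)

#' Select matched unaffected controls for affected cases
#'
#' Matches each case with `ratio` unaffected controls on gestational age
#' (same day), maternal age (same 5-year band) and sample storage duration
#' (same six-month band), sampling without replacement. Ties are broken in
#' first-come order after a seeded shuffle of the pool so that the matched
#' set is reproducible.
#'
#' @param cases Data frame of affected records (as from [generate_cohort()]).
#' @param pool Data frame of candidate unaffected records.
#' @param ratio Controls required per case.
#' @param seed Integer seed for the pool shuffle.
#' @return A data frame of the selected controls with a `matched_case_id`
#'   column.
#' @export
match_controls <- function(cases, pool, ratio = 2, seed = 1L) {
  needed <- c("id", "ga_days", "maternal_age_edd", "storage_months")
  assert_that(all(needed %in% names(cases)) && all(needed %in% names(pool)),
              "cases and pool need id, ga_days, maternal_age_edd, storage_months")
  set.seed(seed)
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  key <- function(d) paste(d$ga_days, age_band(d$maternal_age_edd),
                           storage_band(d$storage_months), sep = "|")
  pool_key <- key(pool)
  case_key <- key(cases)
  taken <- rep(FALSE, nrow(pool))
  picks <- vector("list", nrow(cases))
  unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    avail <- which(pool_key == case_key[i] & !taken)
    if (length(avail) < ratio) {
      unmatched <- c(unmatched, cases$id[i])
      next
    }
    sel <- avail[seq_len(ratio)]
    taken[sel] <- TRUE
    picks[[i]] <- sel
  }
  if (length(unmatched)) {
    stop(sprintf("insufficient matching controls for %d case(s): %s",
                 length(unmatched), paste(unmatched, collapse = ", ")),
         call. = FALSE)
  }
  sel <- unlist(picks)
  out <- pool[sel, , drop = FALSE]
  out$matched_case_id <- rep(cases$id, each = ratio)
  rownames(out) <- NULL
  out
}
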
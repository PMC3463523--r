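#' Fit the gestational-age median regression for a marker
#'
#' Estimates the expected (median) marker concentration as a log-linear
#' function of gestational age in unaffected pregnancies: records are
#' grouped into gestational-age categories (2-day categories in the first
#' trimester, weekly categories in the second), the log10 of each category
#' median is regressed on the category median gestational age, weighted by
#' the number of women in each category.
#'
#' @param records Data frame with columns `ga_days`, the marker
#'   concentration column, and optionally `outcome` (rows with
#'   `outcome != "unaffected"` are dropped) and `id` (used in error
#'   messages).
#' @param marker Name of the concentration column.
#' @param trimester `"first"` (2-day categories) or `"second"` (weekly).
#' @return An object of class `median_regression` with the fitted intercept
#'   and slope (log10 concentration per day), the category table kept for
#'   diagnostics, and the fitted gestational-age range.
#' @seealso [compute_mom()]
#' @export
fit_median_regression <- function(records, marker,
                                  trimester = c("first", "second")) {
  trimester <- match.arg(trimester)
  assert_that(marker %in% names(records),
              sprintf("no column '%s' in records", marker))
  if ("outcome" %in% names(records)) {
    records <- records[records$outcome == "unaffected", , drop = FALSE]
  }
  conc <- records[[marker]]
  bad <- which(!is.finite(conc) | conc <= 0)
  if (length(bad)) {
    ids <- if ("id" %in% names(records)) records$id[bad] else bad
    stop(sprintf("non-positive %s concentrations for records: %s", marker,
                 paste(utils::head(ids, 10), collapse = ", ")), call. = FALSE)
  }
  width <- if (trimester == "first") 2L else 7L
  cat_id <- floor(records$ga_days / width)
  tab <- do.call(rbind, lapply(split(seq_along(cat_id), cat_id), function(ix) {
    data.frame(ga_mid = category_median(records$ga_days[ix]),
               n = length(ix),
               median_conc = category_median(conc[ix]))
  }))
  rownames(tab) <- NULL
  assert_that(nrow(tab) >= 3,
              "need at least 3 non-empty gestational-age categories")
  fit <- stats::lm(log10(median_conc) ~ ga_mid, data = tab, weights = tab$n)
  structure(list(marker = marker,
                 trimester = trimester,
                 width_days = width,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 categories = tab,
                 ga_range = range(records$ga_days)),
            class = "median_regression")
}

#' @export
print.median_regression <- function(x, ...) {
  cat(sprintf("Median regression for %s (%s trimester)\n", x$marker, x$trimester))
  cat(sprintf("  log10(median) = %.5f + %.6f * ga_days\n", x$intercept, x$slope))
  cat(sprintf("  weekly ratio %.3f over %d categories, GA %d-%d days\n",
              10^(7 * x$slope), nrow(x$categories), x$ga_range[1], x$ga_range[2]))
  invisible(x)
}

#' Convert a concentration to a multiple of the median (MoM)
#'
#' Divides a marker concentration by the regressed (expected) concentration
#' for the same gestational age.
#'
#' @param concentration Marker concentration(s); must be positive.
#' @param ga_days Gestational age(s) in days.
#' @param model A [fit_median_regression()] fit.
#' @return MoM value(s), dimensionless and strictly positive. A warning is
#'   issued when `ga_days` falls more than 7 days outside the fitted range.
#' @export
compute_mom <- function(concentration, ga_days, model) {
  stopifnot(inherits(model, "median_regression"))
  assert_that(all(is.finite(concentration) & concentration > 0),
              "concentrations must be positive")
  if (any(ga_days < model$ga_range[1] - 7 | ga_days > model$ga_range[2] + 7)) {
    warning("gestational age more than 7 days outside the fitted range; MoM is an extrapolation")
  }
  concentration / 10^(model$intercept + model$slope * ga_days)
}

#' Fit the maternal-weight adjustment for MoM values
#'
#' Regresses the log10 of the median MoM in maternal-weight categories
#' (default 5 kg bins) on the bin median weight, weighted by bin counts, in
#' unaffected pregnancies. The fitted line predicts the expected MoM at a
#' given weight; dividing by it removes the weight trend.
#'
#' @param moms MoM values of unaffected pregnancies.
#' @param weights_kg Maternal weights (kg), same length.
#' @param bin_width Weight bin width in kg.
#' @return A list of class `weight_adjustment` with `intercept` and `slope`
#'   (log10 MoM per kg) and `per5kg`, the fractional change per 5 kg.
#' @export
fit_weight_adjustment <- function(moms, weights_kg, bin_width = 5) {
  assert_that(length(moms) == length(weights_kg), "lengths differ")
  assert_that(all(moms > 0) && all(weights_kg > 0),
              "MoMs and weights must be positive")
  bin <- floor(weights_kg / bin_width)
  tab <- do.call(rbind, lapply(split(seq_along(bin), bin), function(ix) {
    data.frame(w_mid = category_median(weights_kg[ix]),
               n = length(ix),
               median_mom = category_median(moms[ix]))
  }))
  assert_that(nrow(tab) >= 3, "need at least 3 non-empty weight bins")
  fit <- stats::lm(log10(median_mom) ~ w_mid, data = tab, weights = tab$n)
  slope <- unname(stats::coef(fit)[2])
  structure(list(intercept = unname(stats::coef(fit)[1]),
                 slope = slope,
                 per5kg = 10^(5 * slope) - 1,
                 bins = tab),
            class = "weight_adjustment")
}

#' Covariate adjustment model for MoM values
#'
#' Bundles the maternal-weight regression with the smoking and ethnicity
#' divisors applied after weight adjustment. The study divisors for
#' placental growth factor are 1.32 (smokers) and 1.18 (Afro-Caribbean
#' women) in the first trimester, and 1.36 and 1.30 in the second.
#'
#' @param weight A [fit_weight_adjustment()] fit, or `NULL` for no weight
#'   adjustment.
#' @param smoking_divisor Divisor applied to smokers' MoM values.
#' @param ethnicity_divisors Named numeric vector of divisors; groups
#'   without an entry are not adjusted.
#' @return An object of class `covariate_adjustment`.
#' @export
covariate_adjustment <- function(weight = NULL, smoking_divisor = 1,
                                 ethnicity_divisors = numeric(0)) {
  assert_that(smoking_divisor > 0 && all(ethnicity_divisors > 0),
              "divisors must be positive")
  structure(list(weight = weight,
                 smoking_divisor = smoking_divisor,
                 ethnicity_divisors = ethnicity_divisors),
            class = "covariate_adjustment")
}

#' Adjust MoM values for maternal weight, smoking and ethnicity
#'
#' Divides each MoM by the regressed value for the woman's weight, then by
#' the smoking divisor if she smokes, then by her ethnic group's divisor if
#' one is defined. The factors are multiplicative, so the order is
#' immaterial. Unknown ethnicity labels receive no adjustment and are
#' reported via a message.
#'
#' @param mom MoM value(s).
#' @param weight_kg Maternal weight(s) in kg.
#' @param smoker Logical vector.
#' @param ethnicity Character vector of group labels.
#' @param model A [covariate_adjustment()].
#' @return Adjusted MoM values.
#' @export
adjust_mom <- function(mom, weight_kg, smoker, ethnicity, model) {
  stopifnot(inherits(model, "covariate_adjustment"))
  out <- mom
  if (!is.null(model$weight)) {
    out <- out / 10^(model$weight$intercept + model$weight$slope * weight_kg)
  }
  out <- out / ifelse(smoker, model$smoking_divisor, 1)
  ed <- model$ethnicity_divisors
  if (length(ed)) {
    known_groups <- c("afro_caribbean", "white", "south_asian", "oriental", "other")
    odd <- setdiff(unique(ethnicity), known_groups)
    if (length(odd)) {
      message("unrecognised ethnicity label(s), left unadjusted: ",
              paste(odd, collapse = ", "))
    }
    f <- ifelse(ethnicity %in% names(ed), ed[ethnicity], 1)
    out <- out / unname(f)
  }
  out
}

#' Estimate a group multiplier with a bootstrap confidence interval
#'
#' Ratio of the median MoM in a group (e.g. smokers, an ethnic group) to the
#' median in the reference group, with a percentile bootstrap confidence
#' interval over records.
#'
#' @param moms MoM values.
#' @param group_flag Logical vector: `TRUE` for the group of interest.
#' @param n_boot Bootstrap resamples.
#' @param conf Confidence level.
#' @param seed Seed for the bootstrap.
#' @return A list with `estimate`, `ci` (length 2), `n` per group, and
#'   `reliable` (`FALSE` when either group has fewer than 10 records, in
#'   which case the interval should not be trusted).
#' @export
estimate_group_factor <- function(moms, group_flag, n_boot = 2000,
                                  conf = 0.95, seed = 1L) {
  assert_that(any(group_flag) && any(!group_flag),
              "both groups must be non-empty")
  g <- moms[group_flag]
  r <- moms[!group_flag]
  est <- stats::median(g) / stats::median(r)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    stats::median(sample(g, replace = TRUE)) /
      stats::median(sample(r, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - conf) / 2
  list(estimate = est,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       n = c(group = length(g), reference = length(r)),
       reliable = min(length(g), length(r)) >= 10)
}
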
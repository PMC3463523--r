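#' Maternal age-specific Down syndrome risk model
#'
#' Constructs the parametric maternal-age risk curve used as the screening
#' prior. The livebirth risk at maternal age \eqn{a} (years, at the expected
#' date of delivery) follows the classical three-parameter form
#' \deqn{p(a) = \alpha + e^{\beta + \gamma a},}
#' and the early-second-trimester (mid-trimester) odds are obtained by
#' dividing the livebirth odds by the survival fraction of affected
#' pregnancies from mid-trimester to term (default 0.77, i.e. multiplying
#' the odds by 1/0.77 to allow for fetal loss).
#'
#' The default coefficients are the widely used regression estimates of the
#' age curve (\eqn{\alpha} = 0.000627, \eqn{\beta} = -16.2395,
#' \eqn{\gamma} = 0.286); any published curve of the same form, such as
#' revised national estimates, can be supplied instead.
#'
#' @param alpha,beta,gamma Coefficients of the livebirth risk curve.
#' @param fetal_loss_survival Fraction of affected pregnancies alive at
#'   mid-trimester that survive to term; in (0, 1].
#' @param age_range Ages (years) for which the model is defined.
#' @return An object of class `age_risk_model`.
#' @examples
#' m <- age_risk_model()
#' livebirth_risk(m, c(25, 35, 40))
#' midtrimester_prior_odds(37, m)
#' @export
age_risk_model <- function(alpha = 0.000627, beta = -16.2395, gamma = 0.286,
                           fetal_loss_survival = 0.77,
                           age_range = c(12, 55)) {
  assert_that(fetal_loss_survival > 0 && fetal_loss_survival <= 1,
              "fetal_loss_survival must be in (0, 1]")
  m <- structure(list(alpha = alpha, beta = beta, gamma = gamma,
                      fetal_loss_survival = fetal_loss_survival,
                      age_range = age_range),
                 class = "age_risk_model")
  p <- livebirth_risk(m, seq(age_range[1], age_range[2]))
  assert_that(all(p > 0 & p < 1), "risk curve must stay inside (0, 1) over age_range")
  assert_that(all(diff(livebirth_risk(m, 30:55)) > 0),
              "livebirth risk must be strictly increasing for ages >= 30")
  m
}

#' Livebirth Down syndrome risk at a maternal age
#'
#' @param model An [age_risk_model()].
#' @param age Maternal age in years at the expected date of delivery.
#' @return Probability of an affected livebirth.
#' @export
livebirth_risk <- function(model, age) {
  stopifnot(inherits(model, "age_risk_model"))
  model$alpha + exp(model$beta + model$gamma * age)
}

#' Mid-trimester prior odds of Down syndrome
#'
#' Converts the maternal-age livebirth risk to early-second-trimester odds
#' by dividing the livebirth odds by the fetal-loss survival fraction
#' (equivalently, multiplying by 1/0.77 with the default model).
#'
#' @inheritParams livebirth_risk
#' @return Odds (affected : unaffected, as a single number) at mid-trimester.
#' @export
midtrimester_prior_odds <- function(age, model = age_risk_model()) {
  stopifnot(inherits(model, "age_risk_model"))
  assert_that(all(age >= model$age_range[1] & age <= model$age_range[2]),
              sprintf("age out of supported range [%g, %g]",
                      model$age_range[1], model$age_range[2]))
  p <- livebirth_risk(model, age)
  (p / (1 - p)) / model$fetal_loss_survival
}

#' Maternal age distribution of maternities
#'
#' Loads a single-year histogram of maternal age at delivery. The packaged
#' default (`maternal_age_distribution_synthetic.csv`) is a synthetic
#' single-year approximation to the England and Wales 2006--2008 maternity
#' age profile, built by smooth interpolation of published five-year group
#' shares; any table with columns `age` and `prob` can be supplied instead.
#'
#' @param path Optional path to a CSV with columns `age`, `prob`.
#' @return An object of class `maternal_age_distribution`: a data frame with
#'   columns `age` (integer years) and `prob` (summing to 1).
#' @export
maternal_age_distribution <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "maternal_age_distribution_synthetic.csv",
                        package = "screenmark", mustWork = TRUE)
  }
  d <- utils::read.csv(path)
  assert_that(all(c("age", "prob") %in% names(d)),
              "age distribution file needs columns 'age' and 'prob'")
  assert_that(all(d$prob >= 0), "probabilities must be non-negative")
  assert_that(all(d$age >= 12 & d$age <= 55),
              "age support must lie within [12, 55]")
  d$prob <- d$prob / sum(d$prob)
  structure(d[order(d$age), c("age", "prob")],
            class = c("maternal_age_distribution", "data.frame"))
}

#' Age distribution of affected pregnancies
#'
#' Reweights the maternity age histogram by the age-specific mid-trimester
#' odds, so that simulated affected pregnancies carry the older age profile
#' implied by the age-risk gradient.
#'
#' @param dist A [maternal_age_distribution()].
#' @param model An [age_risk_model()].
#' @return A `maternal_age_distribution` for affected pregnancies.
#' @export
affected_age_distribution <- function(dist, model = age_risk_model()) {
  stopifnot(inherits(dist, "maternal_age_distribution"))
  w <- dist$prob * midtrimester_prior_odds(dist$age, model)
  out <- dist
  out$prob <- w / sum(w)
  out
}

#' Mid-trimester prevalence implied by an age distribution
#'
#' @inheritParams affected_age_distribution
#' @return Probability that a pregnancy drawn from the maternity age
#'   distribution is affected at mid-trimester.
#' @export
implied_prevalence <- function(dist, model = age_risk_model()) {
  stopifnot(inherits(dist, "maternal_age_distribution"))
  odds <- midtrimester_prior_odds(dist$age, model)
  sum(dist$prob * odds / (1 + odds))
}
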
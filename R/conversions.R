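#' Probability and rate conversions
#'
#' Shared arithmetic for placing published survival figures on the model's
#' 6-month cycle grid. All manipulations happen on the hazard (log-survival)
#' scale, never by multiplying probabilities by ratios, so results are always
#' valid probabilities and match the constant-hazard assumption used for
#' breast-cancer recurrence.
#'
#' @name conversions
NULL

#' Per-cycle event probability from a cumulative survival probability
#'
#' Assumes a constant hazard consistent with `surv_prob` survival at
#' `at_years`, and returns the event probability over one cycle.
#'
#' @param surv_prob Probability of remaining event-free at `at_years`,
#'   in (0, 1].
#' @param at_years Time at which `surv_prob` is observed (years, > 0).
#' @param cycle_years Cycle length in years (> 0).
#' @return Per-cycle event probability `1 - surv_prob^(cycle_years/at_years)`.
#' @examples
#' cycle_prob_from_survival(0.912, 10, 0.5) # ~0.0046
#' @export
cycle_prob_from_survival <- function(surv_prob, at_years, cycle_years) {
  stopifnot(at_years > 0, cycle_years > 0)
  if (any(surv_prob <= 0) || any(surv_prob > 1)) {
    stop("surv_prob must be in (0, 1]: infinite hazard at 0")
  }
  1 - surv_prob^(cycle_years / at_years)
}

#' Per-cycle death probability from a median survival
#'
#' Exponential survival with the given median.
#'
#' @param median_months Median survival in months (> 0).
#' @param cycle_years Cycle length in years.
#' @return Per-cycle probability `1 - 0.5^(12 * cycle_years / median_months)`.
#' @export
cycle_prob_from_median <- function(median_months, cycle_years) {
  stopifnot(median_months > 0, cycle_years > 0)
  1 - 0.5^(12 * cycle_years / median_months)
}

#' Rescale a probability by a hazard ratio
#'
#' @param p Baseline probability in [0, 1].
#' @param hr Hazard-scale ratio (> 0).
#' @return `1 - (1 - p)^hr`; `p = 1` maps to 1.
#' @export
rescale_prob_hr <- function(p, hr) {
  stopifnot(all(hr > 0), all(p >= 0), all(p <= 1))
  1 - (1 - p)^hr
}

#' Convert an annual probability to a per-cycle probability
#'
#' @param p_annual Annual probability in [0, 1].
#' @param cycle_years Cycle length in years.
#' @return `1 - (1 - p_annual)^cycle_years`.
#' @export
annual_to_cycle_prob <- function(p_annual, cycle_years) {
  stopifnot(all(p_annual >= 0), all(p_annual <= 1), cycle_years > 0)
  1 - (1 - p_annual)^cycle_years
}

#' Two-tier discount factor
#'
#' Continuous-in-time discounting at `rate_early` up to `switch_year` and
#' `rate_late` thereafter (2.5% then 1.5% after 30 years in the base case).
#'
#' @param t_years Time from model entry (years, vectorised).
#' @param spec Discount specification: list with `rate_early`, `rate_late`,
#'   `switch_year`.
#' @return Discount factor(s) in (0, 1].
#' @export
discount_factor <- function(t_years, spec) {
  stopifnot(all(t_years >= 0))
  early <- (1 + spec$rate_early)^(-pmin(t_years, spec$switch_year))
  late <- (1 + spec$rate_late)^(-pmax(t_years - spec$switch_year, 0))
  early * late
}

# Combine competing per-cycle marginal probabilities into jointly consistent
# allocated probabilities: p_total = 1 - exp(-sum r_i), split proportionally
# to the rates r_i = -log(1 - p_i). Rows of `p` are cycles, columns events.
# Marginals are capped just below 1 so an age-capped death probability of 1
# stays finite on the rate scale.
combine_competing <- function(p) {
  p <- pmin(as.matrix(p), 1 - 1e-12)
  r <- -log1p(-p)
  total <- rowSums(r)
  p_tot <- -expm1(-total)
  share <- r / ifelse(total > 0, total, 1)
  out <- share * p_tot
  out[total == 0, ] <- 0
  out
}
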
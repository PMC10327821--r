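#' Valuation of cohort traces
#'
#' Converts a branch trace into discounted costs by category, life-years and
#' QALYs. Recurring flows are valued against half-cycle-corrected occupancy
#' and discounted at cycle midpoints; one-off flows triggered by incidence
#' (AML and CHF entry, death) are discounted at the midpoint of the cycle in
#' which they occur; entry-time one-offs (test, chemotherapy add-on, sick
#' leave, chemotherapy transportation) are discounted at time zero.
#'
#' @name valuation
NULL

COST_CATEGORIES <- c("test", "adjuvant", "transportation", "sick_leave",
                     "recurrence_free", "distant_recurrence", "aml", "chf",
                     "end_of_life")

# Per-cycle amount for a recurring cost item given its declared period.
per_cycle_amount <- function(costs, item, cycle_years) {
  period <- costs$recurring_cost_period[[item]]
  if (is.null(period)) period <- "cycle"
  if (period == "year") costs[[item]] * cycle_years else costs[[item]]
}

#' Discounted costs by category for one branch
#'
#' Category mapping mirrors the published cost table: `test` (charged at the
#' strategy level, zero here), `adjuvant` (endocrine-therapy drug cost while
#' recurrence-free during the adjuvant period, plus the chemotherapy add-on
#' for ET_CT branches), `transportation` (chemotherapy and endocrine-therapy
#' transport), `sick_leave`, `recurrence_free` (first-year stratum cost in
#' cycles 0-1 replacing the generic recurring cost, then the recurring
#' follow-up cost), `distant_recurrence` (CDK4/6 inhibitor plus disease
#' management), `aml` and `chf` (one-off at entry plus recurring), and
#' `end_of_life` (terminal cost per death).
#'
#' @param trace An `rscea_trace` from [run_branch()].
#' @param branch The branch the trace belongs to.
#' @param config Model configuration.
#' @return Named numeric vector over the nine cost categories (EUR,
#'   discounted, per branch patient).
#' @export
value_costs <- function(trace, branch, config) {
  sp <- config$subpopulations[[branch$stratum_id]]
  co <- config$costs
  cyc <- trace$cycle_length
  eff <- half_cycle_occupancy(trace)
  K <- nrow(eff)
  t_mid <- (seq_len(K) - 0.5) * cyc
  disc_mid <- discount_factor(t_mid, config$discount)
  is_ct <- identical(branch$treatment, "ET_CT")
  out <- stats::setNames(numeric(length(COST_CATEGORIES)), COST_CATEGORIES)

  # recurrence-free: year-1 stratum cost spread over the first year's cycles,
  # generic recurring cost afterwards
  year1_cycles <- max(round(1 / cyc), 1)
  rf_rate <- rep(per_cycle_amount(co, "rf_recurring_cost", cyc), K)
  rf_rate[seq_len(min(year1_cycles, K))] <- sp$rf_year1_cost / year1_cycles
  out["recurrence_free"] <- sum(eff[, "RF"] * rf_rate * disc_mid)

  # adjuvant: ET drug while recurrence-free for the adjuvant duration;
  # chemotherapy costs (treatment + AE management) in cycle 0 for ET_CT
  et_cycles <- min(round(co$et_duration_years / cyc), K)
  adjuvant <- sum(eff[seq_len(et_cycles), "RF"] * (sp$et_annual_cost * cyc) *
                    disc_mid[seq_len(et_cycles)])
  if (is_ct) adjuvant <- adjuvant + sp$ct_addon_cost
  out["adjuvant"] <- adjuvant

  # transportation: chemotherapy transport at entry for ET_CT; endocrine
  # transport as a first-year cost split over the first year's cycle starts
  n1 <- min(year1_cycles, K)
  t_start <- (seq_len(n1) - 1) * cyc
  alive_start <- rowSums(
    trace$occupancy[seq_len(n1), STATES5 != "Death", drop = FALSE])
  transport <- sum(sp$transport_et_cost / year1_cycles * alive_start *
                     discount_factor(t_start, config$discount))
  if (is_ct) transport <- transport + sp$transport_ct_cost
  out["transportation"] <- transport

  if (is_ct) out["sick_leave"] <- sp$sick_leave_cost

  dr_rate <- per_cycle_amount(co, "dr_cdk46_cost", cyc) +
    per_cycle_amount(co, "dr_management_cost", cyc)
  out["distant_recurrence"] <- sum(eff[, "DR"] * dr_rate * disc_mid)

  out["aml"] <- sum(trace$incidence[, "AML"] * co$aml_oneoff * disc_mid) +
    sum(eff[, "AML"] * per_cycle_amount(co, "aml_recurring", cyc) * disc_mid)
  out["chf"] <- sum(trace$incidence[, "CHF"] * co$chf_oneoff * disc_mid) +
    sum(eff[, "CHF"] * per_cycle_amount(co, "chf_recurring", cyc) * disc_mid)

  out["end_of_life"] <- sum(trace$incidence[, "Death"] * co$terminal_cost *
                              disc_mid)
  out
}

#' Discounted life-years and QALYs for one branch
#'
#' Life-years sum half-cycle-corrected alive occupancy over the horizon.
#' QALYs weight each alive state by its utility times the country adjustment
#' (capped at 1) times the age multiplier (re-anchored so it equals 1 at the
#' stratum entry age); the chemotherapy utility decrement is subtracted from
#' recurrence-free occupancy of ET_CT branches for the configured number of
#' cycles (default one cycle, the 6-month chemotherapy course).
#'
#' @inheritParams value_costs
#' @return list with `ly` and `qaly`.
#' @export
value_qalys <- function(trace, branch, config) {
  sp <- config$subpopulations[[branch$stratum_id]]
  ut <- config$utilities
  cyc <- trace$cycle_length
  eff <- half_cycle_occupancy(trace)
  K <- nrow(eff)
  t_mid <- (seq_len(K) - 0.5) * cyc
  disc_mid <- discount_factor(t_mid, config$discount)

  alive <- rowSums(eff[, STATES5 != "Death", drop = FALSE])
  ly <- sum(alive * cyc * disc_mid)

  adj <- if (isTRUE(ut$apply_france_adjustment)) ut$france_adjustment else 1
  u <- pmin(c(RF = ut$u_rf, DR = ut$u_dr, AML = ut$u_aml, CHF = ut$u_chf) *
              adj, 1)
  age_mid <- trace$ages[seq_len(K)] + cyc / 2
  curve <- config$curves$age_utility
  mult <- age_lookup(curve, age_mid, "multiplier") /
    age_lookup(curve, sp$start_age, "multiplier")
  qaly <- sum((eff[, "RF"] * u["RF"] + eff[, "DR"] * u["DR"] +
                 eff[, "AML"] * u["AML"] + eff[, "CHF"] * u["CHF"]) *
                mult * cyc * disc_mid)
  if (identical(branch$treatment, "ET_CT") && ut$ct_decrement > 0) {
    dec_cycles <- seq_len(min(ut$ct_decrement_cycles, K))
    qaly <- qaly - sum(ut$ct_decrement * eff[dec_cycles, "RF"] * cyc *
                         disc_mid[dec_cycles])
  }
  list(ly = ly, qaly = qaly)
}
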
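#' Model configuration
#'
#' A configuration is a plain nested list of class `rscea_config` with
#' sections:
#' \describe{
#'   \item{subpopulations}{named list of strata (`N0_lt50`, `N0_ge50`,
#'     `N1_ge50`), each holding its population weight, starting age,
#'     chemotherapy probabilities under both strategies, recurrence-score
#'     share vector, ten-year recurrence-free survival by (context,
#'     treatment), and stratum-specific first-year costs.}
#'   \item{clinical}{toxicity and mortality parameters.}
#'   \item{utilities}{health-state utilities and adjustments.}
#'   \item{costs}{shared cost parameters with per-item recurrence periods.}
#'   \item{discount}{two-tier annual discount rates and the switch year.}
#'   \item{settings}{willingness-to-pay, cycle length, maximum age.}
#'   \item{curves}{life table, age-utility multiplier, heart-failure
#'     incidence (inline data.frames).}
#' }
#'
#' @name model_config
NULL

new_subpopulation <- function(id, weight, start_age, soc_ct_prob, rs_shares,
                              ct_prob_by_rs, recurrence, rf_year1_cost,
                              ct_addon_cost, sick_leave_cost,
                              transport_ct_cost, transport_et_cost,
                              et_annual_cost) {
  list(id = id, weight = weight, start_age = start_age,
       soc_ct_prob = soc_ct_prob, rs_shares = rs_shares,
       ct_prob_by_rs = ct_prob_by_rs, recurrence = recurrence,
       rf_year1_cost = rf_year1_cost, ct_addon_cost = ct_addon_cost,
       sick_leave_cost = sick_leave_cost,
       transport_ct_cost = transport_ct_cost,
       transport_et_cost = transport_et_cost,
       et_annual_cost = et_annual_cost)
}

#' The embedded base-case configuration
#'
#' Returns the default model configuration: three strata (premenopausal
#' node-negative, postmenopausal node-negative, postmenopausal node-positive)
#' with their published weights, starting ages, chemotherapy-use
#' probabilities, ten-year recurrence-free survival inputs and first-year
#' costs; shared clinical, utility, cost and discounting parameters; and
#' synthetic default curves for the external inputs (life table, age-utility
#' multiplier, heart-failure incidence).
#'
#' Note the premenopausal recurrence-score shares are stored as printed
#' (33.7% / 73.9% / 27.1%, which cannot sum to one); [effective_rs_shares()]
#' resolves the middle category as the complement of the outer two.
#'
#' @return An object of class `rscea_config`.
#' @examples
#' cfg <- base_case_config()
#' cfg$clinical$chf_rr_ct
#' @export
base_case_config <- function() {
  subpops <- list(
    N0_lt50 = new_subpopulation(
      id = "N0_lt50", weight = 0.412, start_age = 43, soc_ct_prob = 0.608,
      rs_shares = list(lt16 = 0.337, mid = 0.739, gt25 = 0.271),
      ct_prob_by_rs = list(lt16 = 0, mid = 0.311, gt25 = 1),
      recurrence = list(
        rs_lt16 = list(ET = 0.970, ET_CT = 0.978),
        rs_mid = list(ET = 0.827, ET_CT = 0.917),
        rs_gt25 = list(ET = 0.711, ET_CT = 0.833),
        soc = list(ET = 0.844, ET_CT = 0.915)),
      rf_year1_cost = 3777, ct_addon_cost = 2063, sick_leave_cost = 6316,
      transport_ct_cost = 2906, transport_et_cost = 255,
      et_annual_cost = 91),
    N0_ge50 = new_subpopulation(
      id = "N0_ge50", weight = 0.167, start_age = 64, soc_ct_prob = 0.294,
      rs_shares = list(lt16 = 0, mid = 0.718, gt25 = 0.282),
      ct_prob_by_rs = list(lt16 = 0, mid = 0, gt25 = 1),
      recurrence = list(
        rs_mid = list(ET = 0.904, ET_CT = 0.908),
        rs_gt25 = list(ET = 0.702, ET_CT = 0.783),
        soc = list(ET = 0.847, ET_CT = 0.873)),
      rf_year1_cost = 2973, ct_addon_cost = 4479, sick_leave_cost = 5235,
      transport_ct_cost = 1738, transport_et_cost = 925,
      et_annual_cost = 223),
    N1_ge50 = new_subpopulation(
      id = "N1_ge50", weight = 0.421, start_age = 61, soc_ct_prob = 0.776,
      rs_shares = list(lt16 = 0, mid = 0.829, gt25 = 0.171),
      ct_prob_by_rs = list(lt16 = 0, mid = 0, gt25 = 1),
      recurrence = list(
        rs_mid = list(ET = 0.912, ET_CT = 0.906),
        rs_gt25 = list(ET = 0.620, ET_CT = 0.754),
        soc = list(ET = 0.862, ET_CT = 0.880)),
      rf_year1_cost = 3444, ct_addon_cost = 3619, sick_leave_cost = 10609,
      transport_ct_cost = 1200, transport_et_cost = 337,
      et_annual_cost = 223))

  config <- list(
    subpopulations = subpops,
    clinical = list(
      aml_cycle_prob = 0.0062,
      chf_rr_ct = 1.61,
      dr_median_os_months = 63.9,
      aml_5yr_death_prob = 0.76,
      chf_excess_hr_year1 = 5.0,
      chf_excess_hr_later = 2.0,
      aml_risk_window_years = 5,  # NULL = unbounded
      dr_toxicity = TRUE),
    utilities = list(
      u_rf = 0.860, u_dr = 0.715, u_aml = 0.271, u_chf = 0.551,
      france_adjustment = 1.043, apply_france_adjustment = TRUE,
      ct_decrement = 0.040, ct_decrement_cycles = 1),
    costs = list(
      test_cost = 1850,
      rf_recurring_cost = 604,
      dr_cdk46_cost = 14395,
      dr_management_cost = 6516,
      aml_oneoff = 23970, aml_recurring = 5806,
      chf_oneoff = 1888, chf_recurring = 1148,
      terminal_cost = 4606,
      et_duration_years = 5,
      recurring_cost_period = list(
        rf_recurring_cost = "cycle",
        dr_cdk46_cost = "year",
        dr_management_cost = "cycle",
        aml_recurring = "cycle",
        chf_recurring = "cycle")),
    discount = list(rate_early = 0.025, rate_late = 0.015, switch_year = 30),
    settings = list(wtp = 20000, cycle_length_years = 0.5, max_age = 100),
    curves = list(
      life_table = make_life_table(),
      age_utility = make_age_utility_multiplier(anchor_age = 43),
      chf_incidence = make_chf_incidence()))
  structure(config, class = "rscea_config")
}

#' Load and validate a model configuration
#'
#' Accepts either a path to a JSON document or an already-parsed nested list.
#' Required sections are `subpopulations`, `clinical`, `utilities`, `costs`,
#' `discount` and `settings`; curves may be given inline, as CSV paths, or
#' omitted entirely, in which case synthetic defaults are substituted and a
#' message is emitted. The returned configuration has passed all invariant
#' checks.
#'
#' @param source Path to a JSON config file, or a nested list.
#' @return A validated `rscea_config`.
#' @export
load_config <- function(source) {
  if (is.character(source) && length(source) == 1) {
    if (!file.exists(source)) stop("config file not found: ", source)
    source <- jsonlite::read_json(source, simplifyVector = TRUE,
                                  simplifyDataFrame = TRUE)
  }
  if (!is.list(source)) stop("config source must be a file path or a list")
  required <- c("subpopulations", "clinical", "utilities", "costs",
                "discount", "settings")
  missing <- setdiff(required, names(source))
  if (length(missing) > 0) {
    stop("configuration error: missing section(s): ",
         paste(missing, collapse = ", "))
  }
  config <- source
  if (is.null(config$curves)) config$curves <- list()
  config$curves <- resolve_curves(config$curves, config)
  # lists parsed from JSON may carry per-stratum data.frames; normalise
  config$subpopulations <- lapply(config$subpopulations, as.list)
  if (is.null(names(config$subpopulations)) ||
      any(names(config$subpopulations) == "")) {
    names(config$subpopulations) <-
      vapply(config$subpopulations, function(sp) sp$id, character(1))
  }
  class(config) <- "rscea_config"
  validate_config(config)
}

resolve_curves <- function(curves, config) {
  resolve_one <- function(curve, maker, label, cols) {
    if (is.null(curve)) {
      message("note: no ", label, " supplied; using synthetic default")
      return(maker())
    }
    if (is.character(curve)) curve <- utils::read.csv(curve)
    curve <- as.data.frame(curve)
    if (!all(cols %in% names(curve))) {
      stop("validation error: ", label, " must have columns ",
           paste(cols, collapse = ", "))
    }
    curve
  }
  anchor <- min(vapply(config$subpopulations,
                       function(sp) as.numeric(sp$start_age), numeric(1)))
  list(
    life_table = resolve_one(curves$life_table, make_life_table,
                             "life_table", c("age", "annual_death_prob")),
    age_utility = resolve_one(curves$age_utility,
                              function() make_age_utility_multiplier(anchor),
                              "age_utility_curve", c("age", "multiplier")),
    chf_incidence = resolve_one(curves$chf_incidence, make_chf_incidence,
                                "chf_incidence_curve", c("age", "annual_prob")))
}

check <- function(ok, field, constraint) {
  if (!isTRUE(all(ok))) {
    stop("validation error: ", field, " ", constraint, call. = FALSE)
  }
}

#' Validate a model configuration
#'
#' Checks every structural invariant: stratum weights sum to 1, shares and
#' probabilities lie in their domains, costs are non-negative, discount rates
#' valid, the horizon is an integer number of cycles per stratum, and the
#' external curves satisfy their type invariants.
#'
#' @param config An `rscea_config`.
#' @return The config, invisibly, if valid; otherwise an error naming the
#'   offending field and constraint.
#' @export
validate_config <- function(config) {
  sp <- config$subpopulations
  w <- vapply(sp, function(s) as.numeric(s$weight), numeric(1))
  check(abs(sum(w) - 1) < 1e-6, "subpopulations$weight", "must sum to 1")
  for (s in sp) {
    id <- s$id
    check(s$weight >= 0 && s$weight <= 1, paste0(id, "$weight"),
          "must be in [0,1]")
    check(s$start_age > 0 && s$start_age < config$settings$max_age,
          paste0(id, "$start_age"), "must lie below max_age")
    check(s$soc_ct_prob >= 0 && s$soc_ct_prob <= 1,
          paste0(id, "$soc_ct_prob"), "must be in [0,1]")
    sh <- effective_rs_shares(s)
    check(all(unlist(sh) >= 0) && all(unlist(sh) <= 1) &&
            abs(sum(unlist(sh)) - 1) < 1e-9,
          paste0(id, "$rs_shares"), "must normalize to a unit simplex")
    check(all(unlist(s$ct_prob_by_rs) >= 0) &&
            all(unlist(s$ct_prob_by_rs) <= 1),
          paste0(id, "$ct_prob_by_rs"), "must be in [0,1]")
    rec <- unlist(s$recurrence)
    check(all(rec > 0) && all(rec <= 1), paste0(id, "$recurrence"),
          "ten-year recurrence-free probabilities must be in (0,1]")
    for (f in c("rf_year1_cost", "ct_addon_cost", "sick_leave_cost",
                "transport_ct_cost", "transport_et_cost", "et_annual_cost")) {
      check(s[[f]] >= 0, paste0(id, "$", f), "must be >= 0")
    }
    horizon <- config$settings$max_age - s$start_age
    n_cycles <- horizon / config$settings$cycle_length_years
    check(abs(n_cycles - round(n_cycles)) < 1e-9,
          paste0(id, " horizon"), "must be an integer number of cycles")
  }
  cl <- config$clinical
  check(cl$aml_cycle_prob >= 0 && cl$aml_cycle_prob <= 1,
        "clinical$aml_cycle_prob", "must be in [0,1]")
  check(cl$aml_5yr_death_prob >= 0 && cl$aml_5yr_death_prob <= 1,
        "clinical$aml_5yr_death_prob", "must be in [0,1]")
  check(cl$chf_rr_ct > 0, "clinical$chf_rr_ct", "must be > 0")
  check(cl$chf_excess_hr_year1 > 0 && cl$chf_excess_hr_later > 0,
        "clinical$chf_excess_hr", "must be > 0")
  check(cl$dr_median_os_months > 0, "clinical$dr_median_os_months",
        "must be > 0")
  ut <- config$utilities
  check(all(unlist(ut[c("u_rf", "u_dr", "u_aml", "u_chf")]) >= 0) &&
          all(unlist(ut[c("u_rf", "u_dr", "u_aml", "u_chf")]) <= 1),
        "utilities", "state utilities must be in [0,1]")
  check(ut$ct_decrement >= 0, "utilities$ct_decrement", "must be >= 0")
  check(ut$france_adjustment > 0, "utilities$france_adjustment",
        "must be > 0")
  co <- config$costs
  for (f in c("test_cost", "rf_recurring_cost", "dr_cdk46_cost",
              "dr_management_cost", "aml_oneoff", "aml_recurring",
              "chf_oneoff", "chf_recurring", "terminal_cost")) {
    check(co[[f]] >= 0, paste0("costs$", f), "must be >= 0")
  }
  for (f in names(co$recurring_cost_period)) {
    check(co$recurring_cost_period[[f]] %in% c("cycle", "year"),
          paste0("costs$recurring_cost_period$", f),
          "must be 'cycle' or 'year'")
  }
  di <- config$discount
  check(di$rate_early >= 0 && di$rate_early < 1 &&
          di$rate_late >= 0 && di$rate_late < 1,
        "discount rates", "must be in [0,1)")
  check(di$switch_year > 0, "discount$switch_year", "must be > 0")
  check(config$settings$wtp >= 0, "settings$wtp", "must be >= 0")
  check(config$settings$cycle_length_years > 0,
        "settings$cycle_length_years", "must be > 0")
  lt <- config$curves$life_table
  check(all(lt$annual_death_prob > 0) && all(lt$annual_death_prob <= 1),
        "life_table$annual_death_prob", "must be in (0,1]")
  check(lt$annual_death_prob[nrow(lt)] == 1, "life_table",
        "must close with probability 1 at the final age")
  q40 <- lt$annual_death_prob[lt$age >= 40]
  check(all(diff(q40) >= 0), "life_table",
        "must be non-decreasing for ages >= 40")
  check(all(config$curves$age_utility$multiplier > 0),
        "age_utility_curve$multiplier", "must be > 0")
  check(all(config$curves$chf_incidence$annual_prob >= 0) &&
          all(config$curves$chf_incidence$annual_prob <= 1),
        "chf_incidence_curve$annual_prob", "must be in [0,1]")
  invisible(config)
}

#' Serialize a configuration to JSON
#'
#' Round-trips through [load_config()]: `load_config(write_config(cfg, f))`
#' reproduces `cfg`.
#'
#' @param config An `rscea_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.rscea_config <- function(x, ...) {
  cat("rscea model configuration\n")
  cat("  strata:",
      paste(sprintf("%s (w=%.3f, age %d)",
                    names(x$subpopulations),
                    vapply(x$subpopulations, function(s) s$weight, 0),
                    vapply(x$subpopulations,
                           function(s) as.integer(s$start_age), 0L)),
            collapse = ", "), "\n")
  cat(sprintf("  cycle %.2g y, horizon to age %d, WTP %s/QALY\n",
              x$settings$cycle_length_years, x$settings$max_age,
              format(x$settings$wtp, big.mark = ",")))
  invisible(x)
}
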
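#' Strategy outcomes and incremental comparison
#'
#' Branch results are weight-averaged to stratum level (adding the test cost
#' once per tested patient at the strategy level), stratum results are
#' weight-averaged to the population, and strategies are compared on
#' incremental cost, QALYs, life-years, dominance status, ICER and net
#' monetary benefit.
#'
#' @name outcomes
NULL

new_strategy_outcome <- function(costs, ly, qaly, ct_proportion,
                                 aml_proportion, chf_proportion) {
  structure(list(costs_by_category = costs, total_cost = sum(costs),
                 ly = ly, qaly = qaly, ct_proportion = ct_proportion,
                 aml_proportion = aml_proportion,
                 chf_proportion = chf_proportion),
            class = "rscea_outcome")
}

# Full valuation of one branch.
branch_outcome <- function(branch, config) {
  trace <- run_branch(branch, config)
  costs <- value_costs(trace, branch, config)
  lq <- value_qalys(trace, branch, config)
  new_strategy_outcome(
    costs, lq$ly, lq$qaly,
    ct_proportion = as.numeric(identical(branch$treatment, "ET_CT")),
    aml_proportion = sum(trace$incidence[, "AML"]),
    chf_proportion = sum(trace$incidence[, "CHF"]))
}

#' Weight-average strategy outcomes
#'
#' All fields, including the per-category cost vector, are averaged with the
#' supplied weights (branch weights within a stratum, stratum weights across
#' the population).
#'
#' @param outcomes list of `rscea_outcome` objects.
#' @param weights Numeric weights summing to 1.
#' @return An `rscea_outcome`.
#' @export
aggregate_outcomes <- function(outcomes, weights) {
  if (length(outcomes) != length(weights)) {
    stop("validation error: outcomes and weights differ in length")
  }
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("validation error: weights must sum to 1")
  }
  wavg <- function(get) {
    Reduce(`+`, Map(function(o, w) get(o) * w, outcomes, weights))
  }
  new_strategy_outcome(
    costs = wavg(function(o) o$costs_by_category),
    ly = wavg(function(o) o$ly), qaly = wavg(function(o) o$qaly),
    ct_proportion = wavg(function(o) o$ct_proportion),
    aml_proportion = wavg(function(o) o$aml_proportion),
    chf_proportion = wavg(function(o) o$chf_proportion))
}

# One (stratum, strategy) cell: run all branches, weight-average, and charge
# the test once per tested patient at entry (undiscounted cycle-0 one-off).
run_stratum_strategy <- function(spec, strategy, config) {
  branches <- branch_weights(spec, strategy)
  outs <- lapply(seq_len(nrow(branches)), function(i) {
    branch_outcome(as.list(branches[i, ]), config)
  })
  out <- aggregate_outcomes(outs, branches$weight)
  if (strategy == "ODX") {
    out$costs_by_category["test"] <- config$costs$test_cost
    out$total_cost <- sum(out$costs_by_category)
  }
  out$ct_proportion <- ct_probability(spec, strategy)
  out
}

#' Compare two strategy outcomes
#'
#' Classifies the comparison as `dominant` (cheaper and more effective),
#' `dominated` (costlier and less effective) or `icer`; the ICER is reported
#' only in the latter case, matching the convention that no ratio is shown
#' for (un)dominated comparisons. Net monetary benefit
#' `wtp * delta_qaly - delta_cost` is always defined. Avoided-event
#' fractions are relative reductions versus the comparator.
#'
#' @param odx Outcome for the test-guided strategy.
#' @param soc Outcome for the comparator.
#' @param wtp Willingness-to-pay per QALY.
#' @return An `rscea_comparison`: list with `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `status`, `icer_value` (NA unless status is `icer`), `nmb`,
#'   `ct_avoided`, `aml_avoided`, `chf_avoided`.
#' @export
compare_strategies <- function(odx, soc, wtp) {
  dc <- odx$total_cost - soc$total_cost
  dq <- odx$qaly - soc$qaly
  dl <- odx$ly - soc$ly
  if (dc < 0 && dq > 0) {
    status <- "dominant"; icer <- NA_real_
  } else if (dc > 0 && dq < 0) {
    status <- "dominated"; icer <- NA_real_
  } else {
    status <- "icer"
    icer <- if (dq == 0) sign(dc) * Inf else dc / dq
  }
  structure(list(
    delta_cost = dc, delta_qaly = dq, delta_ly = dl, status = status,
    icer_value = icer, nmb = wtp * dq - dc,
    ct_avoided = avoided_fraction(soc$ct_proportion, odx$ct_proportion),
    aml_avoided = avoided_fraction(soc$aml_proportion, odx$aml_proportion),
    chf_avoided = avoided_fraction(soc$chf_proportion, odx$chf_proportion)),
    class = "rscea_comparison")
}

#' Relative reduction of an event rate
#'
#' @param soc_rate Comparator rate in [0, 1].
#' @param odx_rate Intervention rate in [0, 1].
#' @return `1 - odx_rate / soc_rate`, or 0 when `soc_rate` is 0.
#' @export
avoided_fraction <- function(soc_rate, odx_rate) {
  stopifnot(soc_rate >= 0, soc_rate <= 1, odx_rate >= 0, odx_rate <= 1)
  if (soc_rate == 0) 0 else 1 - odx_rate / soc_rate
}

#' Run the full deterministic pipeline
#'
#' Decision tree, cohort engine and valuation for every stratum under both
#' strategies, aggregated to the population, with incremental comparisons
#' per stratum and overall.
#'
#' @param config Model configuration; defaults to [base_case_config()].
#' @return An `rscea_result`: list with `strata` (per-stratum list of `ODX`
#'   and `SOC` outcomes plus `comparison`), `population` (the same at
#'   population level) and `config`.
#' @export
run_model <- function(config = base_case_config()) {
  sp <- config$subpopulations
  wtp <- config$settings$wtp
  strata <- lapply(sp, function(s) {
    odx <- run_stratum_strategy(s, "ODX", config)
    soc <- run_stratum_strategy(s, "SOC", config)
    list(ODX = odx, SOC = soc,
         comparison = compare_strategies(odx, soc, wtp))
  })
  weights <- vapply(sp, function(s) as.numeric(s$weight), numeric(1))
  pop_odx <- aggregate_outcomes(lapply(strata, `[[`, "ODX"), weights)
  pop_soc <- aggregate_outcomes(lapply(strata, `[[`, "SOC"), weights)
  structure(list(
    strata = strata,
    population = list(ODX = pop_odx, SOC = pop_soc,
                      comparison = compare_strategies(pop_odx, pop_soc, wtp)),
    config = config), class = "rscea_result")
}

#' @export
print.rscea_comparison <- function(x, ...) {
  lab <- switch(x$status,
                dominant = "dominant",
                dominated = "dominated",
                sprintf("ICER %.0f EUR/QALY", x$icer_value))
  cat(sprintf(
    "  dCost %9.0f EUR  dQALY %6.3f  dLY %6.3f  %s  NMB %0.0f EUR\n",
    x$delta_cost, x$delta_qaly, x$delta_ly, lab, x$nmb))
  cat(sprintf("  avoided: CT %.1f%%  AML %.1f%%  CHF %.1f%%\n",
              100 * x$ct_avoided, 100 * x$aml_avoided, 100 * x$chf_avoided))
  invisible(x)
}

#' @export
print.rscea_result <- function(x, ...) {
  cat("Cost-effectiveness results (test-guided vs standard of care)\n\n")
  cat("Discounted costs per patient by category (EUR):\n")
  tab <- cbind(ODX = x$population$ODX$costs_by_category,
               SOC = x$population$SOC$costs_by_category)
  tab <- rbind(tab, Total = colSums(tab))
  tab <- cbind(tab, Incremental = tab[, "ODX"] - tab[, "SOC"])
  print(round(tab, 0))
  cat(sprintf("\nQALYs: %.2f vs %.2f   LYs: %.2f vs %.2f\n",
              x$population$ODX$qaly, x$population$SOC$qaly,
              x$population$ODX$ly, x$population$SOC$ly))
  cat("\nOverall population:\n")
  print(x$population$comparison)
  for (id in names(x$strata)) {
    cat("\n", id, ":\n", sep = "")
    print(x$strata[[id]]$comparison)
  }
  invisible(x)
}

# Flatten a result into summary lists for JSON/CSV reporting.
summarize_result <- function(result) {
  comp_row <- function(cmp) {
    list(delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly,
         delta_ly = cmp$delta_ly, status = cmp$status,
         icer = if (is.na(cmp$icer_value)) NULL else cmp$icer_value,
         nmb = cmp$nmb, ct_avoided = cmp$ct_avoided,
         aml_avoided = cmp$aml_avoided, chf_avoided = cmp$chf_avoided)
  }
  out_row <- function(o) {
    list(costs = as.list(o$costs_by_category), total_cost = o$total_cost,
         ly = o$ly, qaly = o$qaly, ct_proportion = o$ct_proportion,
         aml_proportion = o$aml_proportion,
         chf_proportion = o$chf_proportion)
  }
  list(
    population = list(ODX = out_row(result$population$ODX),
                      SOC = out_row(result$population$SOC),
                      comparison = comp_row(result$population$comparison)),
    strata = lapply(result$strata, function(s) {
      list(ODX = out_row(s$ODX), SOC = out_row(s$SOC),
           comparison = comp_row(s$comparison))
    }))
}
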
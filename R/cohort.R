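#' Markov cohort engine
#'
#' Five health states — recurrence-free (RF), distant recurrence (DR), acute
#' myeloid leukemia (AML), chronic heart failure (CHF) and Death — advanced
#' on a 6-month cycle. Time in CHF is tracked internally with two tunnel
#' substates so the higher first-year excess mortality applies by tenure, and
#' reported collapsed to a single CHF column. Competing events leaving a
#' state within a cycle are combined on the rate scale
#' (`p_total = 1 - exp(-sum r_i)`, allocated proportionally to the rates), so
#' every transition row is a valid probability vector for any hazard
#' magnitudes.
#'
#' @name cohort_engine
NULL

# Internal state order used by the engine: CHF split by tenure.
STATES7 <- c("RF", "DR", "AML", "CHF0", "CHF1", "CHFL", "Death")
STATES5 <- c("RF", "DR", "AML", "CHF", "Death")

# Per-cycle allocated transition probabilities for one branch:
#  rf   K x 4 (to DR, AML, CHF, Death)
#  dr   K x 3 (to AML, CHF, Death)
#  aml_death, chf_death_first, chf_death_later  length-K vectors
branch_hazards <- function(branch, config) {
  sp <- config$subpopulations[[branch$stratum_id]]
  set <- config$settings
  cl <- config$clinical
  cyc <- set$cycle_length_years
  K <- round((set$max_age - sp$start_age) / cyc)
  k <- 0:(K - 1)
  age_start <- sp$start_age + k * cyc
  is_ct <- identical(branch$treatment, "ET_CT")

  q_bg <- age_lookup(config$curves$life_table, age_start, "annual_death_prob")
  p_bg <- annual_to_cycle_prob(q_bg, cyc)

  p_chf <- annual_to_cycle_prob(
    age_lookup(config$curves$chf_incidence, age_start, "annual_prob"), cyc)
  if (is_ct) p_chf <- rescale_prob_hr(p_chf, cl$chf_rr_ct)

  window <- cl$aml_risk_window_years
  in_window <- if (is.null(window)) rep(TRUE, K) else (k * cyc) < window
  p_aml <- if (is_ct) ifelse(in_window, cl$aml_cycle_prob, 0) else rep(0, K)

  surv10 <- as.numeric(sp$recurrence[[branch$rs_context]][[branch$treatment]])
  p_dr <- rep(cycle_prob_from_survival(surv10, 10, cyc), K)

  rf <- combine_competing(cbind(DR = p_dr, AML = p_aml, CHF = p_chf,
                                Death = p_bg))
  # disease-state death takes the max of the disease-specific and the
  # age-matched background probability (sources already include all-cause)
  p_dr_death <- pmax(p_bg, cycle_prob_from_median(cl$dr_median_os_months, cyc))
  dr_tox <- isTRUE(cl$dr_toxicity) && is_ct
  zero <- rep(0, K)
  dr <- combine_competing(cbind(AML = if (dr_tox) p_aml else zero,
                                CHF = if (dr_tox) p_chf else zero,
                                Death = p_dr_death))
  p_aml_death <- pmax(
    p_bg, cycle_prob_from_survival(1 - cl$aml_5yr_death_prob, 5, cyc))

  list(K = K, cycle_length = cyc,
       ages = sp$start_age + (0:K) * cyc,
       rf = rf, dr = dr, aml_death = p_aml_death,
       chf_death_first = rescale_prob_hr(p_bg, cl$chf_excess_hr_year1),
       chf_death_later = rescale_prob_hr(p_bg, cl$chf_excess_hr_later))
}

#' Per-cycle transition matrix for a branch
#'
#' Assembles the collapsed 5x5 matrix (state order RF, DR, AML, CHF, Death)
#' for one cycle. Because CHF mortality depends on tenure in the state, the
#' CHF row is reported for the requested tenure tier.
#'
#' @param branch One branch (a row of [branch_weights()], as list or
#'   one-row data.frame).
#' @param cycle_index Zero-based cycle index within the horizon.
#' @param config Model configuration.
#' @param chf_tenure `"first_year"` or `"later"`: which excess-mortality tier
#'   the CHF row uses.
#' @return 5x5 matrix; rows sum to 1.
#' @export
build_transition_matrix <- function(branch, cycle_index, config,
                                    chf_tenure = c("later", "first_year")) {
  chf_tenure <- match.arg(chf_tenure)
  hz <- branch_hazards(branch, config)
  if (cycle_index < 0 || cycle_index >= hz$K) {
    stop("cycle_index must lie within the horizon [0, ", hz$K - 1, "]")
  }
  i <- cycle_index + 1
  m <- matrix(0, 5, 5, dimnames = list(STATES5, STATES5))
  m["RF", c("DR", "AML", "CHF", "Death")] <- hz$rf[i, ]
  m["RF", "RF"] <- 1 - sum(hz$rf[i, ])
  m["DR", c("AML", "CHF", "Death")] <- hz$dr[i, ]
  m["DR", "DR"] <- 1 - sum(hz$dr[i, ])
  m["AML", "Death"] <- hz$aml_death[i]
  m["AML", "AML"] <- 1 - hz$aml_death[i]
  p_chf_d <- if (chf_tenure == "first_year") hz$chf_death_first[i] else
    hz$chf_death_later[i]
  m["CHF", "Death"] <- p_chf_d
  m["CHF", "CHF"] <- 1 - p_chf_d
  m["Death", "Death"] <- 1
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12)) {
    stop("internal consistency error: invalid transition row")
  }
  m
}

#' Run the cohort recursion for one branch
#'
#' Propagates a unit cohort from model entry to the horizon and records, per
#' cycle, the state occupancy and the incidence inflows into DR, AML, CHF
#' and Death.
#'
#' @inheritParams build_transition_matrix
#' @return An `rscea_trace`: list with `occupancy` ((K+1) x 5 matrix, row 0 =
#'   all recurrence-free), `incidence` (K x 4 matrix), `ages` (age at each
#'   cycle start) and `cycle_length`.
#' @export
run_branch <- function(branch, config) {
  hz <- branch_hazards(branch, config)
  K <- hz$K
  occ7 <- matrix(0, K + 1, 7, dimnames = list(NULL, STATES7))
  occ7[1, "RF"] <- 1
  inc <- matrix(0, K, 4, dimnames = list(NULL, c("DR", "AML", "CHF", "Death")))
  x <- occ7[1, ]
  for (i in seq_len(K)) {
    rf_out <- hz$rf[i, ]  # DR, AML, CHF, Death
    dr_out <- hz$dr[i, ]  # AML, CHF, Death
    new_dr <- x[1] * rf_out[1]
    new_aml <- x[1] * rf_out[2] + x[2] * dr_out[1]
    new_chf <- x[1] * rf_out[3] + x[2] * dr_out[2]
    d_rf <- x[1] * rf_out[4]
    d_dr <- x[2] * dr_out[3]
    d_aml <- x[3] * hz$aml_death[i]
    d_c0 <- x[4] * hz$chf_death_first[i]
    d_c1 <- x[5] * hz$chf_death_first[i]
    d_cl <- x[6] * hz$chf_death_later[i]
    deaths <- d_rf + d_dr + d_aml + d_c0 + d_c1 + d_cl
    x <- c(x[1] - new_dr - x[1] * rf_out[2] - x[1] * rf_out[3] - d_rf,
           x[2] + new_dr - x[2] * dr_out[1] - x[2] * dr_out[2] - d_dr,
           x[3] + new_aml - d_aml,
           new_chf,
           x[4] - d_c0,
           x[6] + x[5] - d_c1 - d_cl,
           x[7] + deaths)
    occ7[i + 1, ] <- x
    inc[i, ] <- c(new_dr, new_aml, new_chf, deaths)
  }
  occupancy <- cbind(RF = occ7[, "RF"], DR = occ7[, "DR"],
                     AML = occ7[, "AML"],
                     CHF = occ7[, "CHF0"] + occ7[, "CHF1"] + occ7[, "CHFL"],
                     Death = occ7[, "Death"])
  structure(list(occupancy = occupancy, incidence = inc, ages = hz$ages,
                 cycle_length = hz$cycle_length, branch = branch),
            class = "rscea_trace")
}

#' Half-cycle-corrected occupancy
#'
#' Effective per-cycle occupancy as the mean of start-of-cycle and
#' end-of-cycle rows (life-table method); all recurring cost and QALY flows
#' are valued against this matrix.
#'
#' @param trace An `rscea_trace`.
#' @return K x 5 matrix of effective occupancy per cycle.
#' @export
half_cycle_occupancy <- function(trace) {
  occ <- trace$occupancy
  K <- nrow(occ) - 1
  (occ[seq_len(K), , drop = FALSE] + occ[seq_len(K) + 1, , drop = FALSE]) / 2
}

#' Write a branch trace to CSV
#'
#' One row per cycle: cycle index, age at cycle start, the five occupancy
#' columns (start of cycle) and the four incidence inflows during the cycle.
#'
#' @param trace An `rscea_trace`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  K <- nrow(trace$incidence)
  df <- data.frame(cycle = 0:K, age = trace$ages, trace$occupancy,
                   rbind(trace$incidence, NA))
  names(df) <- c("cycle", "age", paste0("occ_", STATES5),
                 paste0("new_", c("DR", "AML", "CHF", "Death")))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
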
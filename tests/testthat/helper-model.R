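# Shared fixtures: degenerate configurations and an independent
# microsimulation oracle for the cohort recursion.

# Curves with no background mortality (except the closing age), no
# heart-failure incidence and a flat utility multiplier.
null_curves <- function(max_age = 120) {
  list(
    life_table = data.frame(age = 0:max_age,
                            annual_death_prob = c(rep(0, max_age), 1)),
    age_utility = data.frame(age = 0:max_age, multiplier = 1),
    chf_incidence = data.frame(age = 0:max_age, annual_prob = 0))
}

# Single-stratum configuration with all hazards switched off by default:
# useful for exact-arithmetic checks. Not validated (the null life table
# deliberately violates the q > 0 invariant).
tiny_config <- function(horizon_years = 5, start_age = 60, surv10 = 1,
                        discount = 0) {
  cfg <- base_case_config()
  sp <- cfg$subpopulations$N0_ge50
  sp$weight <- 1
  sp$start_age <- start_age
  for (ctx in names(sp$recurrence)) {
    sp$recurrence[[ctx]] <- list(ET = surv10, ET_CT = surv10)
  }
  cfg$subpopulations <- list(N0_ge50 = sp)
  cfg$clinical$aml_cycle_prob <- 0
  cfg$settings$max_age <- start_age + horizon_years
  cfg$discount$rate_early <- cfg$discount$rate_late <- discount
  cfg$curves <- null_curves()
  cfg
}

# A configuration in which quality weights are all 1, so QALYs must equal
# life-years end to end.
unit_utility_config <- function() {
  cfg <- base_case_config()
  cfg$utilities$u_rf <- cfg$utilities$u_dr <- 1
  cfg$utilities$u_aml <- cfg$utilities$u_chf <- 1
  cfg$utilities$france_adjustment <- 1
  cfg$utilities$ct_decrement <- 0
  cfg$curves$age_utility <- data.frame(age = 0:120, multiplier = 1)
  cfg
}

soc_et_branch <- function(stratum_id = "N1_ge50") {
  list(stratum_id = stratum_id, strategy = "SOC", rs_context = "soc",
       treatment = "ET", weight = 1)
}

# Independent oracle: individual-level microsimulation using the same
# per-cycle probabilities as the cohort engine, but advanced by multinomial
# sampling of walker counts rather than the deterministic recursion.
microsim_branch <- function(branch, config, n_walkers, seed) {
  hz <- rscea:::branch_hazards(branch, config)
  set.seed(seed)
  counts <- c(n_walkers, rep(0, 6))  # RF DR AML CHF0 CHF1 CHFL Death
  occ <- matrix(0, hz$K + 1, 7)
  occ[1, ] <- counts
  for (i in seq_len(hz$K)) {
    newc <- numeric(7)
    newc[7] <- counts[7]  # death is absorbing
    if (counts[1] > 0) {
      p <- hz$rf[i, ]
      m <- stats::rmultinom(1, counts[1], c(1 - sum(p), p))
      newc[1] <- m[1]
      newc[2] <- newc[2] + m[2]; newc[3] <- newc[3] + m[3]
      newc[4] <- newc[4] + m[4]; newc[7] <- newc[7] + m[5]
    }
    if (counts[2] > 0) {
      p <- hz$dr[i, ]
      m <- stats::rmultinom(1, counts[2], c(1 - sum(p), p))
      newc[2] <- newc[2] + m[1]; newc[3] <- newc[3] + m[2]
      newc[4] <- newc[4] + m[3]; newc[7] <- newc[7] + m[4]
    }
    if (counts[3] > 0) {
      d <- stats::rbinom(1, counts[3], hz$aml_death[i])
      newc[3] <- newc[3] + counts[3] - d; newc[7] <- newc[7] + d
    }
    if (counts[4] > 0) {
      d <- stats::rbinom(1, counts[4], hz$chf_death_first[i])
      newc[5] <- newc[5] + counts[4] - d; newc[7] <- newc[7] + d
    }
    if (counts[5] > 0) {
      d <- stats::rbinom(1, counts[5], hz$chf_death_first[i])
      newc[6] <- newc[6] + counts[5] - d; newc[7] <- newc[7] + d
    }
    if (counts[6] > 0) {
      d <- stats::rbinom(1, counts[6], hz$chf_death_later[i])
      newc[6] <- newc[6] + counts[6] - d; newc[7] <- newc[7] + d
    }
    counts <- newc
    occ[i + 1, ] <- counts
  }
  occ5 <- cbind(occ[, 1], occ[, 2], occ[, 3],
                occ[, 4] + occ[, 5] + occ[, 6], occ[, 7]) / n_walkers
  colnames(occ5) <- c("RF", "DR", "AML", "CHF", "Death")
  occ5
}

# Assert cohort-trace occupancy agrees with a microsimulation within 3
# binomial standard errors at the given cycle rows (1-based, including the
# entry row).
expect_microsim_agreement <- function(trace, sim, rows, n_walkers) {
  for (r in rows) {
    p <- trace$occupancy[r, ]
    tol <- 3 * sqrt(p * (1 - p) / n_walkers) + 2 / n_walkers
    expect_true(all(abs(sim[r, ] - p) <= tol),
                label = paste0("microsim agreement at row ", r))
  }
}

all_base_branches <- function(config) {
  out <- list()
  for (sp in config$subpopulations) {
    for (strategy in c("ODX", "SOC")) {
      br <- branch_weights(sp, strategy)
      for (i in seq_len(nrow(br))) out[[length(out) + 1]] <- as.list(br[i, ])
    }
  }
  out
}
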
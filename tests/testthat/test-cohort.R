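test_that("null-hazard cohort stays recurrence-free", {
  cfg <- tiny_config(horizon_years = 5)
  trace <- run_branch(soc_et_branch("N0_ge50"), cfg)
  expect_equal(nrow(trace$occupancy), 11)
  expect_true(all(trace$occupancy[, "RF"] == 1))
  expect_true(all(trace$incidence == 0))
  # undiscounted person-time = horizon
  eff <- half_cycle_occupancy(trace)
  expect_equal(sum(eff[, "RF"]) * 0.5, 5)
})

test_that("single constant hazard decays geometrically", {
  p_cycle <- 0.1
  cfg <- tiny_config(horizon_years = 10)
  cfg$curves$life_table$annual_death_prob <- 1 - (1 - p_cycle)^2
  trace <- run_branch(soc_et_branch("N0_ge50"), cfg)
  k <- 0:20
  expect_equal(unname(trace$occupancy[, "RF"]), (1 - p_cycle)^k,
               tolerance = 1e-12)
  expect_equal(unname(trace$occupancy[, "Death"]), 1 - (1 - p_cycle)^k,
               tolerance = 1e-12)
})

test_that("transition matrices are valid probability kernels", {
  cfg <- base_case_config()
  for (b in all_base_branches(cfg)) {
    hz <- rscea:::branch_hazards(b, cfg)
    for (k in c(0, 10, hz$K - 1)) {
      for (tenure in c("first_year", "later")) {
        m <- build_transition_matrix(b, k, cfg, chf_tenure = tenure)
        expect_true(all(m >= 0) && all(m <= 1))
        expect_equal(unname(rowSums(m)), rep(1, 5), tolerance = 1e-12)
        expect_equal(unname(m["Death", ]), c(0, 0, 0, 0, 1))
        expect_equal(m["DR", "RF"], 0)
        expect_equal(unname(m["AML", c("RF", "DR", "CHF")]), c(0, 0, 0))
        expect_equal(unname(m["CHF", c("RF", "DR", "AML")]), c(0, 0, 0))
      }
    }
    # endocrine-only branches carry no treatment-induced leukemia risk
    if (b$treatment == "ET") {
      expect_equal(build_transition_matrix(b, 0, cfg)["RF", "AML"], 0)
    }
  }
  expect_error(build_transition_matrix(all_base_branches(cfg)[[1]], 1e6, cfg),
               "horizon")
})

test_that("mass is conserved and death is absorbing on every base branch", {
  cfg <- base_case_config()
  for (b in all_base_branches(cfg)) {
    trace <- run_branch(b, cfg)
    expect_true(all(abs(rowSums(trace$occupancy) - 1) < 1e-9))
    expect_true(all(diff(trace$occupancy[, "Death"]) >= 0))
    expect_true(all(trace$occupancy >= -1e-15))
    # incidence streams account for the final absorbing mass
    expect_equal(sum(trace$incidence[, "Death"]),
                 unname(trace$occupancy[nrow(trace$occupancy), "Death"]),
                 tolerance = 1e-9)
  }
  # with the life table forced to close at the model's maximum age, the
  # whole cohort is absorbed by the horizon
  closed <- cfg
  closed$curves$life_table$annual_death_prob[
    closed$curves$life_table$age >= 99] <- 1
  trace <- run_branch(all_base_branches(closed)[[1]], closed)
  expect_equal(unname(trace$occupancy[nrow(trace$occupancy), "Death"]), 1,
               tolerance = 1e-9)
})

test_that("half-cycle correction averages start and end occupancy", {
  cfg <- tiny_config(horizon_years = 1)
  cfg$curves$life_table$annual_death_prob <- 1 - (1 - 0.2)^2
  trace <- run_branch(soc_et_branch("N0_ge50"), cfg)
  eff <- half_cycle_occupancy(trace)
  expect_equal(unname(eff[1, "RF"]), 0.9)  # 1.0 -> 0.8 over the first cycle
  expect_equal(unname(eff[2, "RF"]), mean(c(0.8, 0.64)))
})

test_that("cohort trace matches a microsimulation oracle (small)", {
  cfg <- base_case_config()
  b <- list(stratum_id = "N1_ge50", strategy = "SOC", rs_context = "soc",
            treatment = "ET_CT", weight = 1)
  trace <- run_branch(b, cfg)
  n <- 20000
  sim <- microsim_branch(b, cfg, n, seed = 424242)
  expect_microsim_agreement(trace, sim, rows = c(2, 21, nrow(sim)), n)
})

test_that("trace writer emits one row per cycle with incidence columns", {
  cfg <- tiny_config(horizon_years = 2)
  trace <- run_branch(soc_et_branch("N0_ge50"), cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace(trace, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 5)
  expect_true(all(c("cycle", "age", "occ_RF", "occ_Death", "new_DR",
                    "new_Death") %in% names(df)))
})
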
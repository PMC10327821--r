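test_that("null-hazard endocrine branch costs assemble additively", {
  cfg <- tiny_config(horizon_years = 1, discount = 0)
  sp <- cfg$subpopulations$N0_ge50
  b <- soc_et_branch("N0_ge50")
  trace <- run_branch(b, cfg)
  costs <- value_costs(trace, b, cfg)
  # year-1 stratum cost replaces the generic recurring follow-up cost
  expect_equal(unname(costs["recurrence_free"]), sp$rf_year1_cost)
  expect_equal(unname(costs["adjuvant"]), sp$et_annual_cost)
  expect_equal(unname(costs["transportation"]), sp$transport_et_cost)
  expect_equal(unname(costs["sick_leave"]), 0)
  expect_equal(unname(costs["test"]), 0)
  expect_equal(sum(costs[c("aml", "chf", "distant_recurrence",
                           "end_of_life")]), 0)
  # chemotherapy branch adds its entry one-offs at full weight
  b_ct <- modifyList(b, list(treatment = "ET_CT"))
  costs_ct <- value_costs(run_branch(b_ct, cfg), b_ct, cfg)
  expect_equal(unname(costs_ct["sick_leave"]), sp$sick_leave_cost)
  expect_equal(unname(costs_ct["adjuvant"] - costs["adjuvant"]),
               sp$ct_addon_cost)
  expect_equal(unname(costs_ct["transportation"] - costs["transportation"]),
               sp$transport_ct_cost)
})

test_that("terminal cost values deaths at the cycle midpoint", {
  cfg <- tiny_config(horizon_years = 1)
  # everyone dies in the first cycle
  cfg$curves$life_table$annual_death_prob <- 1 - 1e-15
  b <- soc_et_branch("N0_ge50")
  trace <- run_branch(b, cfg)
  costs <- value_costs(trace, b, cfg)
  expect_equal(unname(costs["end_of_life"]),
               4606 * discount_factor(0.25, cfg$discount), tolerance = 1e-6)
})

test_that("undiscounted end-of-life cost equals tariff times deaths", {
  cfg <- base_case_config()
  cfg$discount$rate_early <- cfg$discount$rate_late <- 0
  for (b in all_base_branches(cfg)[c(1, 5, 9)]) {
    trace <- run_branch(b, cfg)
    costs <- value_costs(trace, b, cfg)
    expect_equal(unname(costs["end_of_life"]),
                 4606 * sum(trace$incidence[, "Death"]), tolerance = 1e-9)
  }
})

test_that("cost categories are linear in cost inputs", {
  cfg <- base_case_config()
  doubled <- cfg
  for (f in c("test_cost", "rf_recurring_cost", "dr_cdk46_cost",
              "dr_management_cost", "aml_oneoff", "aml_recurring",
              "chf_oneoff", "chf_recurring", "terminal_cost")) {
    doubled$costs[[f]] <- 2 * doubled$costs[[f]]
  }
  for (id in names(doubled$subpopulations)) {
    for (f in c("rf_year1_cost", "ct_addon_cost", "sick_leave_cost",
                "transport_ct_cost", "transport_et_cost",
                "et_annual_cost")) {
      doubled$subpopulations[[id]][[f]] <-
        2 * doubled$subpopulations[[id]][[f]]
    }
  }
  b <- list(stratum_id = "N0_lt50", strategy = "ODX", rs_context = "rs_gt25",
            treatment = "ET_CT", weight = 1)
  c1 <- value_costs(run_branch(b, cfg), b, cfg)
  c2 <- value_costs(run_branch(b, doubled), b, doubled)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)
})

test_that("QALYs apply utilities, adjustment, age curve and decrement", {
  # flat world: QALY = utility x LY exactly
  cfg <- tiny_config(horizon_years = 5, discount = 0)
  cfg$utilities$france_adjustment <- 1
  cfg$curves$age_utility <- data.frame(age = 0:120, multiplier = 1)
  b <- soc_et_branch("N0_ge50")
  trace <- run_branch(b, cfg)
  lq <- value_qalys(trace, b, cfg)
  expect_equal(lq$ly, 5)
  expect_equal(lq$qaly, 5 * 0.860)

  # country adjustment multiplies, capped at 1
  cfg$utilities$france_adjustment <- 1.043
  expect_equal(value_qalys(trace, b, cfg)$qaly, 5 * 0.860 * 1.043)
  cfg$utilities$u_rf <- 0.99
  expect_equal(value_qalys(trace, b, cfg)$qaly, 5 * 1.0)
  cfg$utilities$u_rf <- 0.860

  # chemotherapy decrement applies for one cycle of ET_CT occupancy
  cfg$utilities$france_adjustment <- 1
  b_ct <- modifyList(b, list(treatment = "ET_CT"))
  lq_ct <- value_qalys(run_branch(b_ct, cfg), b_ct, cfg)
  expect_equal(lq$qaly - lq_ct$qaly, 0.040 * 0.5)

  # age multiplier re-anchored at stratum entry age
  cfg$curves$age_utility <- make_age_utility_multiplier(43, 0.003)
  lq_age <- value_qalys(trace, b, cfg)
  mult <- (1 - 0.003 * (floor(60 + (1:10) * 0.5 - 0.25) - 43)) /
    (1 - 0.003 * (60 - 43))
  expect_equal(lq_age$qaly, sum(0.860 * mult * 0.5))
})

test_that("QALYs never exceed life-years at base-case utilities", {
  cfg <- base_case_config()
  for (b in all_base_branches(cfg)[c(2, 6, 10)]) {
    trace <- run_branch(b, cfg)
    lq <- value_qalys(trace, b, cfg)
    expect_lt(lq$qaly, lq$ly)
    expect_lte(lq$ly, 100)
  }
})
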
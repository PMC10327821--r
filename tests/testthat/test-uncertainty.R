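cfg <- base_case_config()

test_that("one-way sensitivity analysis brackets the base case", {
  sel <- c("test_cost", "u_rf", "chf_rr_ct")
  dsa <- suppressWarnings(run_dsa(cfg, params = sel))
  expect_equal(sort(dsa$name), sort(sel))
  expect_true(all(dsa$low <= dsa$base & dsa$base <= dsa$high))
  # collapsed bounds reproduce the base case exactly (zero swing)
  base_cmp <- attr(dsa, "base")
  collapsed <- run_dsa(cfg, params = "test_cost",
                       ranges = data.frame(name = "test_cost",
                                           low = 1850, high = 1850))
  expect_equal(collapsed$swing_cost, 0)
  expect_equal(collapsed$dc_low, base_cmp$delta_cost, tolerance = 1e-9)

  # the test price enters the increment linearly, once, undiscounted
  tc <- dsa[dsa$name == "test_cost", ]
  expect_equal(tc$dc_high - tc$dc_low, 1850 * 0.4, tolerance = 1e-6)
  expect_equal(tc$swing_qaly, 0)
})

test_that("probability bounds stay interior or are clamped with warning", {
  # survival-type probabilities vary on the complementary-risk scale
  dsa <- run_dsa(cfg, params = "N0_lt50.rfs10.rs_lt16.ET")
  expect_equal(dsa$low, 1 - 0.030 * 1.2, tolerance = 1e-9)
  expect_equal(dsa$high, 1 - 0.030 * 0.8, tolerance = 1e-9)
  # explicit out-of-domain bounds are clamped, not propagated
  expect_warning(
    clamped <- run_dsa(cfg, params = "u_rf",
                       ranges = data.frame(name = "u_rf", low = 0.5,
                                           high = 1.2)),
    "clamped")
  expect_lte(clamped$high, 1)
})

test_that("PSA is seed-reproducible and parameter-stable", {
  p1 <- run_psa(cfg, n = 15, seed = 7)
  p2 <- run_psa(cfg, n = 15, seed = 7)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(cfg, n = 15, seed = 8)
  expect_false(identical(p1$draws$delta_cost, p3$draws$delta_cost))
  # summary is recomputable from the draws
  expect_equal(p1$summary$frac_dominant,
               mean(p1$draws$delta_cost < 0 & p1$draws$delta_qaly > 0))
  expect_equal(p1$draws$nmb,
               20000 * p1$draws$delta_qaly - p1$draws$delta_cost)
})

test_that("a degenerate PSA reproduces the deterministic result", {
  spec <- default_psa_spec(cfg)
  spec$scalars$family <- "fixed"
  spec$share_groups <- list()
  p <- run_psa(cfg, spec = spec, n = 1, seed = 1)
  det <- run_model(cfg)$population$comparison
  expect_equal(p$draws$delta_cost, det$delta_cost, tolerance = 1e-9)
  expect_equal(p$draws$delta_qaly, det$delta_qaly, tolerance = 1e-9)
})

test_that("sampled share groups stay on the simplex and center on base", {
  spec <- default_psa_spec(cfg)
  g <- spec$share_groups[["N0_lt50"]]
  set.seed(rscea:::name_seed(3, paste0("rs_shares.", g$id)))
  a <- matrix(rgamma(5000 * 3, shape = g$concentration * g$shares), 5000, 3,
              byrow = TRUE)
  sh <- a / rowSums(a)
  expect_equal(rowSums(sh), rep(1, 5000), tolerance = 1e-12)
  for (j in 1:3) {
    expect_lt(abs(mean(sh[, j]) - g$shares[j]),
              3 * sd(sh[, j]) / sqrt(5000))
  }
})

test_that("CEAC follows from the draws", {
  fake <- list(draws = data.frame(draw = 1, delta_cost = -100,
                                  delta_qaly = -0.01, nmb = NA))
  curve <- ceac(fake, wtp_grid = c(0, 5000, 9999, 10001, 20000))
  expect_equal(curve$probability, c(1, 1, 1, 0, 0))
  # at lambda = 0 the curve reports the fraction of cost-saving draws
  p <- run_psa(cfg, n = 10, seed = 2)
  curve <- ceac(p, wtp_grid = c(0, 20000))
  expect_equal(curve$probability[1], mean(p$draws$delta_cost < 0))
  # non-decreasing whenever every draw gains QALYs
  if (all(p$draws$delta_qaly > 0)) {
    expect_true(all(diff(ceac(p)$probability) >= 0))
  }
})

test_that("scenario runner deep-merges overrides", {
  base_cmp <- run_model(cfg)$population$comparison
  same <- run_scenario(cfg, list())
  expect_equal(same$delta_cost, base_cmp$delta_cost, tolerance = 1e-12)
  expect_equal(same$nmb, base_cmp$nmb, tolerance = 1e-12)

  # aligning test-guided chemotherapy use with standard of care kills the
  # chemotherapy reduction
  ov <- list(subpopulations = list())
  for (id in names(cfg$subpopulations)) {
    q <- cfg$subpopulations[[id]]$soc_ct_prob
    ov$subpopulations[[id]] <- list(
      ct_prob_by_rs = list(lt16 = q, mid = q, gt25 = q))
  }
  aligned <- run_scenario(cfg, ov)
  expect_equal(aligned$ct_avoided, 0, tolerance = 1e-12)

  expect_error(run_scenario(cfg, list(utilities = list(u_rf = 2))),
               "validation")
})
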
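#' Sensitivity and scenario analysis
#'
#' One-way deterministic sensitivity analysis (tornado), probabilistic
#' sensitivity analysis with seeded, parameter-stable random streams, the
#' cost-effectiveness acceptability curve, and a scenario runner that
#' deep-merges configuration overrides.
#'
#' @name uncertainty
NULL

# Deterministic child seed for a named random stream: a polynomial hash of
# the parameter name folded into the root seed, so adding or removing one
# parameter does not perturb the draws of the others.
name_seed <- function(root, name) {
  acc <- as.numeric(root %% 2147483647)
  for (code in utf8ToInt(name)) acc <- (acc * 31 + code) %% 2147483647
  as.integer(acc)
}

set_param <- function(config, path, value) {
  config[[path]] <- value
  config
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full deterministic pipeline at the low and high bound of each
#' selected parameter and reports the swing in incremental cost and QALYs.
#' Default bounds are +/-20% of the base value; probabilities above 0.5 are
#' instead varied by -/+20% of the complementary event probability so the
#' bounds stay interior to (0, 1). User-supplied bounds that violate a
#' probability's domain are clamped to [0, 1] with a warning.
#'
#' @param config Model configuration.
#' @param ranges Optional data.frame with columns `name`, `low`, `high`
#'   overriding the default bounds for those parameters.
#' @param params Optional character vector of parameter names to vary;
#'   defaults to every non-degenerate scalar of [default_psa_spec()].
#' @param rel Half-width of the default relative range (0.2 = +/-20%).
#' @return An `rscea_dsa`: data.frame sorted by cost swing with the bounds
#'   used and the incremental cost/QALY at each bound; the base comparison
#'   is attached as attribute `base`.
#' @export
run_dsa <- function(config, ranges = NULL, params = NULL, rel = 0.2) {
  spec <- default_psa_spec(config)
  tab <- spec$scalars[spec$scalars$family != "fixed", , drop = FALSE]
  if (!is.null(params)) tab <- tab[tab$name %in% params, , drop = FALSE]
  base_cmp <- run_model(config)$population$comparison
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    name <- tab$name[i]; base <- tab$base[i]; path <- tab$path[[i]]
    if (identical(tab$scale[i], "complement")) {
      # vary the rarer complementary event by the same relative amount
      low <- 1 - (1 - base) * (1 + rel); high <- 1 - (1 - base) * (1 - rel)
    } else {
      low <- base * (1 - rel); high <- base * (1 + rel)
    }
    if (!is.null(ranges) && name %in% ranges$name) {
      j <- match(name, ranges$name)
      low <- ranges$low[j]; high <- ranges$high[j]
    }
    if (tab$kind[i] == "prob" && (low < 0 || high > 1)) {
      warning("bounds for ", name, " clamped to [0,1]")
      low <- max(low, 0); high <- min(high, 1)
    }
    cmp_at <- function(v) {
      run_model(set_param(config, path, v))$population$comparison
    }
    lo <- cmp_at(low); hi <- cmp_at(high)
    data.frame(name = name, base = base, low = low, high = high,
               dc_low = lo$delta_cost, dc_high = hi$delta_cost,
               dq_low = lo$delta_qaly, dq_high = hi$delta_qaly,
               swing_cost = abs(hi$delta_cost - lo$delta_cost),
               swing_qaly = abs(hi$delta_qaly - lo$delta_qaly),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$swing_cost), ]
  rownames(out) <- NULL
  structure(out, base = base_cmp, class = c("rscea_dsa", "data.frame"))
}

# Draw n samples for one scalar parameter entry (method of moments).
# scale = "complement" samples 1 - base and returns the complement, keeping
# distributions for probabilities near 1 interior to (0, 1).
sample_param <- function(family, base, se, n, scale = "direct") {
  if (identical(scale, "complement")) {
    return(1 - sample_param(family, 1 - base, se, n))
  }
  switch(family,
    fixed = rep(base, n),
    beta = {
      v <- base * (1 - base) / se^2 - 1
      stopifnot(v > 0)
      stats::rbeta(n, base * v, (1 - base) * v)
    },
    gamma = {
      if (base == 0) return(rep(0, n))
      shape <- (base / se)^2
      stats::rgamma(n, shape = shape, rate = shape / base)
    },
    lognormal = {
      sdlog <- sqrt(log(1 + (se / base)^2))
      stats::rlnorm(n, log(base) - sdlog^2 / 2, sdlog)
    },
    stop("unknown distribution family: ", family))
}

#' Probabilistic sensitivity analysis
#'
#' Samples every parameter jointly from its distribution (share vectors as
#' Dirichlet groups), re-runs the deterministic pipeline per draw, and
#' summarises incremental outcomes. Identical seeds give identical results;
#' each parameter has its own deterministic random stream derived from the
#' root seed.
#'
#' @param config Model configuration.
#' @param spec An `rscea_psa_spec`; defaults to [default_psa_spec()].
#' @param n Number of draws (>= 1).
#' @param seed Root seed.
#' @return An `rscea_psa`: list with `draws` (data.frame: draw, delta_cost,
#'   delta_qaly, nmb), `n`, `seed` and `summary` (mean increments,
#'   probabilistic ICER from mean cost over mean QALY, fraction dominant,
#'   fraction cost-effective at the configured willingness-to-pay).
#' @export
run_psa <- function(config, spec = default_psa_spec(config), n, seed = 1L) {
  stopifnot(n >= 1)
  tab <- spec$scalars
  draws <- matrix(NA_real_, n, nrow(tab))
  for (i in seq_len(nrow(tab))) {
    if (tab$family[i] == "fixed") {
      draws[, i] <- tab$base[i]
    } else {
      set.seed(name_seed(seed, tab$name[i]))
      draws[, i] <- sample_param(tab$family[i], tab$base[i], tab$se[i], n,
                                 tab$scale[i])
    }
  }
  share_draws <- lapply(spec$share_groups, function(g) {
    set.seed(name_seed(seed, paste0("rs_shares.", g$id)))
    a <- matrix(stats::rgamma(n * length(g$shares),
                              shape = g$concentration * g$shares),
                n, length(g$shares), byrow = TRUE)
    sw <- a / rowSums(a)
    colnames(sw) <- names(g$shares)
    sw
  })
  names(share_draws) <- vapply(spec$share_groups, `[[`, "", "id")

  wtp <- config$settings$wtp
  res <- matrix(NA_real_, n, 2)
  for (j in seq_len(n)) {
    cfg <- config
    for (i in seq_len(nrow(tab))) {
      cfg[[tab$path[[i]]]] <- draws[j, i]
    }
    for (id in names(share_draws)) {
      sh <- share_draws[[id]][j, ]
      for (cat in names(sh)) {
        cfg$subpopulations[[id]]$rs_shares[[cat]] <- unname(sh[[cat]])
      }
    }
    cmp <- run_model(cfg)$population$comparison
    res[j, ] <- c(cmp$delta_cost, cmp$delta_qaly)
  }
  df <- data.frame(draw = seq_len(n), delta_cost = res[, 1],
                   delta_qaly = res[, 2],
                   nmb = wtp * res[, 2] - res[, 1])
  mean_dc <- mean(df$delta_cost)
  mean_dq <- mean(df$delta_qaly)
  structure(list(
    draws = df, n = n, seed = seed,
    summary = list(
      mean_delta_cost = mean_dc, mean_delta_qaly = mean_dq,
      prob_icer = if (mean_dc < 0 && mean_dq > 0) NA_real_ else
        mean_dc / mean_dq,
      prob_icer_status = if (mean_dc < 0 && mean_dq > 0) "dominant" else
        if (mean_dc > 0 && mean_dq < 0) "dominated" else "icer",
      frac_dominant = mean(df$delta_cost < 0 & df$delta_qaly > 0),
      frac_ce_at_wtp = mean(df$nmb > 0))),
    class = "rscea_psa")
}

#' @export
print.rscea_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf("PSA: %d draws (seed %d)\n", x$n, x$seed))
  cat(sprintf("  mean dCost %.0f EUR, mean dQALY %.3f (%s)\n",
              s$mean_delta_cost, s$mean_delta_qaly, s$prob_icer_status))
  cat(sprintf("  dominant in %.1f%%, cost-effective at WTP in %.1f%%\n",
              100 * s$frac_dominant, 100 * s$frac_ce_at_wtp))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' @param result An `rscea_psa`.
#' @param wtp_grid Willingness-to-pay thresholds (EUR/QALY).
#' @return data.frame with `wtp` and `probability` that the tested strategy
#'   is cost-effective (`wtp * dQALY - dCost > 0`) at each threshold.
#' @export
ceac <- function(result, wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(nrow(result$draws) > 0)
  prob <- vapply(wtp_grid, function(l) {
    mean(l * result$draws$delta_qaly - result$draws$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

# Recursive override merge; data.frames are replaced, not merged.
deep_merge <- function(base, overrides) {
  if (!is.list(overrides) || is.data.frame(overrides) || !is.list(base)) {
    return(overrides)
  }
  for (nm in names(overrides)) {
    base[[nm]] <- if (nm %in% names(base)) {
      deep_merge(base[[nm]], overrides[[nm]])
    } else {
      overrides[[nm]]
    }
  }
  base
}

#' Run a scenario configuration
#'
#' Deep-merges partial overrides onto a base configuration, validates the
#' result and re-runs the deterministic pipeline.
#'
#' @param base Base configuration.
#' @param overrides Nested list of overriding values (may be empty).
#' @return The overall `rscea_comparison`; the full `rscea_result` is
#'   attached as attribute `result`.
#' @export
run_scenario <- function(base, overrides = list()) {
  cfg <- deep_merge(unclass(base), overrides)
  class(cfg) <- "rscea_config"
  validate_config(cfg)
  result <- run_model(cfg)
  structure(result$population$comparison, result = result)
}
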
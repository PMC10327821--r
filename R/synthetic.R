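#' Synthetic external inputs
#'
#' The analysis needs three external curves (a female life table, an
#' age-utility multiplier, an age-specific heart-failure incidence curve) and
#' a set of parameter-uncertainty distributions. National sources exist for
#' all of them but are not redistributable, so these generators produce
#' configurable stand-ins with realistic shapes; users can substitute real
#' CSV data at any time via the configuration.
#'
#' @name synthetic_inputs
NULL

#' Synthetic female life table (Gompertz-Makeham)
#'
#' Annual death probability at age x is `1 - exp(-(a + b * exp(c * x)))`.
#' Defaults are calibrated so life expectancy at birth is about 85 years,
#' France-like for women. The final-age probability is forced to 1 so the
#' table closes.
#'
#' @param makeham_a Age-independent hazard component (>= 0).
#' @param gompertz_b Gompertz level parameter (> 0).
#' @param gompertz_c Gompertz slope per year of age (> 0).
#' @param max_age Last age in the table.
#' @return data.frame with columns `age`, `annual_death_prob`.
#' @examples
#' lt <- make_life_table()
#' life_expectancy(lt) # ~85
#' @export
make_life_table <- function(makeham_a = 5e-5, gompertz_b = 8e-6,
                            gompertz_c = 0.105, max_age = 110) {
  if (makeham_a < 0) stop("makeham_a must be >= 0")
  if (gompertz_b <= 0 || gompertz_c <= 0) {
    stop("gompertz_b and gompertz_c must be positive")
  }
  age <- 0:max_age
  q <- 1 - exp(-(makeham_a + gompertz_b * exp(gompertz_c * age)))
  q <- pmin(q, 1)
  q[length(q)] <- 1
  data.frame(age = age, annual_death_prob = q)
}

#' Life expectancy from a life table
#'
#' Standard life-table summation with deaths spread uniformly within the year
#' of age (each death contributes half a year in its final year).
#'
#' @param life_table data.frame with `age`, `annual_death_prob`.
#' @param from_age Age at which expectancy is evaluated.
#' @return Expected further years of life at `from_age`.
#' @export
life_expectancy <- function(life_table, from_age = 0) {
  q <- life_table$annual_death_prob[life_table$age >= from_age]
  l <- cumprod(c(1, 1 - q))
  l <- l[seq_along(q)]
  sum(l * (1 - q / 2))
}

# Solve the Gompertz level parameter so the synthetic table hits a target
# life expectancy at birth (used by the synth CLI subcommand).
calibrate_life_table <- function(target_le, makeham_a = 5e-5,
                                 gompertz_c = 0.105, max_age = 110) {
  f <- function(logb) {
    life_expectancy(make_life_table(makeham_a, exp(logb), gompertz_c, max_age))
  }
  root <- stats::uniroot(function(x) f(x) - target_le,
                         lower = log(1e-9), upper = log(1e-2))
  make_life_table(makeham_a, exp(root$root), gompertz_c, max_age)
}

#' Age-utility multiplier curve
#'
#' Ratio of utility at a given age to utility at the anchor age: 1 at the
#' anchor, declining linearly with age above it, floored at 0.5. Emulates the
#' age-related decline seen in EQ-5D population norms.
#'
#' @param anchor_age Age at which the multiplier is 1.
#' @param slope_per_year Linear decline per year of age (>= 0); default 0.003.
#' @param max_age Last age in the curve.
#' @return data.frame with columns `age`, `multiplier` (step function:
#'   values apply to the whole year of age).
#' @export
make_age_utility_multiplier <- function(anchor_age = 43, slope_per_year = 0.003,
                                        max_age = 110) {
  if (slope_per_year < 0) stop("slope_per_year must be >= 0")
  age <- 0:max_age
  m <- pmax(1 - slope_per_year * pmax(age - anchor_age, 0), 0.5)
  data.frame(age = age, multiplier = m)
}

#' Age-specific chronic-heart-failure incidence curve
#'
#' Annual probability `base * 2^((age - 50) / doubling_years)`, capped at
#' 0.2. Stand-in for registry incidence among women without chemotherapy
#' exposure; incidence roughly doubles every decade of age.
#'
#' @param base_annual_prob Annual probability at age 50 (> 0); default 0.001.
#' @param doubling_years Years per doubling (> 0); default 10.
#' @param max_age Last age in the curve.
#' @return data.frame with columns `age`, `annual_prob`.
#' @export
make_chf_incidence <- function(base_annual_prob = 0.001, doubling_years = 10,
                               max_age = 110) {
  if (base_annual_prob <= 0) stop("base_annual_prob must be > 0")
  if (doubling_years <= 0) stop("doubling_years must be > 0")
  age <- 0:max_age
  p <- pmin(base_annual_prob * 2^((age - 50) / doubling_years), 0.2)
  data.frame(age = age, annual_prob = p)
}

# Step lookup into an age curve: values apply to [age, age + 1); ages beyond
# the table are clamped to the nearest end.
age_lookup <- function(curve, ages, value_col) {
  idx <- findInterval(floor(ages), curve$age)
  idx[idx < 1] <- 1
  curve[[value_col]][idx]
}

#' Default probabilistic-sensitivity-analysis distributions
#'
#' Builds a distribution for every sampled scalar parameter of a
#' configuration: beta for probabilities and utilities (method of moments,
#' standard error 10% of the mean), gamma for costs (SE 20% of the mean),
#' lognormal for hazard-scale ratios (SE 10%), and Dirichlet (concentration
#' 400 x shares) for the recurrence-score share vectors. Parameters whose
#' base value is degenerate (0 or 1) are held fixed.
#'
#' Probabilities above 0.5 (recurrence-free survivals, utilities) are
#' parameterised on the complementary-event scale: the beta describes
#' `1 - p` with SE 10% of `1 - p`, so the sampled distribution stays interior
#' to (0, 1) instead of piling mass at 1.
#'
#' @param config A model configuration (see [base_case_config()]).
#' @return An object of class `rscea_psa_spec`: data.frame of parameter
#'   entries plus share groups, consumed by [run_psa()].
#' @export
default_psa_spec <- function(config) {
  tab <- parameter_table(config)
  tab$family <- ifelse(tab$kind == "prob", "beta",
                ifelse(tab$kind == "cost", "gamma",
                ifelse(tab$kind == "ratio", "lognormal", "gamma")))
  tab$scale <- ifelse(tab$kind == "prob" & tab$base > 0.5,
                      "complement", "direct")
  tab$se <- ifelse(tab$kind == "cost", 0.2, 0.1) *
    ifelse(tab$scale == "complement", 1 - tab$base, tab$base)
  degenerate <- (tab$kind == "prob" & (tab$base <= 0 | tab$base >= 1)) |
    tab$base == 0
  tab$family[degenerate] <- "fixed"
  tab$se[degenerate] <- 0
  groups <- lapply(config$subpopulations, function(sp) {
    sh <- unlist(effective_rs_shares(sp))
    list(id = sp$id, shares = sh[sh > 0], concentration = 400)
  })
  structure(list(scalars = tab, share_groups = groups),
            class = "rscea_psa_spec")
}

# Enumerate the sampled scalar parameters of a config as (name, path, kind,
# base). Paths are character vectors usable with `config[[path]]`.
parameter_table <- function(config) {
  rows <- list()
  add <- function(name, path, kind) {
    base <- config[[path]]
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, kind = kind, base = as.numeric(base),
      path = I(list(path)), stringsAsFactors = FALSE)
  }
  for (f in c("aml_cycle_prob", "aml_5yr_death_prob")) {
    add(f, c("clinical", f), "prob")
  }
  for (f in c("chf_rr_ct", "chf_excess_hr_year1", "chf_excess_hr_later")) {
    add(f, c("clinical", f), "ratio")
  }
  add("dr_median_os_months", c("clinical", "dr_median_os_months"), "positive")
  for (f in c("u_rf", "u_dr", "u_aml", "u_chf", "ct_decrement")) {
    add(f, c("utilities", f), "prob")
  }
  add("france_adjustment", c("utilities", "france_adjustment"), "ratio")
  for (f in c("test_cost", "rf_recurring_cost", "dr_cdk46_cost",
              "dr_management_cost", "aml_oneoff", "aml_recurring",
              "chf_oneoff", "chf_recurring", "terminal_cost")) {
    add(f, c("costs", f), "cost")
  }
  for (sp in config$subpopulations) {
    id <- sp$id
    add(paste0(id, ".soc_ct_prob"),
        c("subpopulations", id, "soc_ct_prob"), "prob")
    for (rs in names(sp$ct_prob_by_rs)) {
      add(paste0(id, ".ct_prob.", rs),
          c("subpopulations", id, "ct_prob_by_rs", rs), "prob")
    }
    for (ctx in names(sp$recurrence)) {
      for (trt in c("ET", "ET_CT")) {
        add(paste0(id, ".rfs10.", ctx, ".", trt),
            c("subpopulations", id, "recurrence", ctx, trt), "prob")
      }
    }
    for (f in c("rf_year1_cost", "ct_addon_cost", "sick_leave_cost",
                "transport_ct_cost", "transport_et_cost", "et_annual_cost")) {
      add(paste0(id, ".", f), c("subpopulations", id, f), "cost")
    }
  }
  do.call(rbind, rows)
}

#' Write the synthetic input curves as CSV
#'
#' @param dir Output directory (created if needed).
#' @param life_table,age_utility,chf_incidence Curves to write; defaults are
#'   the package generators' defaults.
#' @return Invisibly, the paths written.
#' @export
write_synthetic_inputs <- function(dir,
                                   life_table = make_life_table(),
                                   age_utility = make_age_utility_multiplier(),
                                   chf_incidence = make_chf_incidence()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("life_table.csv", "age_utility.csv",
                            "chf_incidence.csv"))
  utils::write.csv(life_table, paths[1], row.names = FALSE)
  utils::write.csv(age_utility, paths[2], row.names = FALSE)
  utils::write.csv(chf_incidence, paths[3], row.names = FALSE)
  invisible(paths)
}
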
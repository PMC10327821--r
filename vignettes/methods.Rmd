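---
title: "Model structure, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rscea)
```

This vignette is the package's own account of the science: what the model
computes, the assumptions behind each stage, what the synthetic inputs do
and do not emulate, and the choices made where the design was genuinely
open. It states no empirical result that the test suite or the acceptance
script does not itself compute.

## The decision problem

In hormone-receptor-positive, HER2-negative early breast cancer at high
clinicopathological risk, adjuvant chemotherapy (CT) benefits only a subset
of patients, while exposing all to short- and long-term toxicity. The
21-gene recurrence-score (RS) assay stratifies patients by recurrence risk
and expected CT benefit. The model asks: compared with deciding on
clinicopathological grounds alone (SoC), does RS-guided allocation of CT
save money and/or gain quality-adjusted survival for a national insurer?

Three strata are modelled, with population weights 41.2% / 16.7% / 42.1%
and entry ages 43 / 64 / 61: premenopausal node-negative, postmenopausal
node-negative, postmenopausal node-positive (1–3 nodes). Premenopausal
node-positive patients are excluded because trial evidence shows CT benefit
across the RS range there, leaving no role for the test.

## Decision tree

Each (stratum, strategy) pair is decomposed into *branch cohorts* — the
atomic unit the Markov engine propagates. Under the test strategy a branch
is (RS category, treatment); under SoC it is (pooled context, treatment).
Carrying branches separately rather than mixing treatments in one trace
keeps each cohort homogeneous in its recurrence hazard and toxicity
exposure; results are weight-averaged afterwards. Branch weights are
share × CT-probability products and always sum to one.

The published premenopausal RS shares (33.7% / 73.9% / 27.1%) cannot lie on
a simplex. The package treats the outer categories as authoritative and
derives the middle share as the complement (39.2%); this choice exactly
reproduces the published 35.4% CT reduction for that stratum, which is how
the inconsistency was diagnosed. `effective_rs_shares()` implements the
rule; the printed values are kept verbatim in the configuration so the
resolution is visible, not silently baked in.

## Cohort engine

Five states: recurrence-free (RF), distant recurrence (DR), AML, CHF,
death; 6-month cycles; half-cycle correction (recurring flows valued at the
mean of start- and end-of-cycle occupancy, discounted at cycle midpoints);
horizon to age 100.

* **Recurrence.** Ten-year recurrence-free survival by (context, treatment)
  is converted to a constant per-cycle hazard
  (`cycle_prob_from_survival`). Constant-rate recurrence is an explicit
  modelling assumption carried over from the source evidence; no
  time-varying hazard is offered.
* **Toxicities.** AML applies a per-cycle probability (0.62%) to CT-treated
  patients; CHF applies the age-indexed background incidence, rescaled on
  the hazard scale by 1.61 for CT-treated patients. Both risks also apply
  in the DR state for CT-treated branches (config-togglable via
  `clinical$dr_toxicity`).
* **AML risk window.** The per-cycle AML probability applies for
  `aml_risk_window_years` (default 5) after model entry. An unbounded
  window (available as `NULL`) would compound 0.62% per cycle into a
  lifetime AML incidence above 25% in CT-treated cohorts, two orders of
  magnitude beyond the ~1–2% cumulative incidence reported for
  anthracycline regimens; five years covers the latency window in which
  therapy-related AML concentrates.
* **Mortality.** RF uses the life table. DR uses
  `max(background, exponential hazard from a 63.9-month median)`; AML uses
  `max(background, hazard from a 76% five-year death probability)` — a
  maximum, not a sum, because disease-specific survival sources already
  include all-cause death. CHF mortality is background rescaled by an
  excess hazard ratio that depends on *tenure in the state* (first year
  vs later), implemented with internal tunnel substates and reported
  collapsed. The excess ratios (5.0 year one, 2.0 after) are synthetic
  defaults — the source values are not printed in the literature the
  analysis draws on — and are configurable.
* **Competing risks.** Within a cycle, marginal event probabilities leaving
  a state are converted to rates, summed, and reallocated:
  `p_total = 1 − exp(−Σr)`, `p_i = p_total · r_i/Σr`. Rows are therefore
  valid for any hazard magnitudes, and exact under the constant-hazard
  assumption.
* **Ages** advance 0.5 years per cycle from the stratum entry age; curve
  lookups use the floored age (values apply to `[age, age+1)`).

The deterministic recursion is verified in the test suite against an
independent 200,000-walker microsimulation that uses the same per-cycle
matrices but advances multinomial counts, agreeing within three binomial
standard errors at entry, year 10 and the horizon.

## Valuation

Cost categories mirror the published cost table. Conventions that needed a
decision:

* Recurring amounts printed as per-cycle values (follow-up €604, DR
  management €6,516, AML €5,806, CHF €1,148) are applied per cycle; the
  CDK4/6 drug cost (€14,395) is an annual figure halved per cycle. Every
  recurring item carries an explicit `cycle`/`year` period flag so the
  interpretation is overridable.
* The first-year RF stratum cost *replaces* the generic recurring follow-up
  cost in cycles 0–1 (it is a first-year total including follow-up).
* CT-related one-offs (CT add-on, sick leave, CT transport) hit cycle 0 of
  ET+CT branches undiscounted; endocrine-therapy transport is a first-year
  cost split over the first two cycle starts; the test is charged once per
  tested patient at the strategy level (the test precedes the treatment
  decision, so it cannot be a branch cost).
* Endocrine drug cost applies while recurrence-free for the first five
  years (standard adjuvant duration; `costs$et_duration_years`).
* Terminal care (€4,606) is charged per death at the death-cycle midpoint.

QALYs multiply state utilities by the country adjustment 1.043 (capped at
1; a config switch `apply_france_adjustment` exists because it is ambiguous
whether published utilities are pre- or post-adjustment), and by an age
multiplier re-anchored to 1 at the stratum entry age. The CT utility
decrement (0.040) applies to RF occupancy of ET+CT branches for one cycle —
the 6-month CT course — and is configurable.

## Synthetic external inputs

The analysis needs four inputs that the published evidence cites but does
not print. The generators emulate their *shape*, not any specific national
dataset; a green test therefore establishes internal correctness and
qualitative behaviour, not numerical agreement with any country's data.

* **Life table**: Gompertz–Makeham hazard
  `q(x) = 1 − exp(−(a + b·e^{cx}))`, defaults `a = 5e-5`, `b = 8e-6`,
  `c = 0.105`, giving life expectancy at birth ≈ 85.1 years (France-like
  for women; the level parameter was calibrated once to that target by
  life-table summation). The final-age probability is forced to 1.
* **Age-utility multiplier**: 1 at the anchor age, −0.003/year above it,
  floored at 0.5 — the approximately linear decline of EQ-5D population
  norms over the relevant age span.
* **CHF incidence**: 0.001/year at age 50, doubling per decade, capped at
  0.2 — the roughly exponential age gradient of heart-failure registries.
* **PSA distributions**: beta for probabilities and utilities (SE 10%),
  gamma for costs (SE 20%), lognormal for hazard ratios (SE 10%), Dirichlet
  (concentration 400 × shares) for RS share vectors; degenerate values
  (0/1) held fixed. Probabilities above 0.5 — recurrence-free survivals,
  utilities, the 5-year AML death probability — are parameterised on the
  **complementary-event scale**: the distribution describes `1 − p` with
  the same relative spread. A beta with mean 0.91 and SD 0.09 would pile
  mass at 1 and truncate its upper tail; ±20% bounds on such a parameter
  would leave the unit interval and clamp to the degenerate "no recurrence
  ever". Specifying the uncertainty on the rarer complement keeps every
  distribution interior and every one-way bound meaningful, and is the
  convention this package applies uniformly in both DSA and PSA.

These spreads are conventions, not estimates: the original supplementary
ranges are unavailable, so probabilistic results can only be compared
qualitatively with the published ones.

## Sensitivity machinery

One-way DSA re-runs the full pipeline at each bound and sorts by swing.
PSA derives one deterministic random stream per parameter from the root
seed (polynomial name hash), so adding a parameter never perturbs the
draws of the others and identical seeds are bitwise reproducible. The
probabilistic ICER is the ratio of mean incremental cost to mean
incremental QALYs (not a mean of ratios). The CEAC reports, per
willingness-to-pay λ, the fraction of draws with positive net benefit.
ICERs are reported only when one strategy is not dominant, matching the
published convention.

## Numerical choices and degenerate inputs

* All probability manipulation is on the hazard scale; probabilities of
  exactly 1 are capped at `1 − 1e-12` before the rate transform.
* Transition rows are validated to sum to 1 within 1e-12; traces conserve
  mass within 1e-9 over ~114 cycles.
* A zero-survival recurrence input is a domain error (infinite hazard),
  not a silent cap.
* Share vectors must normalize within 1e-9 after the complement rule;
  stratum weights within 1e-6 (they are printed to three digits).
* Ties in dominance classification (Δ exactly 0) fall through to the ICER
  branch, with a signed infinite ratio rather than an error when ΔQALY = 0.

## Known limitations

* Absolute costs, LYs and QALYs depend on the synthetic curves and the
  toxicity-window and CHF-mortality defaults; they are internally
  consistent but not reproductions of any published absolute figure. The
  decision-tree quantities (CT use and its reduction) are exact.
* No indirect/societal costs, no test failures or clinician overrides of
  RS-guided decisions, no time-varying recurrence hazards, no tunnel states
  for DR treatment lines, no EVPI and no correlated PSA beyond the
  Dirichlet share groups.
* The registry-based and expert-opinion scenario analyses of the source
  evidence require inputs that were never published; the scenario *runner*
  is implemented and tested, but those two scenarios cannot be reproduced
  numerically.
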
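Package: rscea
Title: Cost-Effectiveness of Recurrence-Score-Guided Adjuvant Chemotherapy
Version: 0.1.0
Authors@R:
    person("Model", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decision-tree plus Markov cohort model evaluating 21-gene
    recurrence-score testing against standard of care for adjuvant
    chemotherapy decisions in hormone-receptor-positive, HER2-negative early
    breast cancer, from a health-insurance perspective. Implements treatment
    allocation trees, a five-state cohort engine (recurrence-free, distant
    recurrence, acute myeloid leukemia, chronic heart failure, death) with
    half-cycle correction and two-tier discounting, cost and QALY valuation,
    incremental comparison (ICER, net monetary benefit, dominance),
    deterministic and probabilistic sensitivity analysis with CEAC output,
    and generators for the synthetic external inputs (life table, age-utility
    curve, heart-failure incidence curve, parameter distributions) the
    analysis needs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
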
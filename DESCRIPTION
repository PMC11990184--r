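Package: plantupf
Title: Plant-Based Diet Indices and Ultra-Processed Food Intake from 24-Hour Dietary Recalls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for relating ultra-processed food (UPF) consumption to
    plant-based diet quality in national dietary surveys. Computes each
    participant's share of daily energy from NOVA group 4 foods (with
    disaggregation of handmade mixed dishes into ingredients), scores the
    overall, healthful, and unhealthful plant-based diet indices (PDI, hPDI,
    uPDI) by population-specific quintile scoring of 18 food groups, derives
    an energy-misreporting covariate (energy intake to basal metabolic rate
    ratio), and fits survey-weighted descriptive tables, linear regressions,
    component-score decompositions, and moderation models with
    replicate-weight (delete-a-group jackknife) variance estimation. A
    synthetic dietary-survey generator with known ground truth exercises
    every stage end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
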
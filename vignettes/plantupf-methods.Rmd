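---
title: "Scoring plant-based diet quality against ultra-processed food intake: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring plant-based diet quality against ultra-processed food intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantupf)
```

## The analysis this package implements

Two participant-level quantities are derived from a single 24 h dietary
recall and then related by survey-weighted regression:

1. **UPF energy share** — the percentage of daily energy from NOVA group 4
   (ultra-processed) foods. Handmade mixed dishes are first disaggregated
   into their recipe ingredients so that each ingredient carries its own
   NOVA group; the share is then `100 · E(NOVA4) / E(total)` per person.
2. **Plant-based diet indices** — PDI, hPDI and uPDI, each the sum of 18
   component scores. Daily servings are accumulated into 18 analysis food
   groups; each group's serving distribution is cut at its survey-weighted
   20/40/60/80th percentiles; the quintile is scored forward (score =
   quintile) or reverse (score = 6 − quintile) depending on the index and
   the group's health class; the 18 scores are summed, so each index ranges
   18–90.

The health classes are fixed by the scheme: healthy plant (whole grains,
fruits, vegetables, nuts and seeds, legumes, unsaturated plant
oils/spreads, tea and coffee), unhealthy plant (refined grains, fruit
juices, saturated plant fats, sugars and syrups, miscellaneous plant
products) and animal (animal fats, dairy, eggs, fish and seafood, meat,
miscellaneous animal products). PDI scores all twelve plant groups forward
and the six animal groups reverse; hPDI scores only the healthy plant
groups forward; uPDI scores only the unhealthy plant groups forward.
Animal groups are reverse-scored under all three indices, which is why
their component regressors coincide across indices and are reported as one
combined term.

Three structural identities follow directly and are enforced by tests: for
every plant group the hPDI and uPDI component scores sum to 6 (so
component regression coefficients flip sign exactly between the two
indices); for unhealthy plant groups the PDI and uPDI components are
identical; for animal groups all three are identical.

## The 23-to-18 group collapse

The source apportionment distinguishes 23 groups; the analysis uses 18.
The shipped default collapses the three dairy fat strata into one dairy
group and the four red-meat/poultry strata into one meat group, mapping
every other group to itself. Which strata beyond dairy and meat might
differ in other source databases is not fixed by the scheme; the collapse
map is therefore part of the YAML scheme configuration
(`write_group_scheme()` / `read_group_scheme()`) and the default is an
explicit, documented assumption. Collapsing always conserves total
servings per food, which the loader verifies.

## Tie rules, zero inflation and degenerate quintiles

On a single recall day many food groups (legumes, fish, eggs, fruit
juices) have a majority of non-consumers, so several quintile cutpoints
coincide at zero. Two conventions make scoring deterministic:

- The weighted quantile is the **left-continuous inverse of the weighted
  empirical distribution function**, `Q(p) = inf{x : F_w(x) ≥ p}` — chosen
  because it is reproducible and directly checkable against a brute-force
  rank oracle.
- Quintile membership uses half-open intervals with **ties falling low**:
  quintile = `1 + #(value > c_k)`. All values tied at a collapsed boundary
  share the lowest applicable quintile, so a non-consumer of a healthy
  group scores 1 under forward scoring ("lowest consumption"), never an
  arbitrary middle quintile.

Degenerate cutpoints are reported as a log message rather than an R
warning, because they are the expected behaviour of valid zero-inflated
data, not an error condition. Quintiles are computed on the
survey-weighted distribution by default (`use_weights = FALSE` disables
this), consistent with weighting every other analysis step; both modes
exist because scoring conventions differ between surveys.

## Recipe disaggregation and energy accounting

Energy is carried internally in kJ (1 kcal = 4.184 kJ) and reported in
kcal. For a recipe item the reported recall energy is treated as
authoritative: ingredient energies are first computed from ingredient
energy densities and the grams implied by the recipe weight fractions,
then proportionally rescaled so they sum to the reported energy. This
keeps every participant's total grams and energy identical before and
after disaggregation — an invariant the tests assert — at the cost of
letting ingredient-level energies deviate from their nominal densities
when the recorded recipe energy does. Whether the original survey
processing rescaled in this way is unknowable from the outside; the rule
is this package's own convention. Recipes are resolved exactly one level
deep, and the loader rejects nested recipes, mirroring pre-flattened
recipe files. A recall item without a NOVA assignment is a hard error
rather than a silent default, since silent misclassification would bias
the exposure.

## Energy misreporting

The misreporting covariate is the ratio of reported energy intake to
predicted basal metabolic rate, both in MJ/day. BMR comes from
Schofield-type sex- and age-band-specific linear functions of body weight;
the coefficient table is configurable (YAML) with the Schofield adult set
as default, and the youngest adult band includes age 30 (so a 30-year-old
man of 70 kg gets 0.063·70 + 2.896 = 7.306 MJ/day). Misreporters are never
excluded — the ratio enters model 2 as a continuous covariate — and
participants missing body weight receive the weighted population mean
ratio so the adjusted models keep the full cohort.

## Survey variance machinery

No design-based survey package is assumed; the replicate-weight machinery
is implemented directly because its definition is part of the analysis
contract:

- Point estimates (means, proportions, weighted least squares
  coefficients) use the person weights.
- Variances use `c · Σ_r (θ̂_r − θ̂)²` over the R replicate-weight
  re-estimates, with `c = (R−1)/R` by default — the generic delete-a-group
  jackknife form, configurable for other replication schemes.
- Confidence intervals and p-values use the standard normal reference, the
  usual large-sample survey practice; replicate counts make jackknife t
  degrees of freedom ambiguous.
- The categorical homogeneity test is a weighted Pearson χ² on weighted
  counts rescaled to the sample size; a first-order Rao–Scott correction
  (statistic divided by the mean replicate-estimated design effect of the
  cell proportions) is available behind a flag but off by default.
- p-trend for continuous rows regresses the row variable on the quintile
  number 1–5 as a continuous regressor — the simplest reading of a linear
  trend across ordered groups.

Point estimates are verified against an independent normal-equations
oracle to 1e-8, replicate SEs against hand arithmetic, and the χ² against
hand expected-count arithmetic. The regressions take UPF % energy as the
outcome and each index as the exposure (the direction of the methods they
mirror); `transpose_regression = TRUE` swaps them for sensitivity
analysis. No multiple-testing adjustment is applied anywhere (α = 0.05).

## The synthetic generator

`sim_config()` defaults are the study conditions: n = 2000 participants,
energy ~ Normal(2001, 600) kcal/day truncated at 600, target UPF share
39.1% with residual SD 8, age ~ Normal(49.4, 17.3) truncated to 19–90,
49.4% female, R = 30 replicate groups, and per-group zero-inflation
probabilities between 0.03 (vegetables) and 0.70 (legumes) chosen as
plausible single-recall non-consumption rates. Foods are assigned
round-robin to the 18 groups with group-typical energy densities; two
handmade recipes (built from NOVA 1–3 ingredients) and two
zero-apportionment staple beverages (mineral water, NOVA 1; a cola soft
drink, NOVA 4) are always present.

The key design choice is how the index–UPF association is induced. A
latent diet-quality axis `z ~ N(0,1)` scales serving *amounts* (healthy
groups load positively, unhealthy negatively) while consumption
probabilities stay fixed at the configured zero-inflation rates. The
generator then scores each participant's indices **through the package's
own pipeline** and sets the target UPF share to

```
target + Σ_s slope_s · (index_s − weighted mean) + effect · I(male) · (index − mean) + ε
```

clipped to [0, 100], finally allocating each participant's reported energy
between NOVA-4 and non-NOVA-4 items to realise that share exactly (the
staples guarantee both pools are non-empty, and recipes never straddle the
UPF boundary). Because the downstream re-analysis recomputes exactly the
same indices, the configured slopes are the exact expected regression
coefficients — no rejection sampling, no attenuation through the quintile
nonlinearity — which is what makes sharp recovery tests possible: over 20
seeded datasets of n = 2000 the model-2 coefficient mean must sit within
3 Monte-Carlo standard errors of the configured slope (0, 0.8, and a 0.4
sex-interaction are exercised).

What the generator does **not** emulate: day-to-day intake variation
(there is only one recall), correlated food choices within meals, the real
surveys' stratified-cluster geography (weights are i.i.d. lognormal),
measurement error in grams, or the empirical joint distribution of
sociodemographics and diet (gradients are off by default and mild when
enabled). Passing tests therefore demonstrate that the *pipeline*
implements the scoring and inference correctly under known ground truth —
not that any particular real-world coefficient is reproduced. The printed
coefficients of the original study are estimated on access-restricted
microdata and are data-dependent; this package reproduces the procedure,
not those numbers.

## Problem sizes and determinism

The shipped workflow and tests use n = 2000 for distribution-level checks
and Monte-Carlo recovery (20 datasets per scenario), n = 50–400 for
oracle and property tests — sizes at which the Monte-Carlo bands are tight
enough to detect implementation bias while the whole suite stays fast.
Every random draw descends from a single integer seed; datasets, result
tables and manifests are byte-identical across reruns with the same seed
(manifests deliberately contain no timestamps).

## Known limitations

- The 23→18 collapse map beyond dairy and meat is an assumption, not a
  reproduction of any specific source database.
- The replicate-variance form is the generic delete-a-group jackknife;
  surveys with bootstrap or BRR weights need a different `variance_scale`.
- The Rao–Scott correction implemented is first-order only.
- The BMR equations are configurable but default to Schofield; analyses
  standardised on Henry equations should supply them via YAML.
- Component-association models fit one component at a time (plus
  covariates); they are not a joint decomposition.
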
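#!/usr/bin/env Rscript
# Stage 1: generate the synthetic dietary survey the analysis runs on.
#
# The generator emulates the marginal structure of a national adult
# nutrition survey: ~2001 kcal/day energy intake, a mean ultra-processed
# food (UPF) energy share of 39.1%, zero-inflated single-recall servings in
# 18 food groups, and person + 30 delete-a-group jackknife replicate
# weights. One association is imposed as ground truth: 0.8 percentage
# points of UPF energy per uPDI point, the magnitude reported for the
# unhealthful plant-based diet index in the study this pipeline mirrors.

library(plantupf)

cfg <- sim_config(n_participants = 2000, seed = 20260922, slope_updi = 0.8)
study <- simulate_study(cfg)
dir <- "results/dataset"
write_dataset(study, dir)

gt <- study$population$ground_truth$per_participant
cat("synthetic survey written to", dir, "\n")
cat(sprintf("  participants: %d, recall items: %d, foods: %d (+2 recipes, +2 staples)\n",
            nrow(study$population$participants),
            nrow(study$population$recall), cfg$n_foods))
cat(sprintf("  ground-truth uPDI slope: %.2f %% energy per index point\n",
            cfg$slope_updi))
cat(sprintf("  generated index ranges: PDI %d-%d, hPDI %d-%d, uPDI %d-%d\n",
            min(gt$pdi), max(gt$pdi), min(gt$hpdi), max(gt$hpdi),
            min(gt$updi), max(gt$updi)))
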
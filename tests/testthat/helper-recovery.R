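# Shared end-to-end fit used by the slope- and interaction-recovery checks:
# generate a full synthetic survey, push it through every pipeline stage and
# return the requested model-2 coefficient.
recover_model2_beta <- function(seed, slope_updi = 0, interaction = NULL,
                                term = "updi", n = 2000) {
  cfg <- sim_config(n_participants = n, seed = seed, slope_updi = slope_updi,
                    interaction = interaction)
  st <- simulate_study(cfg)
  pop <- st$population
  flat <- disaggregate(pop$recall, st$bundle)
  cl <- classify_nova(flat, st$bundle)
  upf <- upf_energy_share(cl, quiet = TRUE)
  prof <- servings_profile(cl, collapse_groups(st$bundle$apportionment),
                           st$bundle$scheme)
  sc <- pdi_scores(prof, st$bundle$scheme, design = pop$design, quiet = TRUE)
  mis <- misreporting_scores(upf[, c("participant_id", "total_energy_kj")],
                             pop$participants, design = pop$design,
                             quiet = TRUE)
  tab <- Reduce(function(a, b) merge(a, b, by = "participant_id"),
                list(pop$participants, upf, sc$indices, mis))
  rhs <- "updi + age + sex + education + country_of_birth + rurality + area_disadvantage + ei_bmr_ratio"
  if (!is.null(interaction)) rhs <- paste0(rhs, " + updi:sex")
  f <- stats::as.formula(paste("pct_energy_upf ~", rhs))
  fit <- weighted_linear_fit(f, tab, pop$design, model_tag = "model2")
  fit$beta[fit$term == term]
}
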
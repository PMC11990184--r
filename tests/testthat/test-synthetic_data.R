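test_that("generator config enforces its invariants", {
  expect_error(sim_config(n_participants = 10), ">= 50")
  expect_error(sim_config(n_foods = 10), ">= 18")
  expect_error(sim_config(zero_inflation = c(legumes = 1.4)), "\\[0, 1\\]")
  expect_error(sim_config(zero_inflation = c(unicorn = 0.5)), "unicorn")
  cfg <- sim_config()
  expect_s3_class(cfg, "plantupf_simconfig")
  expect_equal(cfg$n_replicates, 30L)
})

test_that("generated reference bundles are valid, deterministic, and cover all groups", {
  cfg <- sim_config(n_participants = 60, seed = 4)
  expect_no_warning(b1 <- generate_reference_bundle(cfg))
  b2 <- generate_reference_bundle(cfg)
  expect_identical(b1$composition, b2$composition)
  expect_identical(b1$apportionment, b2$apportionment)

  # one food per analysis group at the minimum food count
  cfg18 <- sim_config(n_participants = 60, seed = 4, n_foods = 18)
  b18 <- generate_reference_bundle(cfg18)
  collapsed <- collapse_groups(b18$apportionment, b18$scheme)
  regular <- collapsed[collapsed$servings_per_100g > 0 &
                         !grepl("^2", collapsed$food_code), ]
  per_group <- table(regular$analysis_group)
  expect_length(per_group, 18L)
  expect_true(all(per_group == 1L))
  expect_gte(sum(b18$composition$is_recipe), 1L)  # handmade dishes present
})

test_that("population generation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_participants = 80, seed = 9)
  st1 <- simulate_study(cfg)
  st2 <- simulate_study(cfg)
  expect_identical(st1$population$recall, st2$population$recall)
  expect_identical(st1$population$participants, st2$population$participants)
  expect_identical(st1$population$design$replicate_weights,
                   st2$population$design$replicate_weights)
  expect_identical(st1$population$ground_truth$per_participant,
                   st2$population$ground_truth$per_participant)
})

test_that("per-group zero-inflation probabilities are honoured within binomial error", {
  cfg <- sim_config(n_participants = 1500, seed = 33)
  st <- simulate_study(cfg)
  flat <- disaggregate(st$population$recall, st$bundle)
  prof <- servings_profile(flat, collapse_groups(st$bundle$apportionment),
                           st$bundle$scheme)
  n <- nrow(prof)
  for (g in names(cfg$zero_inflation)) {
    p <- cfg$zero_inflation[[g]]
    observed <- mean(prof[[g]] == 0)
    tol <- 4 * sqrt(p * (1 - p) / n) + 1e-9
    expect_lt(abs(observed - p), max(tol, 0.015))
  }
})

test_that("the weighted mean UPF share hits its target within sampling error", {
  cfg <- sim_config(n_participants = 2000, seed = 14)
  st <- simulate_study(cfg)
  res <- run_pipeline(st, quiet = TRUE, moderation_index = NULL)
  est <- weighted_estimate(res$analysis_table$pct_energy_upf,
                           st$population$design,
                           res$analysis_table$participant_id)
  expect_lt(abs(est$estimate - 39.1), 3 * est$se + 1e-9)
  # energy centred near the configured intake
  expect_lt(abs(mean(res$analysis_table$total_energy_kcal) - 2001), 60)
})

test_that("every generated participant passes the cohort filter", {
  st <- simulate_study(sim_config(n_participants = 100, seed = 3))
  out <- filter_cohort(st$population$participants, quiet = TRUE)
  expect_equal(nrow(out$included), 100L)
  expect_true(all(st$population$participants$age >= 19))
})

test_that("datasets round-trip through the directory format", {
  cfg <- sim_config(n_participants = 80, seed = 12, slope_updi = 0.4)
  st <- simulate_study(cfg)
  dir <- withr::local_tempdir()
  write_dataset(st, dir)
  back <- read_dataset(dir, quiet = TRUE)
  expect_equal(back$population$participants$participant_id,
               st$population$participants$participant_id)
  expect_equal(back$population$design$person_weight,
               st$population$design$person_weight, tolerance = 1e-12)
  expect_equal(back$bundle$apportionment, st$bundle$apportionment)
  expect_equal(back$population$ground_truth$slopes$updi, 0.4)

  res_mem <- run_pipeline(st, quiet = TRUE, moderation_index = NULL)
  res_dir <- run_pipeline(dir, quiet = TRUE, moderation_index = NULL)
  expect_equal(res_dir$scores$indices, res_mem$scores$indices)
  expect_equal(res_dir$table2$beta, res_mem$table2$beta, tolerance = 1e-9)
})

test_that("with all slopes zero the index-UPF correlation is noise", {
  cors <- vapply(1:6, function(s) {
    st <- simulate_study(sim_config(n_participants = 400, seed = 100 + s))
    gt <- st$population$ground_truth$per_participant
    cor(gt$target_upf_share, gt$updi)
  }, numeric(1L))
  # each |r| should look like sampling noise around 0 at n = 400
  expect_lt(max(abs(cors)), 0.15)
  expect_lt(abs(mean(cors)), 0.06)
})
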
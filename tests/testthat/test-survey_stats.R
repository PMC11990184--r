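test_that("cohort filter counts sequential exclusions like a flow diagram", {
  roster <- data.frame(
    participant_id = sprintf("p%03d", 1:100),
    age = c(rep(15, 10), rep(40, 90)),
    pregnant = FALSE, breastfeeding = FALSE, missing_upf = FALSE)
  roster$pregnant[c(3, 11, 12)] <- TRUE   # one pregnant minor: counted under age
  out <- filter_cohort(roster, quiet = TRUE)
  expect_equal(nrow(out$included), 88L)
  expect_equal(out$ledger[["under19"]], 10L)
  expect_equal(out$ledger[["pregnant"]], 2L)
  expect_equal(out$ledger[["included"]], 88L)

  clean <- roster
  clean$age <- 30
  clean$pregnant <- FALSE
  out2 <- filter_cohort(clean, quiet = TRUE)
  expect_equal(out2$included, clean)
  expect_equal(sum(out2$ledger[c("under19", "pregnant", "breastfeeding",
                                 "missing_upf")]), 0L)

  # manual tally on a mixed roster
  mixed <- data.frame(
    participant_id = sprintf("q%02d", 1:12),
    age = c(17, 18, 25, 25, 25, 25, 40, 40, 40, 70, 70, 70),
    pregnant = c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE,
                 FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    breastfeeding = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
                      FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    missing_upf = c(rep(FALSE, 10), TRUE, TRUE))
  out3 <- filter_cohort(mixed, quiet = TRUE)
  expect_equal(as.integer(out3$ledger),
               c(12L, 2L, 1L, 1L, 2L, 6L))
})

test_that("weighted estimates match hand arithmetic including replicate SE", {
  ids <- c("a", "b", "c", "d")
  v <- c(10, 20, 30, 40)
  pw <- c(1, 2, 1, 1)
  repw <- cbind(c(0, 2.5, 1.25, 1.25),
                c(1.25, 0, 1.25, 1.25),
                c(1.25, 2.5, 0, 1.25))
  design <- survey_design(ids, pw, repw, variance_scale = 2 / 3)
  est <- weighted_estimate(v, design, ids, statistic = "mean")
  theta <- sum(pw * v) / sum(pw)
  reps <- apply(repw, 2L, function(w) sum(w * v) / sum(w))
  expect_equal(est$estimate, theta)
  expect_equal(est$se, sqrt(2 / 3 * sum((reps - theta)^2)))

  # equal weights reduce to the unweighted mean; SE 0 when replicates agree
  eqd <- survey_design(ids, rep(1, 4), cbind(rep(1, 4), rep(2, 4)))
  est2 <- weighted_estimate(v, eqd, ids, statistic = "mean")
  expect_equal(est2$estimate, mean(v))
  expect_equal(est2$se, 0)

  prop <- weighted_estimate(c("x", "x", "y", "y"), design, ids,
                            statistic = "proportion", level = "x")
  expect_equal(prop$estimate, (1 + 2) / 5)
})

test_that("weighted least squares matches the normal-equations oracle to 1e-8", {
  set.seed(31)
  n <- 20L
  dat <- data.frame(participant_id = sprintf("p%02d", 1:n),
                    x1 = rnorm(n), x2 = runif(n))
  dat$y <- 1.5 + 2 * dat$x1 - 0.7 * dat$x2 + rnorm(n, 0, 0.3)
  for (wts in list(rep(1, n), runif(n, 0.2, 3))) {
    design <- make_design(dat$participant_id, person_weight = wts)
    fit <- weighted_linear_fit(y ~ x1 + x2, dat, design)
    X <- cbind(1, dat$x1, dat$x2)
    expect_equal(fit$beta, oracle_wls(X, dat$y, wts), tolerance = 1e-8)
    expect_true(all(fit$ci_low <= fit$beta & fit$beta <= fit$ci_high))
  }
})

test_that("an exact linear relationship is recovered with zero replicate variance", {
  n <- 12L
  dat <- data.frame(participant_id = sprintf("p%02d", 1:n), x = 1:n)
  dat$y <- 2 * dat$x
  design <- make_design(dat$participant_id, person_weight = runif(n, 0.5, 2))
  fit <- weighted_linear_fit(y ~ x, dat, design)
  expect_equal(fit$beta[fit$term == "x"], 2, tolerance = 1e-12)
  expect_equal(fit$se[fit$term == "x"], 0, tolerance = 1e-10)
  expect_equal(fit$p_value[fit$term == "x"], 0)
})

test_that("duplicating a participant while halving its weights changes nothing", {
  set.seed(77)
  n <- 15L
  dat <- data.frame(participant_id = sprintf("p%02d", 1:n), x = rnorm(n))
  dat$y <- 1 + 0.8 * dat$x + rnorm(n, 0, 0.2)
  pw <- runif(n, 0.5, 2)
  base <- make_design(dat$participant_id, person_weight = pw, R = 3, seed = 7)

  dup <- rbind(dat, transform(dat[n, ], participant_id = "p_dup"))
  pw2 <- c(pw[-n], pw[n] / 2, pw[n] / 2)
  repw2 <- rbind(base$replicate_weights[-n, , drop = FALSE],
                 base$replicate_weights[n, , drop = FALSE] / 2,
                 base$replicate_weights[n, , drop = FALSE] / 2)
  design2 <- survey_design(dup$participant_id, pw2, repw2,
                           variance_scale = base$variance_scale)
  fit1 <- weighted_linear_fit(y ~ x, dat, base)
  fit2 <- weighted_linear_fit(y ~ x, dup, design2)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-12)
  expect_equal(fit1$se, fit2$se, tolerance = 1e-12)
})

test_that("rank-deficient design matrices are rejected naming the collinear term", {
  n <- 10L
  dat <- data.frame(participant_id = sprintf("p%02d", 1:n), x = rnorm(n))
  dat$z <- 2 * dat$x
  dat$y <- rnorm(n)
  design <- make_design(dat$participant_id)
  expect_error(weighted_linear_fit(y ~ x + z, dat, design), "collinear.*z")
})

test_that("the weighted Pearson chi-squared reproduces hand expected-count arithmetic", {
  x <- rep(c("r1", "r1", "r2", "r2"), c(10, 20, 20, 10))
  g <- rep(c("c1", "c2", "c1", "c2"), c(10, 20, 20, 10))
  out <- weighted_chisq(x, g)
  expect_equal(out$statistic, 20 / 3, tolerance = 1e-9)  # 6.667
  expect_equal(out$df, 1L)
  expect_equal(out$p_value, pchisq(20 / 3, 1, lower.tail = FALSE))

  # perfectly homogeneous table
  x2 <- rep(c("r1", "r2"), each = 20)
  g2 <- rep(rep(c("c1", "c2"), each = 10), 2)
  expect_equal(weighted_chisq(x2, g2)$statistic, 0)

  # doubling all weights leaves the statistic unchanged
  w <- rep(2, length(x))
  expect_equal(weighted_chisq(x, g, w = w)$statistic, 20 / 3,
               tolerance = 1e-9)
})

test_that("adding a constant-covariate model leaves index estimates unchanged", {
  st <- simulate_study(sim_config(n_participants = 200, seed = 5,
                                  slope_updi = 0.5))
  res <- run_pipeline(st, quiet = TRUE, moderation_index = NULL)
  tab <- res$analysis_table
  tab$ei_bmr_ratio <- 1.4  # constant misreporting covariate
  fits <- fit_index_models(tab, st$population$design)
  t2 <- table2_shape(fits)
  for (idx in c("pdi", "hpdi", "updi")) {
    b1 <- t2$beta[t2$index == idx & t2$model_tag == "model1"]
    b2 <- t2$beta[t2$index == idx & t2$model_tag == "model2"]
    expect_equal(b1, b2, tolerance = 1e-10)
  }
})

test_that("component-score associations mirror the scoring antisymmetries", {
  st <- simulate_study(sim_config(n_participants = 250, seed = 13,
                                  slope_updi = 0.6))
  res <- run_pipeline(st, quiet = TRUE, moderation_index = NULL)
  t3 <- res$table3
  scheme <- default_group_scheme()
  healthy <- names(scheme$health_class)[scheme$health_class == "healthy_plant"]
  unhealthy <- names(scheme$health_class)[scheme$health_class == "unhealthy_plant"]
  for (g in c(healthy, unhealthy)) {
    b_h <- t3$beta[t3$index == "hpdi" & t3$component == g]
    b_u <- t3$beta[t3$index == "updi" & t3$component == g]
    expect_equal(b_h, -b_u, tolerance = 1e-10)
  }
  for (g in unhealthy) {
    expect_equal(t3$beta[t3$index == "pdi" & t3$component == g],
                 t3$beta[t3$index == "updi" & t3$component == g],
                 tolerance = 1e-10)
  }
  expect_true("animal_combined" %in% t3$component)
})

test_that("descriptive quintile tables report weighted cells and sane trend tests", {
  st <- simulate_study(sim_config(n_participants = 300, seed = 23))
  res <- run_pipeline(st, quiet = TRUE, moderation_index = NULL)
  tab <- res$analysis_table
  design <- st$population$design
  t1 <- quintile_table(tab, design, index = "updi")
  # categorical percentages sum to 100 within each variable x quintile
  cat_cells <- t1$cells[!is.na(t1$cells$level), ]
  sums <- tapply(cat_cells$estimate,
                 list(cat_cells$variable, cat_cells$quintile), sum)
  expect_equal(as.numeric(sums), rep(100, length(sums)), tolerance = 1e-9)
  expect_true(all(t1$trend$p_trend >= 0 & t1$trend$p_trend <= 1))
  expect_setequal(unique(t1$trend$test_kind), c("linear", "chi2"))

  # a row variable constant across quintiles has a flat trend (p = 1)
  tab2 <- tab
  tab2$age <- 50
  t1c <- quintile_table(tab2, design, index = "updi")
  tr_age <- weighted_linear_fit(age ~ quintile_number,
                                cbind(tab2, quintile_number = t1c$quintile),
                                design)
  expect_equal(tr_age$beta[tr_age$term == "quintile_number"], 0,
               tolerance = 1e-10)
  age_cells <- t1c$cells[t1c$cells$variable == "age", ]
  expect_equal(age_cells$estimate, rep(50, 5))
})

test_that("swapping the reference level of a binary moderator flips the interaction beta", {
  set.seed(55)
  n <- 120L
  dat <- data.frame(participant_id = sprintf("p%03d", 1:n),
                    x = rnorm(n), m = sample(c("female", "male"), n, TRUE))
  dat$y <- 1 + 0.5 * dat$x + 0.4 * dat$x * (dat$m == "male") + rnorm(n, 0, 0.1)
  design <- make_design(dat$participant_id, R = 6)
  dat$mf <- factor(dat$m, levels = c("female", "male"))
  fit1 <- weighted_linear_fit(y ~ x * mf, dat, design)
  dat$mf <- factor(dat$m, levels = c("male", "female"))
  fit2 <- weighted_linear_fit(y ~ x * mf, dat, design)
  b1 <- fit1$beta[grepl("^x:", fit1$term)]
  b2 <- fit2$beta[grepl("^x:", fit2$term)]
  expect_equal(b1, -b2, tolerance = 1e-10)
})

test_that("moderation models report interaction terms and subgroup fits", {
  st <- simulate_study(sim_config(n_participants = 300, seed = 29,
                                  slope_updi = 0.6))
  res <- run_pipeline(st, quiet = TRUE, moderation_index = "updi")
  mods <- res$moderation
  expect_setequal(unique(mods$interactions$moderator),
                  c("age", "sex", "education"))
  expect_true(all(c("updi:age", "updi:sexmale") %in% mods$interactions$term))
  expect_true(all(mods$interactions$ci_low <= mods$interactions$beta))
  expect_equal(sum(mods$subgroups$moderator == "sex"), 2L)
  expect_equal(sum(mods$subgroups$moderator == "education"), 3L)
})
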
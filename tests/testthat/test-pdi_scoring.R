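scheme <- default_group_scheme()
bundle <- load_fixture_bundle()
collapsed <- collapse_groups(bundle$apportionment, scheme)

test_that("servings profiles sum grams x rate with zero fill for unconsumed groups", {
  items <- data.frame(
    participant_id = c("A", "A", "A", "A", "A", "B"),
    food_code = c("10000003", "10000003", "10000002", "10000009", "10000001",
                  "10000002"),
    grams = c(150, 50, 100, 200, 40, 80))
  prof <- servings_profile(items, collapsed, scheme)
  a <- prof[prof$participant_id == "A", ]
  # hand-summed oracle: 150g + 50g broccoli at 1.0/100 g
  expect_equal(a$vegetables, 2.0)
  expect_equal(a$fruits, 0.8)
  expect_equal(a$dairy, 200 / 100 * (0.25 + 0.15))
  expect_equal(a$whole_grains, 40 / 100 * 1.2)
  expect_equal(a$legumes, 0)           # zero fill
  expect_equal(sum(a[, -1] > 0), 4L)
  expect_equal(ncol(prof), 19L)        # id + 18 groups

  # brute-force summation oracle over every item and group
  oracle <- sapply(scheme$analysis_groups, function(g) {
    s <- 0
    for (i in which(items$participant_id == "A")) {
      rows <- collapsed[collapsed$food_code == items$food_code[i] &
                          collapsed$analysis_group == g, ]
      if (nrow(rows)) s <- s + items$grams[i] / 100 * sum(rows$servings_per_100g)
    }
    s
  })
  expect_equal(as.numeric(a[, scheme$analysis_groups]), as.numeric(oracle))

  expect_error(servings_profile(
    data.frame(participant_id = "A", food_code = "99999999", grams = 1),
    collapsed, scheme), "99999999")
})

test_that("weighted quantiles are the left-continuous inverse of the weighted ECDF", {
  # equal weights, servings 1..10: cutpoints 2/4/6/8, two per quintile
  cp <- weighted_quantile(1:10, probs = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(cp, c(2, 4, 6, 8))
  q <- assign_quintile(1:10, cp)
  expect_equal(as.integer(table(q)), rep(2L, 5L))

  # degenerate distribution
  expect_equal(weighted_quantile(rep(0, 8), probs = c(0.2, 0.4, 0.6, 0.8)),
               rep(0, 4))

  # scale invariance in the weights
  set.seed(5)
  x <- rnorm(30)
  w <- runif(30, 0.2, 3)
  expect_equal(weighted_quantile(x, w, probs = c(0.2, 0.5, 0.8)),
               weighted_quantile(x, 2 * w, probs = c(0.2, 0.5, 0.8)))
})

test_that("quintile assignment matches the brute-force weighted-rank oracle", {
  set.seed(99)
  for (rep in 1:10) {
    x <- round(rexp(50), 2)
    x[sample(50, 15)] <- 0  # zero inflation with heavy ties
    w <- runif(50, 0.5, 2)
    cp <- weighted_quantile(x, w, probs = c(0.2, 0.4, 0.6, 0.8))
    expect_equal(assign_quintile(x, cp), oracle_quintile(x, x, w))
  }
  # boundary rules
  cp <- c(1, 2, 3, 4)
  expect_equal(assign_quintile(c(0.5, 2, 4.5), cp), c(1L, 2L, 5L))
})

test_that("degenerate cutpoints send all tied values to the lowest applicable quintile", {
  x <- c(rep(0, 12), 1, 2, 3)  # majority non-consumers
  cp <- weighted_quantile(x, probs = c(0.2, 0.4, 0.6, 0.8))
  expect_equal(cp[1:3], c(0, 0, 0))
  q <- assign_quintile(x, cp)
  expect_true(all(q[x == 0] == 1L))
  # forward scoring of a healthy group then gives non-consumers a 1
  expect_equal(unique(score_component(q[x == 0], "healthy_plant", "hpdi")), 1L)
})

test_that("component scoring follows the forward/reverse rules of the three indices", {
  # plant group in the top quintile scores 5 on the overall index
  expect_equal(score_component(5L, "healthy_plant", "pdi"), 5L)
  expect_equal(score_component(5L, "unhealthy_plant", "pdi"), 5L)
  # animal group in the lowest consumption quintile scores 5 under all three
  for (idx in c("pdi", "hpdi", "updi")) {
    expect_equal(score_component(1L, "animal", idx), 5L)
  }
  expect_equal(score_component(5L, "healthy_plant", "updi"), 1L)
  expect_equal(score_component(3L, "unhealthy_plant", "hpdi"), 3L)

  # cross-index identities for every quintile and class
  for (q in 1:5) {
    expect_equal(score_component(q, "healthy_plant", "hpdi") +
                   score_component(q, "healthy_plant", "updi"), 6L)
    expect_equal(score_component(q, "healthy_plant", "pdi"),
                 score_component(q, "healthy_plant", "hpdi"))
    expect_equal(score_component(q, "unhealthy_plant", "pdi"),
                 score_component(q, "unhealthy_plant", "updi"))
    expect_equal(score_component(q, "unhealthy_plant", "hpdi"),
                 6L - score_component(q, "unhealthy_plant", "updi"))
    expect_equal(score_component(q, "animal", "pdi"),
                 score_component(q, "animal", "hpdi"))
    expect_equal(score_component(q, "animal", "pdi"),
                 score_component(q, "animal", "updi"))
  }
})

test_that("index sums hit the printed bounds and match a naive accumulation oracle", {
  groups <- scheme$analysis_groups
  hc <- scheme$health_class[groups]
  make_components <- function(quintiles) {
    data.frame(participant_id = "A", analysis_group = groups,
               health_class = hc, quintile = quintiles,
               score_pdi = score_component(quintiles, hc, "pdi"),
               score_hpdi = score_component(quintiles, hc, "hpdi"),
               score_updi = score_component(quintiles, hc, "updi"))
  }
  # plant groups top quintile + animal bottom -> every PDI component at 5
  top <- make_components(ifelse(hc == "animal", 1L, 5L))
  expect_equal(compute_indices(top)$pdi, 90L)
  bottom <- make_components(ifelse(hc == "animal", 5L, 1L))
  expect_equal(compute_indices(bottom)$pdi, 18L)

  set.seed(3)
  rnd <- make_components(sample(1:5, 18, replace = TRUE))
  idx <- compute_indices(rnd)
  expect_equal(idx$pdi, sum(rnd$score_pdi))
  expect_equal(idx$hpdi, sum(rnd$score_hpdi))
  expect_equal(idx$updi, sum(rnd$score_updi))

  expect_error(compute_indices(rnd[-1L, ]), "exactly 18")
})

test_that("scored indices are order invariant and stay within 18..90", {
  cfg <- sim_config(n_participants = 120, seed = 21)
  st <- simulate_study(cfg)
  flat <- disaggregate(st$population$recall, st$bundle)
  prof <- servings_profile(flat, collapse_groups(st$bundle$apportionment),
                           st$bundle$scheme)
  sc <- pdi_scores(prof, st$bundle$scheme, design = st$population$design,
                   quiet = TRUE)
  expect_true(all(sc$indices$pdi >= 18 & sc$indices$pdi <= 90))
  perm <- prof[sample(nrow(prof)), ]
  sc2 <- pdi_scores(perm, st$bundle$scheme, design = st$population$design,
                    quiet = TRUE)
  m <- match(sc$indices$participant_id, sc2$indices$participant_id)
  expect_equal(sc$indices$pdi, sc2$indices$pdi[m])
  expect_equal(sc$indices$updi, sc2$indices$updi[m])
})

test_that("with equal weights and distinct servings each quintile holds n/5 participants", {
  set.seed(17)
  x <- sample(seq(0.01, 10, by = 0.01), 100)
  cp <- weighted_quantile(x, probs = c(0.2, 0.4, 0.6, 0.8))
  q <- assign_quintile(x, cp)
  expect_true(all(abs(table(q) - 20) <= 1))
  expect_equal(assign_quintile(x, cp), oracle_quintile(x, x))
})
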
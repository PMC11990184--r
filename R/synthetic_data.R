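# Per-group defaults for the generator: probability of zero servings on a
# single recall day, mean servings/day among consumers, loading of the
# latent diet-quality axis on consumption amounts, and a typical energy
# density (kJ/100 g) for foods of the group.
sim_group_defaults <- function() {
  data.frame(
    analysis_group = c("whole_grains", "fruits", "vegetables", "nuts_seeds",
                       "legumes", "unsaturated_oils", "tea_coffee",
                       "refined_grains", "fruit_juices",
                       "saturated_plant_fats", "sugars_syrups", "misc_plant",
                       "animal_fats", "dairy", "eggs", "fish_seafood",
                       "meat", "misc_animal"),
    zero_inflation = c(0.25, 0.15, 0.03, 0.55, 0.70, 0.30, 0.15,
                       0.05, 0.60, 0.50, 0.30, 0.40,
                       0.45, 0.10, 0.55, 0.65, 0.15, 0.40),
    mean_servings = c(1.5, 1.5, 2.5, 1.0, 0.8, 1.5, 2.0,
                      2.5, 1.0, 0.8, 1.5, 0.8,
                      0.8, 1.5, 0.8, 0.8, 1.5, 0.8),
    axis_loading = c(0.30, 0.35, 0.35, 0.35, 0.30, 0.20, 0.10,
                     -0.30, -0.20, -0.25, -0.35, -0.20,
                     -0.15, -0.05, -0.05, 0.10, -0.15, -0.10),
    energy_density = c(1100, 250, 120, 2500, 400, 3300, 30,
                       1500, 180, 3200, 1600, 800,
                       3000, 300, 600, 700, 900, 1000),
    stringsAsFactors = FALSE
  )
}

# NOVA palettes cycled over the foods of each analysis group.
sim_nova_palette <- function() {
  list(whole_grains = c(1, 3, 4), fruits = c(1, 1, 3),
       vegetables = c(1, 1, 3), nuts_seeds = c(1, 3), legumes = c(1, 3),
       unsaturated_oils = c(2, 4), tea_coffee = c(1, 1),
       refined_grains = c(3, 4, 4), fruit_juices = c(4, 1),
       saturated_plant_fats = c(2, 4), sugars_syrups = c(2, 4, 4),
       misc_plant = c(4, 3), animal_fats = c(2, 3), dairy = c(1, 3, 4),
       eggs = c(1, 1), fish_seafood = c(1, 3, 4), meat = c(1, 3, 4),
       misc_animal = c(4, 3))
}

#' Configuration for the synthetic dietary-survey generator
#'
#' Defaults emulate the marginal structure of a national nutrition survey of
#' adults: total energy intake around 2001 kcal/day, a mean UPF energy share
#' of 39.1%, zero-inflated single-recall serving distributions per food
#' group, and a delete-a-group jackknife replicate-weight design with
#' R = 30. The configured `slope_*` parameters impose a known linear
#' association between each diet index and the UPF energy share (in percent
#' energy per index point), giving ground truth for recovery tests; all
#' default to 0.
#'
#' @param n_participants Number of participants (minimum 50).
#' @param seed Integer seed fixing the whole generation stream.
#' @param n_foods Number of regular foods in the composition table
#'   (minimum 18 so every analysis group is reachable).
#' @param mean_energy_kcal,sd_energy_kcal Daily energy intake distribution.
#' @param target_upf_mean Population mean UPF energy share (percent).
#' @param sd_upf Residual SD of the UPF share around its linear predictor.
#' @param slope_pdi,slope_hpdi,slope_updi Imposed index-UPF slopes.
#' @param zero_inflation Named numeric vector of per-group zero probabilities
#'   (defaults from `sim_group_defaults()`).
#' @param n_replicates Number of jackknife replicate-weight groups.
#' @param interaction Optional list `list(moderator =, index =, effect =)`
#'   adding `effect x I(moderator level) x index` to the UPF linear
#'   predictor; moderator `"sex"` uses the male indicator.
#' @param sociodemo_gradients Couple age and education mildly to the latent
#'   axis (off by default so recovery tests are clean).
#' @param recipe_share Probability that a legume/vegetable serving is
#'   reported as a handmade mixed dish rather than a single food.
#' @return An object of class `plantupf_simconfig`.
#' @export
sim_config <- function(n_participants = 2000, seed = 1, n_foods = 54,
                       mean_energy_kcal = 2001, sd_energy_kcal = 600,
                       target_upf_mean = 39.1, sd_upf = 8,
                       slope_pdi = 0, slope_hpdi = 0, slope_updi = 0,
                       zero_inflation = NULL, n_replicates = 30,
                       interaction = NULL, sociodemo_gradients = FALSE,
                       recipe_share = 0.5) {
  defaults <- sim_group_defaults()
  zi <- stats::setNames(defaults$zero_inflation, defaults$analysis_group)
  if (!is.null(zero_inflation)) {
    bad <- setdiff(names(zero_inflation), names(zi))
    if (length(bad) > 0L) {
      stop("unknown group(s) in zero_inflation: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    zi[names(zero_inflation)] <- zero_inflation
  }
  if (n_participants < 50L) {
    stop("n_participants must be >= 50", call. = FALSE)
  }
  if (n_foods < 18L) stop("n_foods must be >= 18", call. = FALSE)
  if (any(zi < 0 | zi > 1)) {
    stop("zero_inflation probabilities must be in [0, 1]", call. = FALSE)
  }
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (!is.null(interaction)) {
    stopifnot(is.list(interaction),
              all(c("moderator", "index", "effect") %in% names(interaction)))
  }
  structure(list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    n_foods = as.integer(n_foods), mean_energy_kcal = mean_energy_kcal,
    sd_energy_kcal = sd_energy_kcal, target_upf_mean = target_upf_mean,
    sd_upf = sd_upf, slope_pdi = slope_pdi, slope_hpdi = slope_hpdi,
    slope_updi = slope_updi, zero_inflation = zi,
    n_replicates = as.integer(n_replicates), interaction = interaction,
    sociodemo_gradients = isTRUE(sociodemo_gradients),
    recipe_share = recipe_share,
    generator_version = "1"
  ), class = "plantupf_simconfig")
}

#' Generate a synthetic reference bundle
#'
#' Builds composition, recipe, NOVA and apportionment tables that pass every
#' loader invariant: `n_foods` regular foods distributed round-robin over the
#' 18 analysis groups (dairy and meat foods cycled over their source
#' strata, one dairy food apportioned to two strata to exercise
#' multi-mapping), two handmade recipes composed of NOVA 1-3 ingredients,
#' and two zero-apportionment staple beverages (mineral water, NOVA 1, and a
#' cola soft drink, NOVA 4) that anchor the two energy pools of every
#' participant.
#'
#' @param config A `plantupf_simconfig`.
#' @return A validated `plantupf_bundle`.
#' @export
generate_reference_bundle <- function(config = sim_config()) {
  stopifnot(inherits(config, "plantupf_simconfig"))
  set.seed(config$seed)
  scheme <- default_group_scheme()
  defaults <- sim_group_defaults()
  palette <- sim_nova_palette()

  n <- config$n_foods
  groups <- rep(scheme$analysis_groups, length.out = n)
  codes <- sprintf("%08d", 10000000L + seq_len(n))
  dens_base <- stats::setNames(defaults$energy_density,
                               defaults$analysis_group)
  density <- round(dens_base[groups] * exp(stats::rnorm(n, 0, 0.15)), 1)
  rate <- round(stats::runif(n, 0.4, 1.6), 3)

  # Source strata: dairy foods cycle the 3 fat strata, meat foods the 4
  # red-meat/poultry strata, everything else maps to itself.
  dairy_strata <- names(scheme$collapse_map)[scheme$collapse_map == "dairy"]
  meat_strata <- names(scheme$collapse_map)[scheme$collapse_map == "meat"]
  source_group <- groups
  di <- which(groups == "dairy")
  source_group[di] <- dairy_strata[(seq_along(di) - 1L) %% 3L + 1L]
  mi <- which(groups == "meat")
  source_group[mi] <- meat_strata[(seq_along(mi) - 1L) %% 4L + 1L]

  nova_group <- vapply(seq_len(n), function(i) {
    pal <- palette[[groups[i]]]
    pal[(sum(groups[seq_len(i)] == groups[i]) - 1L) %% length(pal) + 1L]
  }, numeric(1L))

  apportionment <- data.frame(food_code = codes, source_group = source_group,
                              servings_per_100g = rate,
                              stringsAsFactors = FALSE)
  # First dairy food is split across two fat strata (a mixed dairy food).
  if (length(di) > 0L) {
    i <- di[1L]
    apportionment <- apportionment[-i, , drop = FALSE]
    apportionment <- rbind(apportionment, data.frame(
      food_code = rep(codes[i], 2L),
      source_group = c(dairy_strata[1L], dairy_strata[3L]),
      servings_per_100g = round(c(0.6, 0.4) * rate[i], 4),
      stringsAsFactors = FALSE))
  }

  water_code <- "20000001"
  cola_code <- "20000002"
  staples <- data.frame(
    food_code = c(water_code, cola_code),
    description = c("mineral water, bottled", "cola soft drink"),
    energy_density_kj_100g = c(1, 180),
    is_recipe = FALSE, stringsAsFactors = FALSE)
  apportionment <- rbind(apportionment, data.frame(
    food_code = c(water_code, cola_code),
    source_group = c("vegetables", "sugars_syrups"),
    servings_per_100g = c(0, 0), stringsAsFactors = FALSE))

  # Handmade mixed dishes: NOVA 1-3 ingredients only, one-level recipes.
  leg_ing <- codes[which(groups == "legumes")[1L]]
  veg_ing <- codes[which(groups == "vegetables")[1L]]
  recipe_codes <- c("30000001", "30000002")
  recipes <- data.frame(
    parent_code = rep(recipe_codes, c(2L, 2L)),
    ingredient_code = c(leg_ing, water_code, veg_ing, water_code),
    weight_fraction = c(0.85, 0.15, 0.9, 0.1),
    stringsAsFactors = FALSE)
  dens_map <- stats::setNames(c(density, staples$energy_density_kj_100g),
                              c(codes, staples$food_code))
  recipe_density <- vapply(recipe_codes, function(p) {
    rows <- recipes[recipes$parent_code == p, ]
    sum(rows$weight_fraction * dens_map[rows$ingredient_code])
  }, numeric(1L))

  composition <- rbind(
    data.frame(food_code = codes,
               description = paste0("synthetic ", gsub("_", " ", groups),
                                    " food ", seq_len(n)),
               energy_density_kj_100g = as.numeric(density),
               is_recipe = FALSE, stringsAsFactors = FALSE),
    staples,
    data.frame(food_code = recipe_codes,
               description = c("homemade lentil soup",
                               "homemade vegetable stew"),
               energy_density_kj_100g = round(as.numeric(recipe_density), 1),
               is_recipe = TRUE, stringsAsFactors = FALSE))

  nova <- data.frame(
    food_code = c(codes, water_code, cola_code),
    nova_group = as.integer(c(nova_group, 1L, 4L)),
    stringsAsFactors = FALSE)

  load_reference_tables(composition, recipes, nova, apportionment,
                        scheme = scheme, quiet = TRUE)
}

# Effective servings of each analysis group delivered per 100 g of a food,
# after one-level recipe resolution.
effective_group_rates <- function(bundle) {
  collapsed <- collapse_groups(bundle$apportionment, bundle$scheme)
  base <- collapsed
  rec <- bundle$recipes
  if (nrow(rec) > 0L) {
    joined <- merge(rec, collapsed, by.x = "ingredient_code",
                    by.y = "food_code", sort = FALSE)
    joined$rate <- joined$weight_fraction * joined$servings_per_100g
    extra <- stats::aggregate(
      list(servings_per_100g = joined$rate),
      by = list(food_code = joined$parent_code,
                analysis_group = joined$analysis_group), FUN = sum)
    base <- rbind(base, extra)
  }
  base
}

#' Generate a synthetic survey population
#'
#' Draws covariates, anthropometry, survey weights and a first-day 24 h
#' recall for each participant. A latent diet-quality axis modulates
#' per-group serving amounts (zero/non-zero consumption stays at the
#' configured zero-inflation probability, independent of the axis); the
#' participant's plant-based diet indices are then computed through the
#' package's own scoring pipeline, and recall energies are allocated between
#' NOVA 4 and non-NOVA-4 items so that the UPF energy share equals
#' `target_upf_mean + sum_s slope_s (index_s - weighted mean) + noise`
#' (clipped to 0-100). The configured slopes are therefore the exact
#' expected regression coefficients of UPF share on each index.
#'
#' @param config A `plantupf_simconfig`.
#' @param bundle A `plantupf_bundle`, typically from
#'   [generate_reference_bundle()] with the same config.
#' @return An object of class `plantupf_population`: list with `recall`,
#'   `participants` (covariates, anthropometry, exclusion flags), `design`
#'   (a `plantupf_design`), `ground_truth` and `config`.
#' @export
generate_population <- function(config = sim_config(),
                                bundle = generate_reference_bundle(config)) {
  stopifnot(inherits(config, "plantupf_simconfig"),
            inherits(bundle, "plantupf_bundle"))
  set.seed(config$seed + 1L)
  n <- config$n_participants
  scheme <- bundle$scheme
  defaults <- sim_group_defaults()
  ids <- sprintf("P%06d", seq_len(n))

  z <- stats::rnorm(n)

  age <- pmin(pmax(stats::rnorm(n, 49.4, 17.3), 19), 90)
  sex <- sample(c("female", "male"), n, replace = TRUE,
                prob = c(0.494, 0.506))
  education <- sample(c("low", "medium", "high"), n, replace = TRUE,
                      prob = c(0.33, 0.34, 0.33))
  if (config$sociodemo_gradients) {
    # Mild gradients: older and more educated participants sit higher on
    # the healthfulness axis (mirrors the descriptive quintile patterns).
    age <- pmin(pmax(age + 3 * z, 19), 90)
    flip <- stats::runif(n) < stats::plogis(0.4 * z) * 0.3
    education[flip] <- "high"
  }
  country_of_birth <- sample(c("Australia", "main_english_speaking", "other"),
                             n, replace = TRUE, prob = c(0.72, 0.11, 0.17))
  rurality <- sample(c("major_city", "inner_regional", "other"),
                     n, replace = TRUE, prob = c(0.70, 0.18, 0.12))
  area_disadvantage <- sample(paste0("Q", 1:5), n, replace = TRUE)
  body_weight <- pmax(stats::rnorm(n, ifelse(sex == "male", 85, 72),
                                   ifelse(sex == "male", 14, 15)), 40)

  person_weight <- exp(stats::rnorm(n, 0, 0.3))
  R <- config$n_replicates
  rep_group <- sample(rep(seq_len(R), length.out = n))
  repw <- outer(rep_group, seq_len(R),
                function(g, r) ifelse(g == r, 0, R / (R - 1)))
  repw <- repw * person_weight
  colnames(repw) <- paste0("rep_", seq_len(R))
  design <- survey_design(ids, person_weight, repw)

  # Per-group servings: Bernoulli consumption at the configured
  # zero-inflation rate (independent of z), gamma amounts scaled by the axis.
  groups <- scheme$analysis_groups
  mu <- stats::setNames(defaults$mean_servings, defaults$analysis_group)
  loading <- stats::setNames(defaults$axis_loading, defaults$analysis_group)
  serv <- matrix(0, n, length(groups), dimnames = list(NULL, groups))
  for (g in groups) {
    consume <- stats::runif(n) >= config$zero_inflation[[g]]
    amount <- stats::rgamma(n, shape = 2,
                            scale = mu[[g]] * exp(loading[[g]] * z) / 2)
    serv[, g] <- ifelse(consume, amount, 0)
  }

  # Food choice per consumed group; handmade recipes can stand in for their
  # dominant group's food.
  rates <- effective_group_rates(bundle)
  comp <- bundle$composition
  group_members <- lapply(groups, function(g) {
    rates$food_code[rates$analysis_group == g & rates$servings_per_100g > 0]
  })
  names(group_members) <- groups
  recipe_codes <- comp$food_code[comp$is_recipe]
  rate_map <- stats::setNames(rates$servings_per_100g,
                              paste(rates$food_code, rates$analysis_group))
  # Collapse multi-row foods to a total per-group rate.
  tot_rate <- stats::aggregate(servings_per_100g ~ food_code + analysis_group,
                               data = rates, FUN = sum)
  tot_map <- stats::setNames(tot_rate$servings_per_100g,
                             paste(tot_rate$food_code,
                                   tot_rate$analysis_group))

  item_list <- list()
  for (g in groups) {
    who <- which(serv[, g] > 0)
    if (length(who) == 0L) next
    members <- group_members[[g]]
    regular <- setdiff(members, recipe_codes)
    rec_members <- intersect(members, recipe_codes)
    pick <- regular[sample.int(length(regular), length(who), replace = TRUE)]
    if (length(rec_members) > 0L) {
      use_recipe <- stats::runif(length(who)) < config$recipe_share
      pick[use_recipe] <- rec_members[1L]
    }
    grams <- 100 * serv[who, g] / tot_map[paste(pick, g)]
    item_list[[g]] <- data.frame(participant_id = ids[who], food_code = pick,
                                 grams = as.numeric(grams),
                                 stringsAsFactors = FALSE)
  }
  items <- do.call(rbind, item_list)
  staples <- data.frame(
    participant_id = rep(ids, 2L),
    food_code = rep(c("20000001", "20000002"), each = n),
    grams = rep(c(500, 330), each = n), stringsAsFactors = FALSE)
  items <- rbind(items, staples)

  dens_map <- stats::setNames(comp$energy_density_kj_100g, comp$food_code)
  items$energy_kj <- items$grams * dens_map[items$food_code] / 100

  # Score the indices through the pipeline itself so that the imposed
  # index-UPF association is exact for the downstream re-analysis.
  flat <- disaggregate(items, bundle)
  collapsed <- collapse_groups(bundle$apportionment, scheme)
  profiles <- servings_profile(flat, collapsed, scheme)
  scores <- pdi_scores(profiles, scheme, design = design,
                       use_weights = TRUE, quiet = TRUE)
  idx <- scores$indices[match(ids, scores$indices$participant_id), ]

  w <- person_weight
  centred <- function(v) v - wmean(v, w)
  lin <- config$target_upf_mean +
    config$slope_pdi * centred(idx$pdi) +
    config$slope_hpdi * centred(idx$hpdi) +
    config$slope_updi * centred(idx$updi)
  if (!is.null(config$interaction)) {
    ia <- config$interaction
    mod_ind <- switch(ia$moderator,
                      sex = as.numeric(sex == "male"),
                      stop("unsupported interaction moderator: ", ia$moderator,
                           call. = FALSE))
    lin <- lin + ia$effect * mod_ind * centred(idx[[ia$index]])
  }
  p_upf <- pmin(pmax(lin + stats::rnorm(n, 0, config$sd_upf), 0), 100)

  # Allocate each participant's reported energy between the NOVA-4 and
  # non-NOVA-4 pools to realise the target share; recipes (NOVA 1-3
  # ingredients only) always sit in the non-UPF pool.
  energy_kcal <- pmax(stats::rnorm(n, config$mean_energy_kcal,
                                   config$sd_energy_kcal), 600)
  energy_kj <- kcal_to_kj(energy_kcal)
  nova_map <- stats::setNames(as.integer(bundle$nova$nova_group),
                              bundle$nova$food_code)
  is_upf_item <- !is.na(nova_map[items$food_code]) &
    nova_map[items$food_code] == 4L
  pidx <- match(items$participant_id, ids)
  pool_sum <- function(sel) {
    s <- tapply(items$energy_kj[sel], factor(items$participant_id[sel],
                                             levels = ids), sum, default = 0)
    as.numeric(s)
  }
  upf_nominal <- pool_sum(is_upf_item)
  non_nominal <- pool_sum(!is_upf_item)
  upf_target <- energy_kj * p_upf / 100
  non_target <- energy_kj - upf_target
  scale_upf <- ifelse(upf_nominal > 0, upf_target / upf_nominal, 0)
  scale_non <- ifelse(non_nominal > 0, non_target / non_nominal, 0)
  items$energy_kj <- items$energy_kj *
    ifelse(is_upf_item, scale_upf[pidx], scale_non[pidx])

  participants <- data.frame(
    participant_id = ids, age = age, sex = sex, education = education,
    country_of_birth = country_of_birth, rurality = rurality,
    area_disadvantage = area_disadvantage, body_weight = body_weight,
    pregnant = FALSE, breastfeeding = FALSE, missing_upf = FALSE,
    stringsAsFactors = FALSE)

  ground_truth <- list(
    generator_version = config$generator_version,
    slopes = list(pdi = config$slope_pdi, hpdi = config$slope_hpdi,
                  updi = config$slope_updi),
    interaction = config$interaction,
    per_participant = data.frame(
      participant_id = ids, latent_axis = z, target_upf_share = p_upf,
      pdi = idx$pdi, hpdi = idx$hpdi, updi = idx$updi,
      stringsAsFactors = FALSE)
  )

  items <- items[order(items$participant_id, items$food_code), ]
  rownames(items) <- NULL
  structure(list(recall = items,
                 participants = participants, design = design,
                 ground_truth = ground_truth, config = config),
            class = "plantupf_population")
}

#' Generate a complete synthetic study (bundle + population)
#' @param config A `plantupf_simconfig`.
#' @return List with `bundle` and `population`.
#' @export
simulate_study <- function(config = sim_config()) {
  bundle <- generate_reference_bundle(config)
  population <- generate_population(config, bundle)
  list(bundle = bundle, population = population)
}

#' Write a generated dataset to a directory
#'
#' Emits the complete input set for a pipeline run: the reference bundle
#' (CSV + scheme YAML) under `reference/`, `recall.csv`,
#' `participants.csv`, `design.csv`, `design_meta.yaml` and
#' `ground_truth.json`.
#'
#' @param study Output of [simulate_study()] (or a list with `bundle` and
#'   `population`).
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(study, dir) {
  pop <- study$population
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reference_bundle(study$bundle, file.path(dir, "reference"))
  utils::write.csv(pop$recall, file.path(dir, "recall.csv"),
                   row.names = FALSE)
  utils::write.csv(pop$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  des <- data.frame(participant_id = pop$design$participant_id,
                    person_weight = pop$design$person_weight,
                    pop$design$replicate_weights,
                    stringsAsFactors = FALSE, check.names = FALSE)
  utils::write.csv(des, file.path(dir, "design.csv"), row.names = FALSE)
  yaml::write_yaml(list(n_replicates = pop$design$n_replicates,
                        variance_scale = pop$design$variance_scale),
                   file.path(dir, "design_meta.yaml"))
  gt <- pop$ground_truth
  jsonlite::write_json(
    list(generator_version = gt$generator_version, slopes = gt$slopes,
         interaction = gt$interaction, per_participant = gt$per_participant),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#' @param dir Dataset directory.
#' @param quiet Suppress loader log messages.
#' @return List with `bundle` and `population` (ground truth reattached).
#' @export
read_dataset <- function(dir, quiet = FALSE) {
  bundle <- read_reference_bundle(file.path(dir, "reference"), quiet = quiet)
  recall <- utils::read.csv(file.path(dir, "recall.csv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(food_code = "character"))
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  des <- utils::read.csv(file.path(dir, "design.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "design_meta.yaml"))
  repw <- as.matrix(des[, grepl("^rep_", names(des)), drop = FALSE])
  design <- survey_design(des$participant_id, des$person_weight, repw,
                          variance_scale = meta$variance_scale)
  gt_path <- file.path(dir, "ground_truth.json")
  ground_truth <- if (file.exists(gt_path)) {
    jsonlite::read_json(gt_path, simplifyVector = TRUE)
  } else NULL
  population <- structure(list(recall = recall, participants = participants,
                               design = design, ground_truth = ground_truth,
                               config = NULL),
                          class = "plantupf_population")
  list(bundle = bundle, population = population)
}
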
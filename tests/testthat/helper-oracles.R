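# Independent oracles and tiny fixtures built in code.

# Brute-force quintile via the strictly-less weighted CDF:
# quintile(v) = 1 + #(k in 1..4 : P_w(X < v) >= k/5).
oracle_quintile <- function(values, x, w = rep(1, length(x))) {
  vapply(values, function(v) {
    f_minus <- sum(w[x < v]) / sum(w)
    1L + min(4L, sum(f_minus >= (1:4) / 5 - 1e-12))
  }, integer(1L))
}

# Normal-equations weighted least squares, independent of lm.wfit.
oracle_wls <- function(X, y, w) {
  XtW <- t(X * w)
  as.numeric(solve(XtW %*% X, XtW %*% y))
}

# A small survey design with explicit replicate weights.
make_design <- function(ids, person_weight = rep(1, length(ids)),
                        R = 4, variance_scale = NULL, seed = 42) {
  set.seed(seed)
  n <- length(ids)
  grp <- sample(rep(seq_len(R), length.out = n))
  repw <- outer(grp, seq_len(R), function(g, r) ifelse(g == r, 0, R / (R - 1)))
  repw <- repw * person_weight
  survey_design(ids, person_weight, repw, variance_scale = variance_scale)
}

# Path to the shipped 12-food / 2-recipe fixture bundle.
fixture_path <- function(file = "") {
  p <- system.file("extdata", "fixture", package = "plantupf")
  if (nzchar(file)) file.path(p, file) else p
}

load_fixture_bundle <- function(quiet = TRUE) {
  load_reference_tables(
    composition = fixture_path("composition.csv"),
    recipes = fixture_path("recipes.csv"),
    nova = fixture_path("nova.csv"),
    apportionment = fixture_path("apportionment.csv"),
    quiet = quiet
  )
}

# Minimal in-code tables for loader error-path tests.
tiny_tables <- function() {
  list(
    composition = data.frame(
      food_code = c("11111111", "22222222", "33333333"),
      description = c("oat", "soup", "carrot"),
      energy_density_kj_100g = c(1500, 700, 150),
      is_recipe = c(FALSE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    recipes = data.frame(
      parent_code = c("22222222", "22222222"),
      ingredient_code = c("11111111", "33333333"),
      weight_fraction = c(0.7, 0.3), stringsAsFactors = FALSE),
    nova = data.frame(food_code = c("11111111", "33333333"),
                      nova_group = c(1, 1), stringsAsFactors = FALSE),
    apportionment = data.frame(
      food_code = c("11111111", "33333333"),
      source_group = c("whole_grains", "vegetables"),
      servings_per_100g = c(1.2, 1.0), stringsAsFactors = FALSE)
  )
}
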
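#' Load and validate the reference tables
#'
#' Builds the validated reference bundle the pipeline runs on: the food
#' composition table (8-digit codes, energy density in kJ/100 g, recipe
#' flag), the recipe/ingredient table used to disaggregate handmade mixed
#' dishes, the NOVA assignment table (food code to NOVA group 1-4) and the
#' plant/animal food-group apportionment (servings per 100 g attributable to
#' each of the 23 source groups). Validation is fail-fast: reference tables
#' are small and any malformed row would propagate into every downstream
#' score, so errors abort rather than drop rows.
#'
#' @param composition,recipes,nova,apportionment Each a data.frame or a path
#'   to a CSV file. Required columns: composition `food_code`, `description`,
#'   `energy_density_kj_100g`, `is_recipe`; recipes `parent_code`,
#'   `ingredient_code`, `weight_fraction`; nova `food_code`, `nova_group`;
#'   apportionment `food_code`, `source_group`, `servings_per_100g`.
#' @param scheme A `plantupf_scheme` (default [default_group_scheme()]), or a
#'   path to a YAML scheme configuration.
#' @param quiet Suppress the row-count log messages.
#' @return An object of class `plantupf_bundle`: list with the four validated
#'   tables and the scheme.
#' @export
load_reference_tables <- function(composition, recipes, nova, apportionment,
                                  scheme = default_group_scheme(),
                                  quiet = FALSE) {
  if (is.character(scheme)) scheme <- read_group_scheme(scheme)
  scheme <- validate_group_scheme(scheme)

  composition <- as_table(composition, "composition")
  recipes <- as_table(recipes, "recipes")
  nova <- as_table(nova, "nova")
  apportionment <- as_table(apportionment, "apportionment")

  require_cols(composition,
               c("food_code", "description", "energy_density_kj_100g",
                 "is_recipe"), "composition")
  require_cols(recipes, c("parent_code", "ingredient_code", "weight_fraction"),
               "recipes")
  require_cols(nova, c("food_code", "nova_group"), "nova")
  require_cols(apportionment,
               c("food_code", "source_group", "servings_per_100g"),
               "apportionment")

  composition$food_code <- normalize_food_code(composition$food_code)
  composition$is_recipe <- as.logical(composition$is_recipe)
  dup <- unique(composition$food_code[duplicated(composition$food_code)])
  if (length(dup) > 0L) {
    stop("duplicate food_code(s) in composition table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(composition$energy_density_kj_100g)) ||
      any(composition$energy_density_kj_100g < 0)) {
    stop("energy_density_kj_100g must be present and >= 0", call. = FALSE)
  }

  recipes$parent_code <- normalize_food_code(recipes$parent_code)
  recipes$ingredient_code <- normalize_food_code(recipes$ingredient_code)
  is_recipe_code <- composition$food_code[composition$is_recipe]
  unknown_parent <- setdiff(recipes$parent_code, is_recipe_code)
  if (length(unknown_parent) > 0L) {
    stop("recipe parent_code(s) not flagged as recipes in composition: ",
         paste(unknown_parent, collapse = ", "), call. = FALSE)
  }
  unknown_ing <- setdiff(recipes$ingredient_code, composition$food_code)
  if (length(unknown_ing) > 0L) {
    stop("recipe ingredient_code(s) missing from composition: ",
         paste(unknown_ing, collapse = ", "), call. = FALSE)
  }
  # One-level resolution only: an ingredient that is itself a recipe would
  # form a (possibly cyclic) nested recipe, which the source file pre-flattens.
  nested <- intersect(recipes$ingredient_code, is_recipe_code)
  if (length(nested) > 0L) {
    stop("recipe cycle / nesting: ingredient(s) are themselves recipes: ",
         paste(nested, collapse = ", "), call. = FALSE)
  }
  frac_sums <- tapply(recipes$weight_fraction, recipes$parent_code, sum)
  bad_sum <- names(frac_sums)[abs(frac_sums - 1) > 1e-6]
  if (length(bad_sum) > 0L) {
    stop(sprintf("recipe weight fractions must sum to 1 (+/- 1e-6); parent(s) %s sum to %s",
                 paste(bad_sum, collapse = ", "),
                 paste(signif(frac_sums[bad_sum], 6), collapse = ", ")),
         call. = FALSE)
  }
  no_components <- setdiff(is_recipe_code, recipes$parent_code)
  if (length(no_components) > 0L) {
    stop("recipe food(s) without components in recipe table: ",
         paste(no_components, collapse = ", "), call. = FALSE)
  }

  nova$food_code <- normalize_food_code(nova$food_code)
  if (!all(nova$nova_group %in% 1:4)) {
    stop("nova_group must be in {1,2,3,4}", call. = FALSE)
  }
  dup_nova <- unique(nova$food_code[duplicated(nova$food_code)])
  if (length(dup_nova) > 0L) {
    stop("duplicate NOVA assignment(s): ", paste(dup_nova, collapse = ", "),
         call. = FALSE)
  }
  non_recipe <- composition$food_code[!composition$is_recipe]
  missing_nova <- setdiff(non_recipe, nova$food_code)
  if (length(missing_nova) > 0L) {
    stop("non-recipe food(s) without a NOVA assignment: ",
         paste(missing_nova, collapse = ", "), call. = FALSE)
  }

  apportionment$food_code <- normalize_food_code(apportionment$food_code)
  bad_group <- setdiff(apportionment$source_group, scheme$source_groups)
  if (length(bad_group) > 0L) {
    stop("unknown source group(s) in apportionment: ",
         paste(bad_group, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(apportionment$servings_per_100g)) ||
      any(apportionment$servings_per_100g < 0)) {
    stop("servings_per_100g must be present and >= 0", call. = FALSE)
  }
  unknown_app <- setdiff(apportionment$food_code, composition$food_code)
  if (length(unknown_app) > 0L) {
    stop("apportionment food_code(s) missing from composition: ",
         paste(unknown_app, collapse = ", "), call. = FALSE)
  }

  log_msg(quiet,
          "reference bundle loaded: %d foods (%d recipes), %d recipe rows, %d NOVA rows, %d apportionment rows",
          nrow(composition), sum(composition$is_recipe), nrow(recipes),
          nrow(nova), nrow(apportionment))

  rownames(composition) <- rownames(recipes) <- rownames(nova) <-
    rownames(apportionment) <- NULL
  structure(list(composition = composition, recipes = recipes, nova = nova,
                 apportionment = apportionment, scheme = scheme),
            class = "plantupf_bundle")
}

#' Collapse the 23 source groups to the 18 analysis groups
#'
#' Sums each food's apportioned servings within analysis groups under the
#' scheme's collapse map (dairy fat strata into one dairy group, red meat and
#' poultry strata into one meat group, all other groups unchanged). Total
#' servings per food are conserved.
#'
#' @param apportionment Apportionment table over source groups (columns
#'   `food_code`, `source_group`, `servings_per_100g`).
#' @param scheme A `plantupf_scheme`.
#' @return A data.frame `food_code`, `analysis_group`, `servings_per_100g`,
#'   one row per food x analysis group.
#' @export
collapse_groups <- function(apportionment, scheme = default_group_scheme()) {
  scheme <- validate_group_scheme(scheme)
  require_cols(apportionment,
               c("food_code", "source_group", "servings_per_100g"),
               "apportionment")
  unmapped <- setdiff(apportionment$source_group, names(scheme$collapse_map))
  if (length(unmapped) > 0L) {
    stop("unmapped source group(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  analysis_group <- unname(scheme$collapse_map[apportionment$source_group])
  agg <- stats::aggregate(
    list(servings_per_100g = apportionment$servings_per_100g),
    by = list(food_code = apportionment$food_code,
              analysis_group = analysis_group),
    FUN = sum
  )
  agg[order(agg$food_code, agg$analysis_group), , drop = FALSE]
}

#' Write a reference bundle to a directory of CSV files
#'
#' Writes `composition.csv`, `recipes.csv`, `nova.csv`, `apportionment.csv`
#' and `group_scheme.yaml` so that [load_reference_tables()] on the directory
#' round-trips the bundle.
#'
#' @param bundle A `plantupf_bundle`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reference_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "plantupf_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("composition", "recipes", "nova", "apportionment")) {
    utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = TRUE)
  }
  write_group_scheme(bundle$scheme, file.path(dir, "group_scheme.yaml"))
  invisible(dir)
}

#' Read a reference bundle written by [write_reference_bundle()]
#' @param dir Directory containing the bundle CSVs and scheme YAML.
#' @param quiet Suppress log messages.
#' @return A validated `plantupf_bundle`.
#' @export
read_reference_bundle <- function(dir, quiet = FALSE) {
  load_reference_tables(
    composition = file.path(dir, "composition.csv"),
    recipes = file.path(dir, "recipes.csv"),
    nova = file.path(dir, "nova.csv"),
    apportionment = file.path(dir, "apportionment.csv"),
    scheme = read_group_scheme(file.path(dir, "group_scheme.yaml")),
    quiet = quiet
  )
}
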
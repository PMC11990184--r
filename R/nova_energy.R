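#' Disaggregate handmade mixed dishes into ingredients
#'
#' Recall items whose food code is flagged as a recipe are replaced by their
#' ingredient records: grams are split by recipe weight fraction and
#' ingredient energies are first computed from each ingredient's energy
#' density, then proportionally rescaled so that they sum to the energy
#' reported for the recipe item. The reported recall energy is authoritative,
#' so every participant's total grams and total energy are conserved exactly
#' by disaggregation. Recipes are resolved one level deep; the loader rejects
#' nested recipes.
#'
#' @param recall Data.frame of first-day 24 h recall items: `participant_id`,
#'   `food_code`, `grams`, `energy_kj` (all non-negative).
#' @param bundle A `plantupf_bundle` from [load_reference_tables()].
#' @return A data.frame with the same columns, recipe rows replaced by
#'   ingredient rows.
#' @export
disaggregate <- function(recall, bundle) {
  stopifnot(inherits(bundle, "plantupf_bundle"))
  require_cols(recall, c("participant_id", "food_code", "grams", "energy_kj"),
               "recall")
  recall$food_code <- normalize_food_code(recall$food_code)
  if (any(recall$grams < 0) || any(recall$energy_kj < 0)) {
    stop("recall grams and energy_kj must be >= 0", call. = FALSE)
  }
  comp <- bundle$composition
  unknown <- setdiff(recall$food_code, comp$food_code)
  if (length(unknown) > 0L) {
    stop("recall food_code(s) missing from composition: ",
         paste(utils::head(unknown, 10L), collapse = ", "), call. = FALSE)
  }
  is_recipe <- recall$food_code %in% comp$food_code[comp$is_recipe]
  plain <- recall[!is_recipe, , drop = FALSE]
  if (!any(is_recipe)) {
    return(plain)
  }

  rec_items <- recall[is_recipe, , drop = FALSE]
  rec_items$.row <- seq_len(nrow(rec_items))
  expanded <- merge(rec_items, bundle$recipes,
                    by.x = "food_code", by.y = "parent_code", sort = FALSE)
  dens <- stats::setNames(comp$energy_density_kj_100g, comp$food_code)
  expanded$grams_ing <- expanded$grams * expanded$weight_fraction
  expanded$energy_nominal <- dens[expanded$ingredient_code] *
    expanded$grams_ing / 100

  # Rescale nominal ingredient energies so each recipe item keeps its
  # reported energy; if all nominal energies are zero, split by grams.
  nominal_sum <- tapply(expanded$energy_nominal, expanded$.row, sum)
  expanded$.nominal_sum <- as.numeric(nominal_sum[as.character(expanded$.row)])
  zero_nom <- expanded$.nominal_sum <= 0
  expanded$energy_ing <- ifelse(
    zero_nom,
    expanded$energy_kj * expanded$weight_fraction,
    expanded$energy_kj * expanded$energy_nominal / expanded$.nominal_sum
  )

  out <- data.frame(
    participant_id = c(plain$participant_id, expanded$participant_id),
    food_code = c(plain$food_code, expanded$ingredient_code),
    grams = c(plain$grams, expanded$grams_ing),
    energy_kj = c(plain$energy_kj, expanded$energy_ing),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Attach NOVA groups to recall items
#'
#' Every (post-disaggregation) item must carry exactly one NOVA group; a
#' missing assignment is a hard error rather than a silent default, since
#' misclassification propagates directly into the UPF energy share.
#'
#' @param items Data.frame `participant_id`, `food_code`, `grams`,
#'   `energy_kj` (recipes already disaggregated).
#' @param bundle A `plantupf_bundle`.
#' @return `items` with an integer `nova_group` column (1-4).
#' @export
classify_nova <- function(items, bundle) {
  stopifnot(inherits(bundle, "plantupf_bundle"))
  require_cols(items, c("participant_id", "food_code", "grams", "energy_kj"),
               "items")
  items$food_code <- normalize_food_code(items$food_code)
  nova <- stats::setNames(as.integer(bundle$nova$nova_group),
                          bundle$nova$food_code)
  grp <- nova[items$food_code]
  if (anyNA(grp)) {
    stop("item(s) without NOVA assignment: ",
         paste(utils::head(unique(items$food_code[is.na(grp)]), 10L),
               collapse = ", "), call. = FALSE)
  }
  items$nova_group <- unname(grp)
  items
}

#' Per-participant energy share from ultra-processed foods
#'
#' Computes for each participant the percentage of daily energy contributed
#' by each NOVA group, in particular `pct_energy_upf`, the NOVA group 4
#' (ultra-processed food) share: 100 x energy(NOVA 4) / total energy.
#' Participants with zero total energy cannot have a defined share and are
#' excluded with a logged message.
#'
#' @param items Classified items from [classify_nova()].
#' @param quiet Suppress the exclusion log message.
#' @return Data.frame `participant_id`, `total_energy_kj`,
#'   `total_energy_kcal`, `pct_energy_nova1` .. `pct_energy_nova4`,
#'   `pct_energy_upf` (equal to the NOVA 4 column).
#' @export
upf_energy_share <- function(items, quiet = FALSE) {
  require_cols(items, c("participant_id", "energy_kj", "nova_group"), "items")
  tot <- tapply(items$energy_kj, items$participant_id, sum)
  ids <- names(tot)
  zero <- tot <= 0
  if (any(zero)) {
    log_msg(quiet, "excluding %d participant(s) with zero total energy",
            sum(zero))
  }
  by_group <- tapply(items$energy_kj,
                     list(items$participant_id,
                          factor(items$nova_group, levels = 1:4)),
                     sum, default = 0)
  by_group <- by_group[ids, , drop = FALSE]
  pct <- sweep(by_group, 1L, as.numeric(tot), "/") * 100

  out <- data.frame(
    participant_id = ids,
    total_energy_kj = as.numeric(tot),
    total_energy_kcal = kj_to_kcal(as.numeric(tot)),
    pct_energy_nova1 = pct[, 1L],
    pct_energy_nova2 = pct[, 2L],
    pct_energy_nova3 = pct[, 3L],
    pct_energy_nova4 = pct[, 4L],
    stringsAsFactors = FALSE
  )
  out$pct_energy_upf <- out$pct_energy_nova4
  out <- out[!zero, , drop = FALSE]
  rownames(out) <- NULL
  out
}
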
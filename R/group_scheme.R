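#' Food-group scheme for plant-based diet index scoring
#'
#' The plant-based diet indices score 18 analysis food groups: 7 healthy
#' plant groups (whole grains, fruits, vegetables, nuts and seeds, legumes,
#' unsaturated plant oils and spreads, tea and coffee), 5 unhealthy plant
#' groups (refined grains, fruit juices, saturated plant fats, sugars and
#' syrups, miscellaneous plant products) and 6 animal groups (animal fats,
#' dairy, eggs, fish and seafood, meat, miscellaneous animal products).
#'
#' The source food-composition apportionment distinguishes 23 groups; dairy
#' is split into low-, medium- and high-fat strata and meat into four red
#' meat / poultry strata by fat content. `default_group_scheme()` collapses
#' those strata into the single dairy and meat analysis groups and maps every
#' other source group to itself. The exact membership of the extra source
#' strata is a documented assumption of the default scheme and can be
#' replaced via a YAML configuration (see [read_group_scheme()]).
#'
#' @return An object of class `plantupf_scheme`: a list with elements
#'   `source_groups` (23 labels), `analysis_groups` (18 labels),
#'   `collapse_map` (named character, source -> analysis) and `health_class`
#'   (named character, analysis group -> one of `"healthy_plant"`,
#'   `"unhealthy_plant"`, `"animal"`).
#' @examples
#' sch <- default_group_scheme()
#' table(sch$health_class)
#' @export
default_group_scheme <- function() {
  healthy <- c("whole_grains", "fruits", "vegetables", "nuts_seeds",
               "legumes", "unsaturated_oils", "tea_coffee")
  unhealthy <- c("refined_grains", "fruit_juices", "saturated_plant_fats",
                 "sugars_syrups", "misc_plant")
  animal <- c("animal_fats", "dairy", "eggs", "fish_seafood", "meat",
              "misc_animal")
  analysis_groups <- c(healthy, unhealthy, animal)

  dairy_strata <- c("dairy_low_fat", "dairy_medium_fat", "dairy_high_fat")
  meat_strata <- c("red_meat_lean", "red_meat_regular",
                   "poultry_lean", "poultry_regular")
  identity_groups <- setdiff(analysis_groups, c("dairy", "meat"))

  collapse_map <- c(
    stats::setNames(identity_groups, identity_groups),
    stats::setNames(rep("dairy", length(dairy_strata)), dairy_strata),
    stats::setNames(rep("meat", length(meat_strata)), meat_strata)
  )

  health_class <- c(
    stats::setNames(rep("healthy_plant", length(healthy)), healthy),
    stats::setNames(rep("unhealthy_plant", length(unhealthy)), unhealthy),
    stats::setNames(rep("animal", length(animal)), animal)
  )

  scheme <- list(
    source_groups = names(collapse_map),
    analysis_groups = analysis_groups,
    collapse_map = collapse_map,
    health_class = health_class
  )
  class(scheme) <- "plantupf_scheme"
  validate_group_scheme(scheme)
}

#' Validate a food-group scheme
#'
#' Checks the structural invariants of the 23-to-18 collapse: exactly 18
#' analysis groups split 7 / 5 / 6 across health classes, and every source
#' group mapped to exactly one analysis group.
#'
#' @param scheme A `plantupf_scheme` list.
#' @return The scheme, invisibly classed, on success; errors otherwise.
#' @export
validate_group_scheme <- function(scheme) {
  stopifnot(is.list(scheme))
  needed <- c("source_groups", "analysis_groups", "collapse_map",
              "health_class")
  missing <- setdiff(needed, names(scheme))
  if (length(missing) > 0L) {
    stop("scheme config missing element(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (length(scheme$analysis_groups) != 18L) {
    stop("scheme must define exactly 18 analysis groups, got ",
         length(scheme$analysis_groups), call. = FALSE)
  }
  if (anyDuplicated(scheme$source_groups) || anyDuplicated(scheme$analysis_groups)) {
    stop("duplicate group labels in scheme", call. = FALSE)
  }
  unmapped <- setdiff(scheme$source_groups, names(scheme$collapse_map))
  if (length(unmapped) > 0L) {
    stop("source group(s) without a collapse mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  bad_target <- setdiff(unname(scheme$collapse_map), scheme$analysis_groups)
  if (length(bad_target) > 0L) {
    stop("collapse map targets unknown analysis group(s): ",
         paste(bad_target, collapse = ", "), call. = FALSE)
  }
  hc <- scheme$health_class[scheme$analysis_groups]
  if (anyNA(hc)) {
    stop("health class missing for analysis group(s): ",
         paste(scheme$analysis_groups[is.na(hc)], collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(hc, levels = c("healthy_plant", "unhealthy_plant",
                                        "animal")))
  if (!identical(as.integer(counts), c(7L, 5L, 6L))) {
    stop(sprintf(paste0("scheme must have 7 healthy_plant, 5 unhealthy_plant",
                        " and 6 animal groups; got %d/%d/%d"),
                 counts[[1L]], counts[[2L]], counts[[3L]]), call. = FALSE)
  }
  class(scheme) <- "plantupf_scheme"
  scheme
}

#' Read / write a group scheme as YAML
#'
#' @param path Path to a YAML file with fields `source_groups`,
#'   `analysis_groups`, `collapse_map`, `health_class`.
#' @return For `read_group_scheme`, a validated `plantupf_scheme`; for
#'   `write_group_scheme`, the path invisibly.
#' @export
read_group_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  scheme <- list(
    source_groups = as.character(raw$source_groups),
    analysis_groups = as.character(raw$analysis_groups),
    collapse_map = unlist(raw$collapse_map),
    health_class = unlist(raw$health_class)
  )
  validate_group_scheme(scheme)
}

#' @rdname read_group_scheme
#' @param scheme A `plantupf_scheme`.
#' @export
write_group_scheme <- function(scheme, path) {
  scheme <- validate_group_scheme(scheme)
  yaml::write_yaml(list(
    source_groups = scheme$source_groups,
    analysis_groups = scheme$analysis_groups,
    collapse_map = as.list(scheme$collapse_map),
    health_class = as.list(scheme$health_class)
  ), path)
  invisible(path)
}
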
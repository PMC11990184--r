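# Run one pipeline stage, aborting with the stage name on failure.
run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Component scores in wide per-participant form
#' @param components Long table from [component_scores()].
#' @return Data.frame `participant_id` plus `<group>_pdi`, `<group>_hpdi`,
#'   `<group>_updi` columns.
#' @export
component_scores_wide <- function(components) {
  pid <- sort(unique(components$participant_id))
  out <- data.frame(participant_id = pid, stringsAsFactors = FALSE)
  for (idx in c("pdi", "hpdi", "updi")) {
    mat <- tapply(components[[paste0("score_", idx)]],
                  list(factor(components$participant_id, levels = pid),
                       components$analysis_group), sum)
    colnames(mat) <- paste0(colnames(mat), "_", idx)
    out <- cbind(out, as.data.frame(mat))
  }
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Chains every stage: cohort filter, recipe disaggregation, NOVA
#' classification and UPF energy share, servings profiles, quintile-based
#' index scoring, the energy-misreporting covariate, and the survey-weighted
#' statistics (descriptive quintile tables, index regressions, component
#' associations, moderation models). A machine-readable manifest records the
#' row counts at each stage and the flags used, so reruns with the same
#' inputs are byte-identical.
#'
#' @param data Either a dataset directory written by [write_dataset()] or a
#'   list with `bundle` and `population` (e.g. from [simulate_study()]).
#' @param out_dir Optional output directory for the result CSVs, cutpoint
#'   audit YAML and `manifest.json`.
#' @param use_weighted_quintiles Compute index scoring quintiles on the
#'   survey-weighted serving distributions (default `TRUE`).
#' @param transpose_regression Swap outcome and exposure in the index models
#'   (sensitivity analysis; default `FALSE`).
#' @param rao_scott Apply the Rao-Scott correction to the categorical
#'   homogeneity tests.
#' @param moderation_index Index passed to [moderation_models()]
#'   (`NULL` skips moderation).
#' @param quiet Suppress log messages.
#' @return List of class `plantupf_result`: `upf_share`, `profiles`,
#'   `scores` (cutpoints/components/indices), `analysis_table`, `table1`
#'   (per index), `table2`, `table2_full`, `table3`, `moderation`,
#'   `exclusions`, `manifest`.
#' @export
run_pipeline <- function(data, out_dir = NULL, use_weighted_quintiles = TRUE,
                         transpose_regression = FALSE, rao_scott = FALSE,
                         moderation_index = "updi", quiet = FALSE) {
  loaded <- run_stage("load", {
    if (is.character(data)) read_dataset(data, quiet = quiet) else data
  })
  bundle <- loaded$bundle
  pop <- loaded$population
  stopifnot(inherits(bundle, "plantupf_bundle"))
  scheme <- bundle$scheme
  design <- pop$design

  filt <- run_stage("filter_cohort", filter_cohort(pop$participants,
                                                   quiet = quiet))
  included <- filt$included
  recall <- pop$recall[pop$recall$participant_id %in%
                         included$participant_id, , drop = FALSE]

  flat <- run_stage("disaggregate", disaggregate(recall, bundle))
  classified <- run_stage("nova_classify", classify_nova(flat, bundle))
  upf <- run_stage("upf_share", upf_energy_share(classified, quiet = quiet))

  collapsed <- run_stage("collapse_groups",
                         collapse_groups(bundle$apportionment, scheme))
  profiles <- run_stage("servings_profile",
                        servings_profile(classified, collapsed, scheme))
  scores <- run_stage("pdi_scoring",
                      pdi_scores(profiles, scheme, design = design,
                                 use_weights = use_weighted_quintiles,
                                 quiet = quiet))

  misrep <- run_stage("misreporting", misreporting_scores(
    upf[, c("participant_id", "total_energy_kj")],
    included[, c("participant_id", "sex", "age", "body_weight")],
    design = design, quiet = quiet))

  analysis_table <- run_stage("analysis_table", {
    tab <- merge(included, upf, by = "participant_id")
    tab <- merge(tab, scores$indices, by = "participant_id")
    tab <- merge(tab, misrep, by = "participant_id")
    prepare_covariates(tab)
  })

  table2_full <- run_stage("index_models",
                           fit_index_models(analysis_table, design,
                                            transpose = transpose_regression))
  table2 <- table2_shape(table2_full)
  table3 <- run_stage("component_associations",
                      component_associations(analysis_table,
                                             scores$components, design,
                                             scheme))
  table1 <- run_stage("quintile_tables", {
    out <- lapply(c("pdi", "hpdi", "updi"), function(i) {
      quintile_table(analysis_table, design, index = i,
                     rao_scott = rao_scott)
    })
    names(out) <- c("pdi", "hpdi", "updi")
    out
  })
  moderation <- if (!is.null(moderation_index)) {
    run_stage("moderation",
              moderation_models(analysis_table, design,
                                index = moderation_index))
  } else NULL

  manifest <- list(
    package = "plantupf",
    package_version = as.character(utils::packageVersion("plantupf")),
    generator_version = pop$config$generator_version,
    flags = list(use_weighted_quintiles = use_weighted_quintiles,
                 transpose_regression = transpose_regression,
                 rao_scott = rao_scott),
    counts = list(
      participants_in = nrow(pop$participants),
      exclusions = as.list(filt$ledger),
      recall_items = nrow(recall),
      items_post_disaggregation = nrow(flat),
      participants_with_upf_share = nrow(upf),
      analysis_rows = nrow(analysis_table)
    )
  )

  result <- structure(list(
    upf_share = upf, profiles = profiles, scores = scores,
    analysis_table = analysis_table, table1 = table1, table2 = table2,
    table2_full = table2_full, table3 = table3, moderation = moderation,
    exclusions = filt$ledger, manifest = manifest
  ), class = "plantupf_result")

  if (!is.null(out_dir)) {
    run_stage("write_outputs", write_results(result, out_dir))
  }
  result
}

#' Write pipeline results to a directory
#'
#' CSV outputs carry full precision; two-decimal rounding is a display
#' concern left to the reader.
#'
#' @param result A `plantupf_result`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  upf_out <- result$upf_share[, c("participant_id", "total_energy_kcal",
                                  "pct_energy_upf")]
  utils::write.csv(upf_out, file.path(out_dir, "upf_share.csv"),
                   row.names = FALSE)
  scores_out <- merge(component_scores_wide(result$scores$components),
                      result$scores$indices, by = "participant_id")
  utils::write.csv(scores_out, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  write_cutpoints_yaml(result$scores$cutpoints,
                       file.path(out_dir, "cutpoints.yaml"))
  for (i in names(result$table1)) {
    utils::write.csv(result$table1[[i]]$cells,
                     file.path(out_dir, paste0("table1_", i, "_cells.csv")),
                     row.names = FALSE)
    utils::write.csv(result$table1[[i]]$trend,
                     file.path(out_dir, paste0("table1_", i, "_trend.csv")),
                     row.names = FALSE)
  }
  utils::write.csv(result$table2, file.path(out_dir, "table2.csv"),
                   row.names = FALSE)
  utils::write.csv(result$table3, file.path(out_dir, "table3.csv"),
                   row.names = FALSE)
  if (!is.null(result$moderation)) {
    utils::write.csv(result$moderation$interactions,
                     file.path(out_dir, "moderation_interactions.csv"),
                     row.names = FALSE)
    utils::write.csv(result$moderation$subgroups,
                     file.path(out_dir, "moderation_subgroups.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
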
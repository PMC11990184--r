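#' Per-participant daily servings across the 18 analysis groups
#'
#' Sums, for every participant and analysis group, `grams / 100 x
#' servings_per_100g` over all recall items. Groups a participant did not
#' consume are zero-filled, so every profile carries all 18 groups.
#'
#' @param items Recall items (post-disaggregation): `participant_id`,
#'   `food_code`, `grams`.
#' @param apportionment Collapsed apportionment from [collapse_groups()]:
#'   `food_code`, `analysis_group`, `servings_per_100g`.
#' @param scheme A `plantupf_scheme` supplying the group order.
#' @return Data.frame with `participant_id` and one numeric servings/day
#'   column per analysis group.
#' @export
servings_profile <- function(items, apportionment,
                             scheme = default_group_scheme()) {
  scheme <- validate_group_scheme(scheme)
  require_cols(items, c("participant_id", "food_code", "grams"), "items")
  require_cols(apportionment,
               c("food_code", "analysis_group", "servings_per_100g"),
               "apportionment")
  items$food_code <- normalize_food_code(items$food_code)
  missing <- setdiff(items$food_code, apportionment$food_code)
  if (length(missing) > 0L) {
    stop("item food_code(s) missing from apportionment: ",
         paste(utils::head(missing, 10L), collapse = ", "), call. = FALSE)
  }
  joined <- merge(items[, c("participant_id", "food_code", "grams")],
                  apportionment, by = "food_code", sort = FALSE)
  joined$servings <- joined$grams / 100 * joined$servings_per_100g
  mat <- tapply(joined$servings,
                list(factor(joined$participant_id),
                     factor(joined$analysis_group,
                            levels = scheme$analysis_groups)),
                sum, default = 0)
  out <- data.frame(participant_id = rownames(mat), stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(mat, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Weighted quantiles (left-continuous inverse of the weighted ECDF)
#'
#' `Q(p) = inf { x : F_w(x) >= p }` where `F_w` is the weighted empirical
#' distribution function. With equal weights this reproduces the usual
#' type-1 sample quantile. Quantiles are invariant to rescaling all weights.
#'
#' @param x Numeric values.
#' @param w Positive weights (recycled if scalar); default equal.
#' @param probs Probabilities in (0, 1].
#' @return Numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w = NULL, probs) {
  stopifnot(length(x) > 0L, all(probs > 0), all(probs <= 1))
  if (is.null(w)) w <- rep(1, length(x))
  if (length(w) == 1L) w <- rep(w, length(x))
  stopifnot(length(w) == length(x), all(w >= 0), sum(w) > 0)
  ord <- order(x)
  xs <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  vapply(probs, function(p) xs[which(cw >= p - 1e-12)[1L]], numeric(1L))
}

#' Population-specific quintile cutpoints per analysis group
#'
#' Computes the weighted 20/40/60/80th percentiles of each group's
#' servings/day distribution over the included population. With heavy zero
#' inflation (e.g. legumes on a single recall day) several cutpoints can
#' coincide at 0; such degenerate groups are reported via a log message and
#' the tie rule in [assign_quintile()] handles them deterministically.
#'
#' @param profiles Servings profiles from [servings_profile()].
#' @param design Optional `plantupf_design`; its person weights are used when
#'   `use_weights` is `TRUE`.
#' @param use_weights Compute cutpoints on the survey-weighted distribution
#'   (default) or unweighted.
#' @param quiet Suppress the degeneracy log message.
#' @return Data.frame `analysis_group`, `c1`..`c4`, `weighted`, `degenerate`.
#' @export
quintile_cutpoints <- function(profiles, design = NULL, use_weights = TRUE,
                               quiet = FALSE) {
  groups <- setdiff(names(profiles), "participant_id")
  if (nrow(profiles) < 5L) {
    stop("need at least 5 participants to form quintiles", call. = FALSE)
  }
  w <- NULL
  weighted <- FALSE
  if (isTRUE(use_weights) && !is.null(design)) {
    stopifnot(inherits(design, "plantupf_design"))
    idx <- match(profiles$participant_id, design$participant_id)
    if (anyNA(idx)) {
      stop("design is missing weights for some participants", call. = FALSE)
    }
    w <- design$person_weight[idx]
    weighted <- TRUE
  }
  cuts <- t(vapply(groups, function(g) {
    weighted_quantile(profiles[[g]], w, probs = c(0.2, 0.4, 0.6, 0.8))
  }, numeric(4L)))
  out <- data.frame(analysis_group = groups,
                    c1 = cuts[, 1L], c2 = cuts[, 2L],
                    c3 = cuts[, 3L], c4 = cuts[, 4L],
                    weighted = weighted,
                    stringsAsFactors = FALSE)
  out$degenerate <- (out$c1 == out$c2) | (out$c2 == out$c3) |
    (out$c3 == out$c4)
  if (any(out$degenerate)) {
    log_msg(quiet, "degenerate quintile cutpoints (tied boundaries) in: %s",
            paste(out$analysis_group[out$degenerate], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' Assign consumption quintiles given cutpoints
#'
#' Intervals are half-open with ties falling low: quintile
#' `1 + #(value > c_k)`, i.e. `(-Inf, c1], (c1, c2], ..., (c4, Inf)`. When
#' cutpoints collapse (zero-inflated groups), all tied values share the
#' lowest applicable quintile, so non-consumers of a group always land in
#' quintile 1.
#'
#' @param values Numeric servings (or any scores to be binned).
#' @param cutpoints Numeric length-4 non-decreasing vector, or a one-row slice
#'   of the [quintile_cutpoints()] output.
#' @return Integer vector of quintiles in 1..5.
#' @export
assign_quintile <- function(values, cutpoints) {
  if (is.data.frame(cutpoints)) {
    stopifnot(nrow(cutpoints) == 1L)
    cutpoints <- as.numeric(cutpoints[1L, c("c1", "c2", "c3", "c4")])
  }
  stopifnot(length(cutpoints) == 4L, !is.unsorted(cutpoints))
  q <- 1L + (values > cutpoints[1L]) + (values > cutpoints[2L]) +
    (values > cutpoints[3L]) + (values > cutpoints[4L])
  as.integer(q)
}

#' Component score for one food group under one index
#'
#' Forward scoring gives the quintile itself (1 for the lowest consumption
#' quintile, 5 for the highest); reverse scoring gives `6 - quintile`.
#' The overall PDI scores every plant group forward and every animal group in
#' reverse; the healthful hPDI scores only healthy plant groups forward; the
#' unhealthful uPDI scores only unhealthy plant groups forward. Animal groups
#' are reverse-scored under all three indices.
#'
#' @param quintile Integer vector in 1..5.
#' @param health_class Character vector: `"healthy_plant"`,
#'   `"unhealthy_plant"` or `"animal"`.
#' @param index_type One of `"pdi"`, `"hpdi"`, `"updi"`.
#' @return Integer scores in 1..5.
#' @export
score_component <- function(quintile, health_class, index_type) {
  index_type <- match.arg(tolower(index_type), c("pdi", "hpdi", "updi"))
  stopifnot(all(quintile %in% 1:5),
            all(health_class %in% c("healthy_plant", "unhealthy_plant",
                                    "animal")))
  forward <- switch(index_type,
    pdi = health_class %in% c("healthy_plant", "unhealthy_plant"),
    hpdi = health_class == "healthy_plant",
    updi = health_class == "unhealthy_plant"
  )
  n <- max(length(quintile), length(forward))
  quintile <- rep_len(as.integer(quintile), n)
  forward <- rep_len(forward, n)
  ifelse(forward, quintile, 6L - quintile)
}

#' Component scores for all participants, groups and indices
#'
#' @param profiles Servings profiles from [servings_profile()].
#' @param cutpoints Output of [quintile_cutpoints()].
#' @param scheme A `plantupf_scheme`.
#' @return Long data.frame: `participant_id`, `analysis_group`,
#'   `health_class`, `quintile`, `score_pdi`, `score_hpdi`, `score_updi`.
#' @export
component_scores <- function(profiles, cutpoints,
                             scheme = default_group_scheme()) {
  scheme <- validate_group_scheme(scheme)
  groups <- scheme$analysis_groups
  missing <- setdiff(groups, cutpoints$analysis_group)
  if (length(missing) > 0L) {
    stop("cutpoints missing for group(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pieces <- lapply(groups, function(g) {
    cp <- cutpoints[cutpoints$analysis_group == g, , drop = FALSE]
    q <- assign_quintile(profiles[[g]], cp)
    hc <- unname(scheme$health_class[[g]])
    data.frame(
      participant_id = profiles$participant_id,
      analysis_group = g,
      health_class = hc,
      quintile = q,
      score_pdi = score_component(q, hc, "pdi"),
      score_hpdi = score_component(q, hc, "hpdi"),
      score_updi = score_component(q, hc, "updi"),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Sum component scores into the three indices
#'
#' Each index is the sum of its 18 component scores, giving a possible range
#' of 18 to 90 per index.
#'
#' @param components Long component-score table from [component_scores()].
#' @return Data.frame `participant_id`, `pdi`, `hpdi`, `updi` (integers).
#' @export
compute_indices <- function(components) {
  require_cols(components,
               c("participant_id", "analysis_group", "score_pdi",
                 "score_hpdi", "score_updi"), "components")
  n_comp <- table(components$participant_id)
  if (any(n_comp != 18L)) {
    stop("each participant must have exactly 18 component scores; offending: ",
         paste(utils::head(names(n_comp)[n_comp != 18L], 5L), collapse = ", "),
         call. = FALSE)
  }
  pid <- factor(components$participant_id)
  out <- data.frame(
    participant_id = levels(pid),
    pdi = as.integer(tapply(components$score_pdi, pid, sum)),
    hpdi = as.integer(tapply(components$score_hpdi, pid, sum)),
    updi = as.integer(tapply(components$score_updi, pid, sum)),
    stringsAsFactors = FALSE
  )
  stopifnot(all(out$pdi >= 18L & out$pdi <= 90L),
            all(out$hpdi >= 18L & out$hpdi <= 90L),
            all(out$updi >= 18L & out$updi <= 90L))
  rownames(out) <- NULL
  out
}

#' Score the three plant-based diet indices in one call
#'
#' Convenience wrapper: quintile cutpoints, component scores and index sums.
#'
#' @inheritParams quintile_cutpoints
#' @param scheme A `plantupf_scheme`.
#' @return List with `cutpoints`, `components`, `indices`.
#' @export
pdi_scores <- function(profiles, scheme = default_group_scheme(),
                       design = NULL, use_weights = TRUE, quiet = FALSE) {
  cp <- quintile_cutpoints(profiles, design = design,
                           use_weights = use_weights, quiet = quiet)
  comp <- component_scores(profiles, cp, scheme)
  list(cutpoints = cp, components = comp, indices = compute_indices(comp))
}

#' Write quintile cutpoints to a YAML audit file
#' @param cutpoints Output of [quintile_cutpoints()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cutpoints_yaml <- function(cutpoints, path) {
  entries <- lapply(seq_len(nrow(cutpoints)), function(i) {
    list(analysis_group = cutpoints$analysis_group[i],
         cutpoints = as.numeric(cutpoints[i, c("c1", "c2", "c3", "c4")]),
         weighted = cutpoints$weighted[i],
         degenerate = cutpoints$degenerate[i])
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}
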
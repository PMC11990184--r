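#' Survey design with person and replicate weights
#'
#' Holds the person (sampling) weight and the R sets of replicate weights
#' used for variance estimation. Variance of any weighted statistic theta is
#' estimated as `variance_scale x sum_r (theta_r - theta)^2` over the
#' replicate estimates, the generic delete-a-group jackknife form; the
#' default scale `(R - 1) / R` corresponds to that scheme.
#'
#' @param participant_id Identifier vector.
#' @param person_weight Positive person weights.
#' @param replicate_weights Matrix or data.frame, one column per replicate
#'   (R >= 2), non-negative entries.
#' @param variance_scale Multiplier for the replicate sum of squares.
#' @return An object of class `plantupf_design`.
#' @export
survey_design <- function(participant_id, person_weight, replicate_weights,
                          variance_scale = NULL) {
  replicate_weights <- as.matrix(replicate_weights)
  n <- length(participant_id)
  stopifnot(length(person_weight) == n,
            nrow(replicate_weights) == n,
            ncol(replicate_weights) >= 2L,
            all(person_weight > 0),
            all(replicate_weights >= 0))
  if (anyDuplicated(participant_id)) {
    stop("duplicate participant_id in survey design", call. = FALSE)
  }
  R <- ncol(replicate_weights)
  if (is.null(variance_scale)) variance_scale <- (R - 1) / R
  structure(list(participant_id = as.character(participant_id),
                 person_weight = as.numeric(person_weight),
                 replicate_weights = replicate_weights,
                 n_replicates = R,
                 variance_scale = variance_scale),
            class = "plantupf_design")
}

#' @export
print.plantupf_design <- function(x, ...) {
  cat(sprintf("<plantupf_design> %d participants, %d replicate weights, variance scale %.4f\n",
              length(x$participant_id), x$n_replicates, x$variance_scale))
  invisible(x)
}

# Align design weights to a vector of participant ids.
align_design <- function(design, ids) {
  stopifnot(inherits(design, "plantupf_design"))
  idx <- match(as.character(ids), design$participant_id)
  if (anyNA(idx)) {
    stop("survey design is missing weights for participant(s): ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  list(w = design$person_weight[idx],
       repw = design$replicate_weights[idx, , drop = FALSE])
}

#' Sequential cohort filter with exclusion ledger
#'
#' Applies the inclusion criteria in order — age under 19, pregnancy,
#' breastfeeding, missing UPF intake data — counting exclusions at each step
#' so the resulting ledger mirrors a participant flow diagram.
#'
#' @param participants Data.frame with `participant_id`, `age`, and logical
#'   columns `pregnant`, `breastfeeding`, `missing_upf`.
#' @param quiet Suppress the ledger log message.
#' @return List with `included` (the surviving rows) and `ledger` (named
#'   integer vector of sequential exclusion counts).
#' @export
filter_cohort <- function(participants, quiet = FALSE) {
  require_cols(participants,
               c("participant_id", "age", "pregnant", "breastfeeding",
                 "missing_upf"), "participants")
  ledger <- c(initial = nrow(participants))
  keep <- participants
  drop_step <- function(keep, flag, name, ledger) {
    n_drop <- sum(flag)
    ledger[[name]] <- n_drop
    list(keep = keep[!flag, , drop = FALSE], ledger = ledger)
  }
  s <- drop_step(keep, keep$age < 19, "under19", ledger)
  s <- drop_step(s$keep, s$keep$pregnant, "pregnant", s$ledger)
  s <- drop_step(s$keep, s$keep$breastfeeding, "breastfeeding", s$ledger)
  s <- drop_step(s$keep, s$keep$missing_upf, "missing_upf", s$ledger)
  ledger <- c(s$ledger, included = nrow(s$keep))
  log_msg(quiet, "cohort filter: %s",
          paste(sprintf("%s=%d", names(ledger), ledger), collapse = ", "))
  list(included = s$keep, ledger = ledger)
}

# Weighted mean of v under weights w.
wmean <- function(v, w) sum(w * v) / sum(w)

#' Survey-weighted estimate with replicate-based standard error
#'
#' Point estimate from the person weights; the standard error is the square
#' root of `variance_scale x sum_r (theta_r - theta)^2` over replicate-weight
#' re-estimates.
#'
#' @param values Numeric vector (for `statistic = "mean"`) or any vector (for
#'   `statistic = "proportion"` together with `level`).
#' @param design A `plantupf_design`.
#' @param ids Participant ids aligning `values` with the design.
#' @param statistic `"mean"` or `"proportion"`.
#' @param level For proportions, the level whose weighted share is estimated.
#' @param domain Optional logical vector restricting estimation to a
#'   subpopulation (weights outside the domain are zeroed, survey-style).
#' @return List with `estimate`, `se`, `statistic`.
#' @export
weighted_estimate <- function(values, design, ids,
                              statistic = c("mean", "proportion"),
                              level = NULL, domain = NULL) {
  statistic <- match.arg(statistic)
  al <- align_design(design, ids)
  v <- if (statistic == "proportion") {
    if (is.null(level)) stop("proportion estimates need a level", call. = FALSE)
    as.numeric(values == level)
  } else {
    as.numeric(values)
  }
  dom <- if (is.null(domain)) rep(TRUE, length(v)) else domain
  w <- al$w * dom
  if (sum(w) <= 0) stop("zero total weight", call. = FALSE)
  est <- wmean(v, w)
  reps <- vapply(seq_len(ncol(al$repw)), function(r) {
    wr <- al$repw[, r] * dom
    if (sum(wr) <= 0) est else wmean(v, wr)
  }, numeric(1L))
  se <- sqrt(design$variance_scale * sum((reps - est)^2))
  list(estimate = est, se = se, statistic = statistic)
}

# Canonical factor coding for the covariate set.
covariate_levels <- list(
  sex = c("female", "male"),
  education = c("low", "medium", "high"),
  country_of_birth = c("Australia", "main_english_speaking", "other"),
  rurality = c("major_city", "inner_regional", "other"),
  area_disadvantage = c("Q1", "Q2", "Q3", "Q4", "Q5")
)

#' Coerce covariate columns to their canonical factor coding
#' @param data Data.frame possibly holding covariate columns.
#' @return `data` with recognised covariates as ordered-reference factors.
#' @export
prepare_covariates <- function(data) {
  for (nm in names(covariate_levels)) {
    if (nm %in% names(data) && !is.factor(data[[nm]])) {
      bad <- setdiff(unique(as.character(data[[nm]])), covariate_levels[[nm]])
      if (length(bad) > 0L) {
        stop(sprintf("unexpected level(s) for %s: %s", nm,
                     paste(bad, collapse = ", ")), call. = FALSE)
      }
      data[[nm]] <- factor(data[[nm]], levels = covariate_levels[[nm]])
    }
  }
  data
}

covariate_rhs <- "age + sex + education + country_of_birth + rurality + area_disadvantage"

#' Survey-weighted linear regression with replicate-weight inference
#'
#' Weighted least squares for the point estimates; standard errors from the
#' replicate weights (`variance_scale x sum_r (b_r - b)^2` per coefficient),
#' with large-sample normal 95% confidence intervals and p-values.
#'
#' @param formula Model formula.
#' @param data Data.frame containing `participant_id` and model variables.
#' @param design A `plantupf_design`.
#' @param model_tag Label stored alongside the results (e.g. `"crude"`).
#' @return Data.frame `term`, `beta`, `se`, `ci_low`, `ci_high`, `p_value`,
#'   `model_tag`, with attribute `n` (rows used).
#' @export
weighted_linear_fit <- function(formula, data, design, model_tag = "") {
  data <- prepare_covariates(data)
  mf <- stats::model.frame(formula, data)
  X <- stats::model.matrix(formula, mf)
  y <- stats::model.response(mf)
  al <- align_design(design, data$participant_id)
  w <- al$w

  # A constant column is indistinguishable from the intercept; absorb it
  # rather than failing, so e.g. a constant misreporting covariate leaves
  # the other coefficients untouched.
  if ("(Intercept)" %in% colnames(X) && ncol(X) > 1L) {
    const <- vapply(seq_len(ncol(X)), function(j) {
      colnames(X)[j] != "(Intercept)" && length(unique(X[, j])) == 1L
    }, logical(1L))
    if (any(const)) {
      message("constant term(s) absorbed into the intercept: ",
              paste(colnames(X)[const], collapse = ", "))
      X <- X[, !const, drop = FALSE]
    }
  }

  qrX <- qr(X * sqrt(w))
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design matrix; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  beta <- stats::lm.wfit(X, y, w)$coefficients
  B <- vapply(seq_len(ncol(al$repw)), function(r) {
    stats::lm.wfit(X, y, al$repw[, r])$coefficients
  }, numeric(ncol(X)))
  if (anyNA(B)) {
    stop("replicate fit rank-deficient; increase replicate group sizes",
         call. = FALSE)
  }
  se <- sqrt(design$variance_scale * rowSums((B - beta)^2))
  z <- qnorm_975()
  zstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  out <- data.frame(
    term = colnames(X),
    beta = unname(beta),
    se = unname(se),
    ci_low = unname(beta - z * se),
    ci_high = unname(beta + z * se),
    p_value = 2 * stats::pnorm(-abs(zstat)),
    model_tag = model_tag,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n") <- nrow(mf)
  out
}

qnorm_975 <- function() stats::qnorm(0.975)

#' Regressions of UPF energy share on the three diet indices
#'
#' The nine headline fits: outcome = percent of daily energy from
#' ultra-processed foods, exposure = PDI, hPDI or uPDI (continuous), under
#' three adjustment sets — crude; model 1 adds age, sex, education, country
#' of birth, rurality and area-level disadvantage; model 2 adds the EI:BMR
#' energy-misreporting ratio. Setting `transpose = TRUE` swaps outcome and
#' exposure for sensitivity analysis.
#'
#' @param analysis_table Data.frame with `participant_id`, `pct_energy_upf`,
#'   `pdi`, `hpdi`, `updi`, the covariates and `ei_bmr_ratio`.
#' @param design A `plantupf_design`.
#' @param transpose Regress the index on UPF share instead.
#' @return Data.frame of all coefficient rows with columns `index`, `model_tag`
#'   plus the [weighted_linear_fit()] columns; the exposure row carries
#'   `is_index_term = TRUE`.
#' @export
fit_index_models <- function(analysis_table, design, transpose = FALSE) {
  models <- list(
    crude = "%s ~ %s",
    model1 = paste0("%s ~ %s + ", covariate_rhs),
    model2 = paste0("%s ~ %s + ", covariate_rhs, " + ei_bmr_ratio")
  )
  out <- list()
  for (index in c("pdi", "hpdi", "updi")) {
    lhs <- if (transpose) index else "pct_energy_upf"
    rhs_var <- if (transpose) "pct_energy_upf" else index
    for (tag in names(models)) {
      f <- stats::as.formula(sprintf(models[[tag]], lhs, rhs_var))
      fit <- weighted_linear_fit(f, analysis_table, design, model_tag = tag)
      fit$index <- index
      fit$is_index_term <- fit$term == rhs_var
      out[[paste(index, tag)]] <- fit
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract the index-coefficient summary (Table 2 shape)
#' @param results Output of [fit_index_models()].
#' @return One row per index x model: `index`, `model_tag`, `beta`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
table2_shape <- function(results) {
  res <- results[results$is_index_term,
                 c("index", "model_tag", "beta", "ci_low", "ci_high",
                   "p_value")]
  rownames(res) <- NULL
  res
}

#' Component-score associations with UPF energy share (Table 3 shape)
#'
#' One fully adjusted (model 2) fit per plant food group and index, with the
#' group's component score under that index as the exposure and UPF percent
#' energy as the outcome. Because animal groups are reverse-scored
#' identically under all three indices, the six animal component scores are
#' summed into one combined regressor fitted once.
#'
#' @param analysis_table As in [fit_index_models()].
#' @param components Long component-score table from [component_scores()].
#' @param design A `plantupf_design`.
#' @param scheme A `plantupf_scheme`.
#' @return Data.frame `index`, `component`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `p_value`.
#' @export
component_associations <- function(analysis_table, components, design,
                                   scheme = default_group_scheme()) {
  scheme <- validate_group_scheme(scheme)
  rhs <- paste0(" + ", covariate_rhs, " + ei_bmr_ratio")
  plant_groups <- scheme$analysis_groups[
    scheme$health_class[scheme$analysis_groups] != "animal"]
  animal_groups <- setdiff(scheme$analysis_groups, plant_groups)

  fit_one <- function(score_df, index, component) {
    tab <- merge(analysis_table, score_df, by = "participant_id", sort = FALSE)
    f <- stats::as.formula(paste0("pct_energy_upf ~ component_score", rhs))
    fit <- weighted_linear_fit(f, tab, design, model_tag = "model2")
    row <- fit[fit$term == "component_score", ]
    data.frame(index = index, component = component,
               beta = row$beta, se = row$se, ci_low = row$ci_low,
               ci_high = row$ci_high, p_value = row$p_value,
               stringsAsFactors = FALSE)
  }

  out <- list()
  for (index in c("pdi", "hpdi", "updi")) {
    score_col <- paste0("score_", index)
    for (g in plant_groups) {
      sub <- components[components$analysis_group == g, ]
      score_df <- data.frame(participant_id = sub$participant_id,
                             component_score = sub[[score_col]],
                             stringsAsFactors = FALSE)
      out[[paste(index, g)]] <- fit_one(score_df, index, g)
    }
  }
  # Animal groups: identical scores under all indices; one combined term.
  anim <- components[components$analysis_group %in% animal_groups, ]
  pid <- factor(anim$participant_id)
  combined <- data.frame(
    participant_id = levels(pid),
    component_score = as.numeric(tapply(anim$score_pdi, pid, sum)),
    stringsAsFactors = FALSE
  )
  out[["animal_combined"]] <- fit_one(combined, "all", "animal_combined")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Weighted Pearson chi-squared test of homogeneity
#'
#' Pearson's chi-squared computed on weighted cell counts rescaled so their
#' total equals the unweighted sample size (with unit weights this is the
#' classical statistic). The optional first-order Rao-Scott correction
#' divides the statistic by the mean design effect of the cell proportions,
#' estimated from the replicate weights.
#'
#' @param x,g Factors (or vectors coerced to factors) defining the table.
#' @param design Optional `plantupf_design` (required for `rao_scott`).
#' @param ids Participant ids aligning rows with the design.
#' @param w Explicit weights (unit weights if neither `w` nor `design` given).
#' @param rao_scott Apply the first-order correction.
#' @return List `statistic`, `df`, `p_value`.
#' @export
weighted_chisq <- function(x, g, design = NULL, ids = NULL, w = NULL,
                           rao_scott = FALSE) {
  x <- factor(x)
  g <- factor(g)
  n <- length(x)
  if (is.null(w)) {
    w <- if (is.null(design)) rep(1, n) else align_design(design, ids)$w
  }
  W <- tapply(w, list(x, g), sum, default = 0)
  C <- W / sum(W) * n
  E <- outer(rowSums(C), colSums(C)) / n
  valid <- E > 0
  stat <- sum((C[valid] - E[valid])^2 / E[valid])
  df <- (nlevels(x) - 1L) * (nlevels(g) - 1L)

  if (isTRUE(rao_scott)) {
    if (is.null(design)) {
      stop("rao_scott correction requires a survey design", call. = FALSE)
    }
    al <- align_design(design, ids)
    deffs <- c()
    for (lx in levels(x)) {
      for (lg in levels(g)) {
        v <- as.numeric(x == lx & g == lg)
        p <- wmean(v, al$w)
        if (p <= 0 || p >= 1) next
        reps <- vapply(seq_len(ncol(al$repw)), function(r) {
          wmean(v, al$repw[, r])
        }, numeric(1L))
        v_rep <- design$variance_scale * sum((reps - p)^2)
        v_srs <- p * (1 - p) / n
        deffs <- c(deffs, v_rep / v_srs)
      }
    }
    if (length(deffs) > 0L && mean(deffs) > 0) stat <- stat / mean(deffs)
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Descriptive table by index quintile with trend tests (Table 1 shape)
#'
#' Participants are binned into weighted quintiles of the chosen index
#' (cutpoints from [weighted_quantile()], tie rule from
#' [assign_quintile()]). Continuous rows report the weighted mean and
#' replicate-based SE per quintile and a p-trend from a weighted regression
#' of the variable on quintile number (1-5, continuous); categorical rows
#' report weighted percentages per quintile and a weighted Pearson
#' chi-squared p across quintiles.
#'
#' @param analysis_table Data.frame with the index column, continuous
#'   variables `age`, `total_energy_kcal`, `pct_energy_upf` and the covariate
#'   set.
#' @param design A `plantupf_design`.
#' @param index One of `"pdi"`, `"hpdi"`, `"updi"`.
#' @param rao_scott Apply the Rao-Scott correction in the categorical tests.
#' @return List with `cells` (variable, level, quintile, estimate, se),
#'   `trend` (variable, p_trend, test_kind), `cutpoints`, and `quintile`
#'   (per-participant assignment).
#' @export
quintile_table <- function(analysis_table, design, index = "pdi",
                           rao_scott = FALSE) {
  index <- match.arg(index, c("pdi", "hpdi", "updi"))
  tab <- prepare_covariates(analysis_table)
  al <- align_design(design, tab$participant_id)
  cp <- weighted_quantile(tab[[index]], al$w, probs = c(0.2, 0.4, 0.6, 0.8))
  qnum <- assign_quintile(tab[[index]], cp)

  continuous <- intersect(c("age", "total_energy_kcal", "pct_energy_upf"),
                          names(tab))
  categorical <- intersect(names(covariate_levels), names(tab))
  categorical <- setdiff(categorical, "age")

  cells <- list()
  trend <- list()
  for (v in continuous) {
    for (q in 1:5) {
      est <- weighted_estimate(tab[[v]], design, tab$participant_id,
                               statistic = "mean", domain = qnum == q)
      cells[[paste(v, q)]] <- data.frame(
        variable = v, level = NA_character_, quintile = q,
        estimate = est$estimate, se = est$se, stringsAsFactors = FALSE)
    }
    tr <- weighted_linear_fit(
      stats::as.formula(paste(v, "~ quintile_number")),
      cbind(tab, quintile_number = qnum), design, model_tag = "trend")
    trend[[v]] <- data.frame(
      variable = v, p_trend = tr$p_value[tr$term == "quintile_number"],
      test_kind = "linear", stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    lev <- levels(tab[[v]])
    for (l in lev) {
      for (q in 1:5) {
        est <- weighted_estimate(tab[[v]], design, tab$participant_id,
                                 statistic = "proportion", level = l,
                                 domain = qnum == q)
        cells[[paste(v, l, q)]] <- data.frame(
          variable = v, level = l, quintile = q,
          estimate = 100 * est$estimate, se = 100 * est$se,
          stringsAsFactors = FALSE)
      }
    }
    ch <- weighted_chisq(tab[[v]], factor(qnum), design = design,
                         ids = tab$participant_id, rao_scott = rao_scott)
    trend[[v]] <- data.frame(variable = v, p_trend = ch$p_value,
                             test_kind = "chi2", stringsAsFactors = FALSE)
  }
  cells <- do.call(rbind, cells)
  trend <- do.call(rbind, trend)
  rownames(cells) <- rownames(trend) <- NULL
  list(cells = cells, trend = trend, cutpoints = cp, quintile = qnum)
}

#' Moderation of the index-UPF association by age, sex and education
#'
#' Augments the fully adjusted (model 2) regression with index x moderator
#' interaction terms, one moderator at a time, and reports the interaction
#' coefficients with replicate-based inference. Subgroup fits (model 2
#' within each level of a categorical moderator, or below/above the weighted
#' median for age) are emitted alongside.
#'
#' @param analysis_table As in [fit_index_models()].
#' @param design A `plantupf_design`.
#' @param index One of `"pdi"`, `"hpdi"`, `"updi"`.
#' @param moderators Subset of `c("age", "sex", "education")`.
#' @return List with `interactions` (coefficient rows for the product terms)
#'   and `subgroups` (index beta per moderator level).
#' @export
moderation_models <- function(analysis_table, design, index = "updi",
                              moderators = c("age", "sex", "education")) {
  index <- match.arg(index, c("pdi", "hpdi", "updi"))
  moderators <- match.arg(moderators, c("age", "sex", "education"),
                          several.ok = TRUE)
  tab <- prepare_covariates(analysis_table)
  base_rhs <- paste0(index, " + ", covariate_rhs, " + ei_bmr_ratio")

  interactions <- list()
  subgroups <- list()
  for (m in moderators) {
    f <- stats::as.formula(paste0("pct_energy_upf ~ ", base_rhs, " + ",
                                  index, ":", m))
    fit <- weighted_linear_fit(f, tab, design,
                               model_tag = paste0("model2+", index, "x", m))
    inter <- fit[grepl(paste0("^", index, ":"), fit$term), , drop = FALSE]
    inter$index <- index
    inter$moderator <- m
    interactions[[m]] <- inter

    if (m == "age") {
      al <- align_design(design, tab$participant_id)
      med <- weighted_quantile(tab$age, al$w, probs = 0.5)
      lev_list <- list(below_median_age = tab$age <= med,
                       above_median_age = tab$age > med)
    } else {
      lev_list <- lapply(levels(tab[[m]]), function(l) tab[[m]] == l)
      names(lev_list) <- levels(tab[[m]])
    }
    for (lname in names(lev_list)) {
      sub <- tab[lev_list[[lname]], , drop = FALSE]
      # Drop the moderator from the adjustment set inside its own stratum.
      rhs_terms <- c(index, "age", "sex", "education", "country_of_birth",
                     "rurality", "area_disadvantage", "ei_bmr_ratio")
      rhs_terms <- setdiff(rhs_terms, m)
      fsub <- stats::as.formula(paste0("pct_energy_upf ~ ",
                                       paste(rhs_terms, collapse = " + ")))
      fit_sub <- weighted_linear_fit(fsub, sub, design,
                                     model_tag = paste0("subgroup:", m))
      row <- fit_sub[fit_sub$term == index, ]
      subgroups[[paste(m, lname)]] <- data.frame(
        index = index, moderator = m, level = lname, n = attr(fit_sub, "n"),
        beta = row$beta, se = row$se, ci_low = row$ci_low,
        ci_high = row$ci_high, p_value = row$p_value,
        stringsAsFactors = FALSE)
    }
  }
  interactions <- do.call(rbind, interactions)
  subgroups <- do.call(rbind, subgroups)
  rownames(interactions) <- rownames(subgroups) <- NULL
  list(interactions = interactions, subgroups = subgroups)
}
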
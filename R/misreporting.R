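#' Schofield-type BMR prediction coefficients
#'
#' Adult basal metabolic rate predicted as a sex- and age-band-specific
#' linear function of body weight, `BMR (MJ/day) = slope x weight (kg) +
#' intercept`. The shipped default is the Schofield adult coefficient set,
#' with the youngest band running to age 30 inclusive; an alternative set
#' (e.g. Henry) can be supplied via [read_bmr_coefficients()].
#'
#' @return Data.frame `sex`, `age_min`, `age_max`, `slope`, `intercept`.
#' @export
schofield_coefficients <- function() {
  data.frame(
    sex = rep(c("male", "female"), each = 3L),
    age_min = rep(c(18, 30, 60), 2L),
    age_max = rep(c(30, 60, 120), 2L),
    slope = c(0.063, 0.048, 0.049, 0.062, 0.034, 0.038),
    intercept = c(2.896, 3.653, 2.459, 2.036, 3.538, 2.755),
    stringsAsFactors = FALSE
  )
}

#' Read / write BMR coefficient tables as YAML
#' @param path YAML file with a list of records carrying `sex`, `age_min`,
#'   `age_max`, `slope`, `intercept`.
#' @return For the reader, a coefficient data.frame; for the writer, `path`.
#' @export
read_bmr_coefficients <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- do.call(rbind, lapply(raw, function(r) {
    data.frame(sex = r$sex, age_min = r$age_min, age_max = r$age_max,
               slope = r$slope, intercept = r$intercept,
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(c("sex", "age_min", "age_max", "slope", "intercept") %in%
                  names(out)))
  out
}

#' @rdname read_bmr_coefficients
#' @param coefficients A BMR coefficient data.frame.
#' @export
write_bmr_coefficients <- function(coefficients, path) {
  yaml::write_yaml(
    lapply(seq_len(nrow(coefficients)), function(i) as.list(coefficients[i, ])),
    path)
  invisible(path)
}

#' Estimate basal metabolic rate from anthropometry
#'
#' @param anthro Data.frame `participant_id`, `sex` (`"female"`/`"male"`),
#'   `age` (years), `body_weight` (kg, may be `NA`).
#' @param coefficients Coefficient table, default [schofield_coefficients()].
#' @return Numeric BMR in MJ/day, `NA` where body weight is missing.
#' @export
estimate_bmr <- function(anthro, coefficients = schofield_coefficients()) {
  require_cols(anthro, c("participant_id", "sex", "age", "body_weight"),
               "anthropometry")
  stopifnot(all(anthro$sex %in% c("female", "male")))
  band <- vapply(seq_len(nrow(anthro)), function(i) {
    hit <- which(coefficients$sex == anthro$sex[i] &
                   anthro$age[i] >= coefficients$age_min &
                   anthro$age[i] <= coefficients$age_max)
    if (length(hit) == 0L) NA_integer_ else hit[1L]
  }, integer(1L))
  if (anyNA(band)) {
    bad <- which(is.na(band))[1L]
    stop(sprintf("no BMR coefficients for sex=%s age=%s",
                 anthro$sex[bad], anthro$age[bad]), call. = FALSE)
  }
  coefficients$slope[band] * anthro$body_weight +
    coefficients$intercept[band]
}

#' Energy intake to basal metabolic rate ratio
#'
#' The continuous energy-misreporting proxy: reported daily energy intake
#' divided by predicted BMR, both in MJ/day (the ratio is unit-free as long
#' as both are on the same scale). Misreporters are never excluded on the
#' basis of this ratio; it enters the regression models as a covariate.
#'
#' @param energy_intake Numeric, MJ/day.
#' @param bmr Numeric, MJ/day, strictly positive.
#' @return Numeric ratio.
#' @export
ei_bmr_ratio <- function(energy_intake, bmr) {
  if (any(!is.na(bmr) & bmr <= 0)) {
    stop("bmr must be > 0", call. = FALSE)
  }
  energy_intake / bmr
}

#' Misreporting covariate for the analysis table
#'
#' Joins recall energy totals with anthropometry, predicts BMR and returns
#' the EI:BMR ratio per participant. Participants with missing body weight
#' get the survey-weighted population mean ratio imputed (with a logged
#' count), so the covariate is complete for the adjusted models.
#'
#' @param energy Data.frame `participant_id`, `total_energy_kj`.
#' @param anthro Anthropometry data.frame (see [estimate_bmr()]).
#' @param design Optional `plantupf_design` used to weight the imputation
#'   mean; unweighted mean if `NULL`.
#' @param coefficients BMR coefficient table.
#' @param quiet Suppress the imputation log message.
#' @return Data.frame `participant_id`, `ei_bmr_ratio`.
#' @export
misreporting_scores <- function(energy, anthro, design = NULL,
                                coefficients = schofield_coefficients(),
                                quiet = FALSE) {
  require_cols(energy, c("participant_id", "total_energy_kj"), "energy")
  merged <- merge(energy, anthro, by = "participant_id", sort = FALSE)
  if (nrow(merged) < nrow(energy)) {
    stop("anthropometry missing for some participants", call. = FALSE)
  }
  bmr <- estimate_bmr(merged, coefficients)
  ei_mj <- merged$total_energy_kj / 1000
  ratio <- ei_bmr_ratio(ei_mj, bmr)
  if (anyNA(ratio)) {
    n_miss <- sum(is.na(ratio))
    w <- rep(1, nrow(merged))
    if (!is.null(design)) {
      idx <- match(merged$participant_id, design$participant_id)
      w <- design$person_weight[idx]
    }
    ok <- !is.na(ratio)
    ratio[!ok] <- sum(w[ok] * ratio[ok]) / sum(w[ok])
    log_msg(quiet, "imputed EI:BMR ratio for %d participant(s) missing body weight",
            n_miss)
  }
  data.frame(participant_id = merged$participant_id, ei_bmr_ratio = ratio,
             stringsAsFactors = FALSE)
}
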
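#' A study participant's anthropometry
#'
#' @param id Identifier.
#' @param sex `"female"` or `"male"`.
#' @param age_years Age in years.
#' @param weight_kg Body weight in kg.
#' @param height_m Height in metres (optional; only needed by
#'   weight-and-height BMR equations or g/kg guideline units).
#' @return Object of class `participant`. Values outside plausible adult
#'   ranges (age 18-110, weight 25-300 kg, height 1.2-2.3 m) raise warnings,
#'   not errors: self-reported anthropometry is noisy.
#' @export
participant <- function(id, sex, age_years, weight_kg, height_m = NA_real_) {
  sex <- match.arg(sex, c("female", "male"))
  if (age_years <= 0 || weight_kg <= 0) stop("age and weight must be positive")
  if (age_years < 18 || age_years > 110) {
    warning("participant ", id, ": age ", age_years, " outside 18-110")
  }
  if (weight_kg < 25 || weight_kg > 300) {
    warning("participant ", id, ": weight ", weight_kg, " outside 25-300 kg")
  }
  if (!is.na(height_m) && (height_m < 1.2 || height_m > 2.3)) {
    warning("participant ", id, ": height ", height_m, " outside 1.2-2.3 m")
  }
  structure(list(id = id, sex = sex, age_years = age_years,
                 weight_kg = weight_kg, height_m = height_m),
            class = "participant")
}

#' Henry basal-metabolic-rate prediction coefficients
#'
#' Coefficient tables for the Henry (Oxford) BMR equations, shipped as
#' editable CSV under `inst/extdata` rather than hard-coded: each row gives
#' `BMR = a_weight * weight_kg + b_height * height_m + c_const` in the row's
#' unit for one sex and age band. The default set is the weight-only adult
#' equations (self-reported height is noisier than self-reported weight);
#' `variant = "weight_height"` loads the weight-and-height set.
#'
#' @param variant `"weight_only"` or `"weight_height"`.
#' @param path Optional path to a custom coefficient CSV with columns
#'   `sex, age_lo, age_hi, a_weight, b_height, c_const, unit`.
#' @return Data frame of class `bmr_coefficients`.
#' @export
henry_coefficients <- function(variant = c("weight_only", "weight_height"),
                               path = NULL) {
  variant <- match.arg(variant)
  if (is.null(path)) {
    path <- system.file("extdata",
                        paste0("henry_bmr_", variant, ".csv"),
                        package = "mealrecall")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "age_lo", "age_hi", "a_weight", "b_height", "c_const",
                "unit")
  if (!all(required %in% names(tab))) {
    stop("coefficient table must have columns: ",
         paste(required, collapse = ", "))
  }
  if (!all(tab$unit %in% c("MJ_per_day", "kcal_per_day"))) {
    stop("unit must be MJ_per_day or kcal_per_day")
  }
  # age bands must partition the adult range per sex without overlap
  for (s in unique(tab$sex)) {
    bands <- tab[tab$sex == s, ]
    bands <- bands[order(bands$age_lo), ]
    if (any(bands$age_hi[-nrow(bands)] > bands$age_lo[-1])) {
      stop("overlapping age bands for sex ", s)
    }
  }
  structure(tab, class = c("bmr_coefficients", "data.frame"))
}

KCAL_PER_MJ <- 239.005736

#' Predicted basal metabolic rate
#'
#' Looks up the coefficient row covering the participant's sex and age
#' (bands are `age_lo <= age < age_hi`) and evaluates
#' `a_weight * weight + b_height * height + c_const`, converting MJ/day to
#' kcal/day with 1 MJ = 239.005736 kcal.
#'
#' @param p A [participant()].
#' @param coeffs A [henry_coefficients()] table.
#' @return Predicted BMR in kcal/day.
#' @export
bmr <- function(p, coeffs = henry_coefficients()) {
  if (!inherits(p, "participant")) stop("p must be a participant")
  row <- coeffs[coeffs$sex == p$sex &
                  coeffs$age_lo <= p$age_years &
                  p$age_years < coeffs$age_hi, , drop = FALSE]
  if (nrow(row) == 0) {
    stop("no BMR coefficient row covers sex = ", p$sex,
         ", age = ", p$age_years)
  }
  row <- row[1, ]
  if (row$b_height != 0 && is.na(p$height_m)) {
    stop("participant ", p$id, " has no height but the coefficient row ",
         "requires one")
  }
  h <- if (is.na(p$height_m)) 0 else p$height_m
  val <- row$a_weight * p$weight_kg + row$b_height * h + row$c_const
  if (row$unit == "MJ_per_day") val <- val * KCAL_PER_MJ
  val
}

#' Goldberg screening of reported energy intake
#'
#' Classifies the ratio of reported energy intake to predicted BMR:
#' `ratio < under_cutoff` flags under-reporting and `ratio > over_cutoff`
#' over-reporting; both boundaries belong to the plausible region. The
#' default cutoffs 0.96 and 2.49 are the Goldberg limits for a single-day
#' recall. Screening is advisory — downstream comparisons accept an optional
#' exclusion mask rather than dropping participants automatically.
#'
#' @param ei_kcal Reported energy intake, kcal/day (vectorised).
#' @param bmr_kcal Predicted BMR, kcal/day (> 0).
#' @param under_cutoff,over_cutoff Goldberg cutoffs.
#' @return Data frame with columns `ratio` and `status`
#'   (factor: under / plausible / over).
#' @export
classify_misreporter <- function(ei_kcal, bmr_kcal, under_cutoff = 0.96,
                                 over_cutoff = 2.49) {
  if (any(bmr_kcal <= 0)) stop("BMR must be positive")
  if (under_cutoff >= over_cutoff) stop("cutoffs out of order")
  ratio <- ei_kcal / bmr_kcal
  status <- ifelse(ratio < under_cutoff, "under",
                   ifelse(ratio > over_cutoff, "over", "plausible"))
  data.frame(ratio = ratio,
             status = factor(status, levels = c("under", "plausible", "over")))
}

#' Screen a cohort's energy intakes
#'
#' @param participants List of [participant()]s.
#' @param energy_kcal Named numeric vector of daily energy intakes keyed by
#'   participant id.
#' @param coeffs [henry_coefficients()].
#' @param under_cutoff,over_cutoff Passed to [classify_misreporter()].
#' @return Data frame: id, bmr_kcal, ei_kcal, ratio, status.
#' @export
screen_cohort <- function(participants, energy_kcal,
                          coeffs = henry_coefficients(),
                          under_cutoff = 0.96, over_cutoff = 2.49) {
  rows <- lapply(participants, function(p) {
    ei <- energy_kcal[[as.character(p$id)]]
    if (is.null(ei)) stop("no energy intake for participant ", p$id)
    b <- bmr(p, coeffs)
    cls <- classify_misreporter(ei, b, under_cutoff, over_cutoff)
    data.frame(id = p$id, bmr_kcal = b, ei_kcal = ei, ratio = cls$ratio,
               status = cls$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
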
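#' Reference intakes for the NRF9.3 nutrient-profiling score
#'
#' NRF9.3 scores a food or meal as the sum of capped percent daily values of
#' 9 encouraged nutrients minus the percent maximal reference values of 3
#' limited nutrients, on a per-100 kcal basis. The default reference values
#' follow the published NRF9.3 description (US label daily values): protein
#' 50 g, fiber 25 g, vitamin A 800 ug RAE, vitamin C 60 mg, vitamin E 20 mg,
#' calcium 1000 mg, iron 18 mg, potassium 3500 mg, magnesium 400 mg;
#' maximal reference values saturated fat 20 g, (added) sugar 50 g, sodium
#' 2400 mg. Added sugar is rarely available in composition tables, so by
#' default total sugars substitute for it (`sugar_as_added = TRUE`, logged).
#'
#' @param dv Named numeric vector of 9 daily reference values for encouraged
#'   nutrients (keys are canonical nutrient ids).
#' @param mrv Named numeric vector of 3 maximal reference values for limited
#'   nutrients.
#' @param cap_percent Cap on each encouraged nutrient's percent contribution
#'   (default 100); limited terms are never capped.
#' @param sugar_as_added If `TRUE` the `sugar_g` key stands in for added
#'   sugar.
#' @return Object of class `reference_intakes`.
#' @export
nrf_references <- function(
    dv = c(protein_g = 50, fiber_g = 25, vitamin_a_ug = 800,
           vitamin_c_mg = 60, vitamin_e_mg = 20, calcium_mg = 1000,
           iron_mg = 18, potassium_mg = 3500, magnesium_mg = 400),
    mrv = c(satfat_g = 20, sugar_g = 50, sodium_mg = 2400),
    cap_percent = 100,
    sugar_as_added = TRUE) {
  if (length(dv) != 9) stop("NRF9.3 requires exactly 9 encouraged nutrients")
  if (length(mrv) != 3) stop("NRF9.3 requires exactly 3 limited nutrients")
  if (any(dv <= 0) || any(mrv <= 0)) stop("reference values must be positive")
  if (is.null(names(dv)) || is.null(names(mrv))) {
    stop("reference values must be named with nutrient keys")
  }
  if (!is.numeric(cap_percent) || cap_percent <= 0) {
    stop("cap_percent must be positive")
  }
  if (isTRUE(sugar_as_added) && "sugar_g" %in% names(mrv) &&
      isTRUE(getOption("mealrecall.verbose", FALSE))) {
    message("NRF9.3: total sugars substituted for added sugar")
  }
  structure(list(dv = dv, mrv = mrv, cap_percent = cap_percent,
                 sugar_as_added = isTRUE(sugar_as_added)),
            class = "reference_intakes")
}

#' NRF9.3 score of a per-100 g nutrient profile
#'
#' Amounts are first rescaled from per-100 g to per-100 kcal
#' (`amount * 100 / energy_kcal`), making the score invariant to meal energy
#' density and comparable across meals of very different weights. Encouraged
#' contributions are capped at `cap_percent` per nutrient; limited
#' contributions are uncapped. Nutrients absent from the profile count as 0.
#'
#' @param profile A `per_100g` [nutrient_vector()] with `energy_kcal` > 0.
#' @param refs A [nrf_references()] object.
#' @param basis `"per_100kcal"` (canonical, default) or `"per_100g"`
#'   (sensitivity analysis: amounts used as-is, losing scale invariance).
#' @return A single numeric score.
#' @export
nrf93 <- function(profile, refs = nrf_references(), basis = c("per_100kcal", "per_100g")) {
  stop_if_not_nv(profile, "profile")
  basis <- match.arg(basis)
  if (!inherits(refs, "reference_intakes")) stop("refs must be reference_intakes")
  amount <- function(key) {
    if (key %in% names(profile)) as.numeric(profile[[key]]) else 0
  }
  if (basis == "per_100kcal") {
    energy <- amount("energy_kcal")
    if (energy <= 0) stop("nrf93 undefined for zero-energy profile")
    rescale <- 100 / energy
  } else {
    rescale <- 1
  }
  enc <- vapply(names(refs$dv), function(k) {
    min(refs$cap_percent, 100 * amount(k) * rescale / refs$dv[[k]])
  }, numeric(1))
  lim <- vapply(names(refs$mrv), function(k) {
    100 * amount(k) * rescale / refs$mrv[[k]]
  }, numeric(1))
  sum(enc) - sum(lim)
}
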
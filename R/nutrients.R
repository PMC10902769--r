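#' Canonical nutrient keys
#'
#' The nutrient variables routinely reported by dietary recall instruments,
#' as canonical string ids with the unit embedded in the key. Unknown keys are
#' always carried through untouched by every operation in the package; this
#' vector only fixes the spelling used by the shipped configuration files and
#' the synthetic-data generator.
#'
#' @return Character vector of nutrient keys.
#' @export
canonical_nutrients <- function() {
  c(
    "energy_kcal", "protein_g", "carbohydrate_g", "sugar_g", "fiber_g",
    "fat_g", "satfat_g", "mufa_g", "pufa_g",
    "vitamin_d_ug", "folate_ug", "vitamin_c_mg",
    "calcium_mg", "iron_mg", "potassium_mg", "sodium_mg",
    "thiamin_mg", "riboflavin_mg",
    "vitamin_a_ug", "vitamin_e_mg", "magnesium_mg", "alcohol_g"
  )
}

#' Create a nutrient vector
#'
#' A nutrient vector is the universal currency of the pipeline: a named set of
#' non-negative amounts (one per nutrient key) together with a basis stating
#' what the amounts refer to: per 100 g of food (`per_100g`), a whole day
#' (`per_day`) or a single portion (`per_portion`). Arithmetic is only defined
#' between vectors sharing a basis.
#'
#' @param values Named numeric vector of non-negative amounts; names are
#'   nutrient keys such as `energy_kcal` or `sodium_mg`.
#' @param basis One of `"per_100g"`, `"per_day"`, `"per_portion"`.
#' @return An object of class `nutrient_vector`.
#' @export
nutrient_vector <- function(values = numeric(), basis) {
  basis <- match.arg(basis, c("per_100g", "per_day", "per_portion"))
  values <- unlist(values)
  if (length(values) > 0 && (is.null(names(values)) || any(!nzchar(names(values))))) {
    stop("all nutrient amounts must be named with a nutrient key")
  }
  if (anyDuplicated(names(values))) {
    stop("duplicate nutrient keys: ",
         paste(unique(names(values)[duplicated(names(values))]), collapse = ", "))
  }
  nm <- names(values)
  values <- as.numeric(values)
  names(values) <- nm
  if (any(!is.finite(values))) stop("nutrient amounts must be finite")
  if (any(values < 0)) {
    stop("negative nutrient amount for: ",
         paste(names(values)[values < 0], collapse = ", "))
  }
  structure(values, basis = basis, class = "nutrient_vector")
}

#' @export
print.nutrient_vector <- function(x, ...) {
  cat("<nutrient_vector ", attr(x, "basis"), ", ", length(x), " nutrients>\n",
      sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' @rdname nutrient_vector
#' @param x Object to test.
#' @export
is_nutrient_vector <- function(x) inherits(x, "nutrient_vector")

nv_basis <- function(x) attr(x, "basis")

stop_if_not_nv <- function(x, what = "x") {
  if (!is_nutrient_vector(x)) stop(what, " must be a nutrient_vector")
  invisible(x)
}

#' Nutrient-vector arithmetic
#'
#' Component-wise addition of two vectors of identical basis (keys are
#' unioned, absent keys treated as 0) and scaling by a non-negative scalar.
#'
#' @param x,y `nutrient_vector` objects of the same basis.
#' @return A `nutrient_vector` of the shared basis.
#' @export
nv_add <- function(x, y) {
  stop_if_not_nv(x); stop_if_not_nv(y, "y")
  if (nv_basis(x) != nv_basis(y)) {
    stop("cannot add nutrient vectors of different basis: ",
         nv_basis(x), " vs ", nv_basis(y))
  }
  keys <- union(names(x), names(y))
  xv <- stats::setNames(as.numeric(x)[match(keys, names(x))], keys)
  yv <- stats::setNames(as.numeric(y)[match(keys, names(y))], keys)
  xv[is.na(xv)] <- 0; yv[is.na(yv)] <- 0
  nutrient_vector(xv + yv, nv_basis(x))
}

#' @rdname nv_add
#' @param k Non-negative finite scalar.
#' @param basis Optional new basis for the scaled vector (e.g. a per-100 g
#'   profile scaled by weight/100 becomes `per_portion`).
#' @export
nv_scale <- function(x, k, basis = nv_basis(x)) {
  stop_if_not_nv(x)
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k < 0) {
    stop("scale factor must be a single non-negative number")
  }
  nutrient_vector(stats::setNames(as.numeric(x) * k, names(x)), basis)
}

#' @rdname nv_add
#' @param xs List of `nutrient_vector`s of one basis; empty list allowed when
#'   `basis` is supplied.
#' @export
nv_sum <- function(xs, basis = NULL) {
  if (length(xs) == 0) {
    if (is.null(basis)) stop("basis required to sum an empty list")
    return(nutrient_vector(numeric(), basis))
  }
  Reduce(nv_add, xs)
}

#' Energy conversion factors
#'
#' Metabolisable-energy factors in kcal per gram of macronutrient. Defaults
#' follow the UK/CoFID convention (protein 4, carbohydrate 3.75 as
#' monosaccharide equivalent, fat 9, alcohol 7) because the comparator
#' 24-hour-recall food list is CoFID based; they are configurable since
#' composition tables derived from other sources may embed Atwater factors
#' (carbohydrate 4).
#'
#' @param protein,carbohydrate,fat,alcohol Positive factors, kcal/g.
#' @return Named list of class `energy_factors`.
#' @export
energy_factors <- function(protein = 4, carbohydrate = 3.75, fat = 9,
                           alcohol = 7) {
  f <- list(protein = protein, carbohydrate = carbohydrate, fat = fat,
            alcohol = alcohol)
  bad <- vapply(f, function(v) !is.numeric(v) || length(v) != 1 ||
                  !is.finite(v) || v <= 0, logical(1))
  if (any(bad)) stop("energy factors must be positive: ",
                     paste(names(f)[bad], collapse = ", "))
  structure(f, class = "energy_factors")
}

#' Per-100 g profile of a multi-food meal
#'
#' The nutrient profile of an eating occasion per 100 g is the weight-weighted
#' mean of the per-100 g profiles of its constituent foods. It is invariant to
#' uniform rescaling of all food weights.
#'
#' @param profiles List of per-100 g `nutrient_vector`s, one per food.
#' @param weights_g Positive food weights in grams, same length as `profiles`.
#' @return A per-100 g `nutrient_vector`.
#' @export
meal_profile <- function(profiles, weights_g) {
  if (length(profiles) == 0) stop("meal must contain at least one food")
  if (length(profiles) != length(weights_g)) {
    stop("profiles and weights_g lengths differ")
  }
  if (any(!is.finite(weights_g)) || any(weights_g <= 0)) {
    stop("all food weights must be positive")
  }
  for (p in profiles) {
    stop_if_not_nv(p, "each food profile")
    if (nv_basis(p) != "per_100g") stop("food profiles must be per_100g")
  }
  total <- sum(weights_g)
  acc <- nutrient_vector(numeric(), "per_100g")
  for (i in seq_along(profiles)) {
    acc <- nv_add(acc, nv_scale(profiles[[i]], weights_g[i] / total))
  }
  acc
}

#' One eating occasion from a weighed diary
#'
#' @param participant_id Participant identifier.
#' @param day_index Diary day, integer >= 1.
#' @param occasion_label Free-text occasion label as recorded in the diary.
#' @param foods Data frame with columns `food_id` and `weight_g` (> 0).
#' @param food_profiles Named list mapping `food_id` to a per-100 g
#'   `nutrient_vector`.
#' @param meal_type Optional; one of `breakfast`, `light_meal`, `main_meal`,
#'   `snack`, `beverage`, or `NA` if not yet assigned.
#' @param weekend Logical stratum label (optional, default `FALSE`).
#' @return An object of class `meal_record`.
#' @export
meal_record <- function(participant_id, day_index, occasion_label, foods,
                        food_profiles, meal_type = NA_character_,
                        weekend = FALSE) {
  if (!is.data.frame(foods) || !all(c("food_id", "weight_g") %in% names(foods))) {
    stop("foods must be a data frame with columns food_id, weight_g")
  }
  if (nrow(foods) == 0) stop("meal must contain at least one food")
  if (any(foods$weight_g <= 0)) stop("food weights must be positive")
  if (!is.numeric(day_index) || day_index < 1) stop("day_index must be >= 1")
  missing_foods <- setdiff(foods$food_id, names(food_profiles))
  if (length(missing_foods) > 0) {
    stop("no composition profile for food(s): ",
         paste(missing_foods, collapse = ", "))
  }
  if (!is.na(meal_type)) {
    meal_type <- match.arg(meal_type, meal_types())
  }
  profs <- food_profiles[as.character(foods$food_id)]
  structure(
    list(
      participant_id = participant_id,
      day_index = as.integer(day_index),
      occasion_label = occasion_label,
      meal_type = meal_type,
      foods = foods,
      total_weight_g = sum(foods$weight_g),
      profile_per100g = meal_profile(profs, foods$weight_g),
      weekend = isTRUE(weekend)
    ),
    class = "meal_record"
  )
}

#' @rdname meal_record
#' @export
meal_types <- function() {
  c("breakfast", "light_meal", "main_meal", "snack", "beverage")
}

#' Macronutrient contribution to total energy intake
#'
#' Percentage of total energy intake (%TEI) contributed by each macronutrient:
#' `100 * grams * kcal_per_g / energy_kcal`. Sugar uses the carbohydrate
#' factor; saturated, mono- and polyunsaturated fat all use the fat factor.
#' Computed per participant-day, never from cohort medians (percentages of
#' medians are not compositional).
#'
#' @param day A `per_day` `nutrient_vector` containing `energy_kcal` > 0.
#' @param factors An [energy_factors()] object.
#' @return Named numeric vector of %TEI values, one entry per macronutrient
#'   key present in `day` (`protein_g`, `carbohydrate_g`, `sugar_g`, `fat_g`,
#'   `satfat_g`, `mufa_g`, `pufa_g`, `alcohol_g`).
#' @export
percent_tei <- function(day, factors = energy_factors()) {
  stop_if_not_nv(day, "day")
  if (!inherits(factors, "energy_factors")) stop("factors must be energy_factors")
  energy <- if ("energy_kcal" %in% names(day)) as.numeric(day[["energy_kcal"]]) else NA_real_
  if (is.na(energy) || energy <= 0) {
    stop("percent_tei requires a positive energy_kcal amount")
  }
  macro_factor <- c(
    protein_g = factors$protein,
    carbohydrate_g = factors$carbohydrate,
    sugar_g = factors$carbohydrate,
    fat_g = factors$fat,
    satfat_g = factors$fat,
    mufa_g = factors$fat,
    pufa_g = factors$fat,
    alcohol_g = factors$alcohol
  )
  keys <- intersect(names(macro_factor), names(day))
  grams <- stats::setNames(as.numeric(day)[match(keys, names(day))], keys)
  100 * grams * macro_factor[keys] / energy
}

#' Salt equivalent of a sodium intake
#'
#' Standard NaCl conversion: 1 g sodium corresponds to 2.5 g salt, so
#' `salt_g = sodium_mg * 2.5 / 1000`. Used when guideline categories are
#' expressed in grams of salt while intakes are estimated as milligrams of
#' sodium.
#'
#' @param sodium_mg Non-negative sodium amount in mg (vectorised).
#' @return Salt in grams.
#' @export
salt_from_sodium <- function(sodium_mg) {
  if (any(!is.finite(sodium_mg)) || any(sodium_mg < 0)) {
    stop("sodium_mg must be non-negative")
  }
  sodium_mg * 2.5 / 1000
}
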
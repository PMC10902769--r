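#' Meal slots of the generic recall and the bank type they draw from
#'
#' The instrument asks about seven slots for the previous day. Snack slots
#' (morning, afternoon, evening) all draw from the snack bank; lunch draws
#' from light meals and the evening meal from main meals.
#'
#' @return Named character vector: slot -> meal type.
#' @export
recall_slots <- function() {
  c(breakfast = "breakfast",
    morning_snack = "snack",
    lunch = "light_meal",
    afternoon_snack = "snack",
    evening_meal = "main_meal",
    evening_snack = "snack",
    beverage = "beverage")
}

#' One answer of the generic recall
#'
#' A respondent either picks a generic meal (then also picks which of the 3
#' displayed portion images — the bank's 2nd, 4th and 6th septiles — best
#' matches, and whether that image was smaller than, the same as, or larger
#' than what they ate) or answers "none of the above" with a free-text
#' description. Beverage slots instead ask how many of the displayed portion
#' were drunk, with no smaller/same/larger follow-up.
#'
#' @param slot One of `names(recall_slots())`.
#' @param generic_meal_id Chosen generic meal id, or `NULL` for none-of-the-
#'   above.
#' @param image_index Displayed portion septile, one of 2, 4, 6 (required
#'   when a meal is chosen).
#' @param relative One of `"image_smaller_than_consumed"`, `"same"`,
#'   `"image_larger_than_consumed"` (food slots with a chosen meal only).
#' @param count Number of portions consumed (beverage slots only, >= 1).
#' @param free_text Description typed for none-of-the-above.
#' @return Object of class `recall_response`.
#' @export
recall_response <- function(slot, generic_meal_id = NULL, image_index = NULL,
                            relative = NULL, count = NULL, free_text = NULL) {
  slot <- match.arg(slot, names(recall_slots()))
  is_beverage <- slot == "beverage"
  if (is.null(generic_meal_id)) {
    if (!is.null(image_index) || !is.null(relative) || !is.null(count)) {
      stop("none-of-the-above responses carry no portion information")
    }
  } else {
    if (is.null(image_index) || !image_index %in% c(2, 4, 6)) {
      stop("image_index must be 2, 4 or 6")
    }
    if (is_beverage) {
      if (is.null(count) || count < 1 || count != round(count)) {
        stop("beverage responses need a positive integer count")
      }
      if (!is.null(relative)) stop("beverage responses have no relative answer")
    } else {
      if (is.null(relative)) {
        stop("food-slot responses need a smaller/same/larger answer")
      }
      relative <- match.arg(relative, c("image_smaller_than_consumed", "same",
                                        "image_larger_than_consumed"))
      if (!is.null(count)) stop("count is only valid for beverage slots")
    }
  }
  structure(list(slot = slot, generic_meal_id = generic_meal_id,
                 image_index = image_index, relative = relative,
                 count = if (is_beverage && !is.null(generic_meal_id))
                   as.integer(count) else NULL,
                 free_text = free_text),
            class = "recall_response")
}

#' Resolve the portion septile from the image answers
#'
#' Displayed images are the 2nd, 4th and 6th septile portions; the follow-up
#' shifts by one septile: "image smaller than consumed" moves up, "image
#' larger than consumed" moves down. The 3x3 answer grid therefore reaches
#' every septile 1..7 (3 and 5 twice).
#'
#' @param image_index 2, 4 or 6.
#' @param relative One of `"image_smaller_than_consumed"`, `"same"`,
#'   `"image_larger_than_consumed"`.
#' @return Portion index in 1..7.
#' @export
resolve_portion <- function(image_index, relative) {
  if (!image_index %in% c(2, 4, 6)) stop("image_index must be 2, 4 or 6")
  relative <- match.arg(relative, c("image_smaller_than_consumed", "same",
                                    "image_larger_than_consumed"))
  delta <- switch(relative,
                  image_smaller_than_consumed = 1L,
                  same = 0L,
                  image_larger_than_consumed = -1L)
  as.integer(image_index) + delta
}

#' Nutrient intake from one generic meal at one portion
#'
#' `intake = profile_per100g * portion_weight_g / 100`, returned on the
#' `per_day` basis so meal intakes add directly into day totals.
#'
#' @param gm A [generic_meal()].
#' @param portion_index Septile index 1..7.
#' @return A `per_day` [nutrient_vector()].
#' @export
meal_intake <- function(gm, portion_index) {
  if (!inherits(gm, "generic_meal")) stop("gm must be a generic_meal")
  if (!portion_index %in% 1:7) stop("portion_index must be in 1..7")
  nv_scale(gm$profile_per100g, gm$portion_weights_g[portion_index] / 100,
           basis = "per_day")
}

#' Nutrient intake from a beverage response
#'
#' Beverages use the displayed portion directly (no smaller/same/larger
#' step) multiplied by the reported number of portions.
#'
#' @param gm A beverage [generic_meal()].
#' @param image_index Displayed septile, 2, 4 or 6.
#' @param count Number of portions consumed, >= 1.
#' @return A `per_day` [nutrient_vector()].
#' @export
beverage_intake <- function(gm, image_index, count) {
  if (!image_index %in% c(2, 4, 6)) stop("image_index must be 2, 4 or 6")
  if (count < 1 || count != round(count)) stop("count must be a positive integer")
  nv_scale(meal_intake(gm, image_index), count)
}

#' Score one recalled day against a generic-meal bank
#'
#' Resolves every response to a generic meal and portion, sums the
#' corresponding nutrient intakes into a day total, and records
#' none-of-the-above answers as unresolved (they contribute zero nutrients
#' but are counted, so analyses can flag incomplete days). Skipped slots
#' simply contribute nothing.
#'
#' @param responses List of [recall_response()]s for one participant-day.
#' @param bank A [meal_bank()].
#' @param participant_id Carried into the result.
#' @return Object of class `day_intake`: `participant_id`, `totals`
#'   (`per_day` [nutrient_vector()]), `resolved_meals` (data frame: slot,
#'   generic_meal_id, portion_index, weight_g), `unresolved` (data frame:
#'   slot, free_text).
#' @export
score_day <- function(responses, bank, participant_id = NA_character_) {
  if (!inherits(bank, "meal_bank")) stop("bank must be a meal_bank")
  slot_type <- recall_slots()
  totals <- nutrient_vector(numeric(), "per_day")
  resolved <- list()
  unresolved <- list()
  for (r in responses) {
    if (!inherits(r, "recall_response")) stop("responses must be recall_response objects")
    if (is.null(r$generic_meal_id)) {
      unresolved[[length(unresolved) + 1]] <- data.frame(
        slot = r$slot,
        free_text = if (is.null(r$free_text)) NA_character_ else r$free_text,
        stringsAsFactors = FALSE)
      next
    }
    gm <- bank$generic_meals[[r$generic_meal_id]]
    if (is.null(gm)) stop("unknown generic meal id: ", r$generic_meal_id)
    if (gm$meal_type != slot_type[[r$slot]]) {
      stop("generic meal '", r$generic_meal_id, "' (", gm$meal_type,
           ") does not match slot '", r$slot, "' (", slot_type[[r$slot]], ")")
    }
    if (r$slot == "beverage") {
      intake <- beverage_intake(gm, r$image_index, r$count)
      portion <- as.integer(r$image_index)
      weight <- gm$portion_weights_g[portion] * r$count
    } else {
      portion <- resolve_portion(r$image_index, r$relative)
      intake <- meal_intake(gm, portion)
      weight <- gm$portion_weights_g[portion]
    }
    totals <- nv_add(totals, intake)
    resolved[[length(resolved) + 1]] <- data.frame(
      slot = r$slot, generic_meal_id = gm$id, portion_index = portion,
      weight_g = weight, stringsAsFactors = FALSE)
  }
  empty_resolved <- data.frame(slot = character(), generic_meal_id = character(),
                               portion_index = integer(), weight_g = numeric(),
                               stringsAsFactors = FALSE)
  empty_unresolved <- data.frame(slot = character(), free_text = character(),
                                 stringsAsFactors = FALSE)
  structure(list(
    participant_id = participant_id,
    totals = totals,
    resolved_meals = if (length(resolved)) do.call(rbind, resolved) else empty_resolved,
    unresolved = if (length(unresolved)) do.call(rbind, unresolved) else empty_unresolved
  ), class = "day_intake")
}
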
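pkg_version <- function() {
  as.character(utils::packageVersion("mealrecall"))
}

provenance_block <- function(seed = NA, extra = list()) {
  c(list(tool = "mealrecall", version = pkg_version(), seed = seed), extra)
}

read_checked_csv <- function(path, required, id_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(required, names(tab))
  if (length(missing)) {
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(id_col) && anyDuplicated(tab[[id_col]])) {
    dups <- unique(tab[[id_col]][duplicated(tab[[id_col]])])
    stop(path, ": duplicate ", id_col, ": ", paste(dups, collapse = ", "))
  }
  tab
}

write_csv_with_header <- function(tab, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(provenance_block(seed),
                                           auto_unbox = TRUE)), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read and write the package's file formats
#'
#' Food composition tables and intake tables are CSV (with a one-line `#`
#' provenance header on write); diary records are long CSV; generic-meal
#' banks and recall responses are JSON. Readers validate the schema and name
#' the offending column or id in errors.
#'
#' @param path File path.
#' @return `read_foods`: data frame with `food_id`, `food_group` and nutrient
#'   columns. `read_diary`: long data frame. `read_bank`: a [meal_bank()].
#'   `read_responses`: named list (one entry per participant-day) of lists of
#'   [recall_response()]s. `read_intakes`: wide data frame keyed by
#'   `participant_id`.
#' @name io
#' @export
read_foods <- function(path) {
  tab <- read_checked_csv(path, c("food_id", "food_group", "energy_kcal"),
                          id_col = "food_id")
  nutrient_cols <- setdiff(names(tab), c("food_id", "food_group"))
  for (nc in nutrient_cols) {
    if (!is.numeric(tab[[nc]])) stop(path, ": column ", nc, " must be numeric")
    if (any(tab[[nc]] < 0)) stop(path, ": negative amounts in ", nc)
  }
  tab
}

#' @rdname io
#' @param foods Food composition table.
#' @param seed Seed recorded in the provenance header.
#' @export
write_foods <- function(foods, path, seed = NA) {
  write_csv_with_header(foods, path, seed)
}

#' @rdname io
#' @export
read_diary <- function(path) {
  tab <- read_checked_csv(path, c("participant_id", "day", "occasion_label",
                                  "food_id", "weight_g"))
  if (any(tab$weight_g <= 0)) {
    stop(path, ": non-positive weight_g at row(s) ",
         paste(which(tab$weight_g <= 0), collapse = ", "))
  }
  tab
}

#' @rdname io
#' @param diary Long diary data frame.
#' @export
write_diary <- function(diary, path, seed = NA) {
  write_csv_with_header(diary, path, seed)
}

#' Build meal records from a long diary table
#'
#' Groups diary rows by participant, day and occasion label and constructs
#' one [meal_record()] per occasion. Meal types are taken from a `meal_type`
#' column when present, otherwise assigned via [assign_meal_type()] with
#' `rules`.
#'
#' @param diary Long diary data frame ([read_diary()]).
#' @param foods Food composition table ([read_foods()]).
#' @param rules Typing rules for [assign_meal_type()] (only needed when the
#'   diary has no `meal_type` column).
#' @return Named list of [meal_record()]s.
#' @export
diary_to_meals <- function(diary, foods, rules = NULL) {
  profiles <- foods_to_profiles(foods)
  food_groups <- stats::setNames(foods$food_group, foods$food_id)
  unknown <- setdiff(unique(diary$food_id), foods$food_id)
  if (length(unknown)) {
    stop("diary references unknown food id(s): ",
         paste(unknown, collapse = ", "))
  }
  key <- paste(diary$participant_id, diary$day, diary$occasion_label,
               sep = "\r")
  meals <- lapply(split(seq_len(nrow(diary)), key), function(idx) {
    rows <- diary[idx, ]
    rec <- meal_record(
      participant_id = rows$participant_id[1],
      day_index = rows$day[1],
      occasion_label = rows$occasion_label[1],
      foods = data.frame(food_id = rows$food_id, weight_g = rows$weight_g,
                         stringsAsFactors = FALSE),
      food_profiles = profiles,
      meal_type = if ("meal_type" %in% names(rows)) rows$meal_type[1]
                  else NA_character_,
      weekend = if ("weekend" %in% names(rows)) isTRUE(rows$weekend[1])
                else FALSE
    )
    if (is.na(rec$meal_type)) {
      if (is.null(rules)) {
        stop("diary has no meal_type column and no typing rules were given")
      }
      rec$meal_type <- assign_meal_type(rec, rules, food_groups)
    }
    rec
  })
  ids <- vapply(meals, function(m) {
    sprintf("%s_d%d_%s", m$participant_id, m$day_index, m$occasion_label)
  }, character(1))
  stats::setNames(meals, make.unique(ids))
}

#' @rdname io
#' @param bank A [meal_bank()].
#' @export
write_bank <- function(bank, path, seed = NA) {
  gm_list <- lapply(unname(bank$generic_meals), function(g) {
    list(id = g$id, meal_type = g$meal_type,
         profile_per100g = as.list(stats::setNames(
           as.numeric(g$profile_per100g), names(g$profile_per100g))),
         portion_weights_g = g$portion_weights_g,
         member_count = length(g$member_meal_ids),
         member_meal_ids = g$member_meal_ids,
         medoid_meal_id = g$medoid_meal_id)
  })
  jsonlite::write_json(
    list(provenance = c(provenance_block(seed), bank$provenance),
         generic_meals = gm_list),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname io
#' @export
read_bank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path)
  if (is.null(raw$generic_meals)) stop(path, ": no generic_meals field")
  gms <- lapply(raw$generic_meals, function(g) {
    for (f in c("id", "meal_type", "profile_per100g", "portion_weights_g",
                "medoid_meal_id")) {
      if (is.null(g[[f]])) stop(path, ": generic meal missing field ", f)
    }
    generic_meal(
      id = g$id, meal_type = g$meal_type,
      profile_per100g = nutrient_vector(unlist(g$profile_per100g),
                                        "per_100g"),
      portion_weights_g = unlist(g$portion_weights_g),
      member_meal_ids = if (is.null(g$member_meal_ids)) g$medoid_meal_id
                        else unlist(g$member_meal_ids),
      medoid_meal_id = g$medoid_meal_id)
  })
  meal_bank(gms, provenance = raw$provenance)
}

#' @rdname io
#' @param responses Named list (participant-day key) of lists of
#'   [recall_response()]s, or a flat list of responses each carrying
#'   `participant_id`.
#' @export
write_responses <- function(responses, path, seed = NA) {
  flat <- list()
  for (key in names(responses)) {
    for (r in responses[[key]]) {
      flat[[length(flat) + 1]] <- list(
        record_id = key,
        slot = r$slot,
        generic_meal_id = r$generic_meal_id,
        image_index = r$image_index,
        relative = r$relative,
        count = r$count,
        free_text = r$free_text)
    }
  }
  jsonlite::write_json(list(provenance = provenance_block(seed),
                            responses = flat),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname io
#' @export
read_responses <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path)
  items <- if (!is.null(raw$responses)) raw$responses else raw
  out <- list()
  for (it in items) {
    if (is.null(it$slot)) stop(path, ": response missing slot")
    key <- if (is.null(it$record_id)) "all" else it$record_id
    r <- recall_response(
      slot = it$slot,
      generic_meal_id = it$generic_meal_id,
      image_index = it$image_index,
      relative = it$relative,
      count = it$count,
      free_text = it$free_text)
    out[[key]] <- c(out[[key]], list(r))
  }
  out
}

#' @rdname io
#' @param intakes Wide intake table (`participant_id` + nutrient columns).
#' @export
write_intakes <- function(intakes, path, seed = NA) {
  write_csv_with_header(intakes, path, seed)
}

#' @rdname io
#' @export
read_intakes <- function(path) {
  read_checked_csv(path, "participant_id", id_col = "participant_id")
}

#' @rdname io
#' @export
read_participants <- function(path) {
  tab <- read_checked_csv(path, c("id", "sex", "age_years", "weight_kg"),
                          id_col = "id")
  lapply(seq_len(nrow(tab)), function(i) {
    participant(tab$id[i], tab$sex[i], tab$age_years[i], tab$weight_kg[i],
                if ("height_m" %in% names(tab)) tab$height_m[i] else NA_real_)
  })
}

#' @rdname io
#' @export
read_guidelines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- jsonlite::read_json(path)
  entries <- if (!is.null(raw$guidelines)) raw$guidelines else raw
  lapply(entries, function(e) {
    for (f in c("nutrient", "unit", "cut_points", "labels")) {
      if (is.null(e[[f]])) stop(path, ": guideline entry missing field ", f)
    }
    guideline_entry(e$nutrient, e$unit, unlist(e$cut_points),
                    unlist(e$labels))
  })
}
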
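# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Configuration of the synthetic cohort
#'
#' The generator emulates the structure of a 4-day weighed-food-diary survey
#' and of a paired-recall comparison cohort: multi-food meals of five types,
#' lognormal portion weights, a comparator instrument with multiplicative
#' lognormal error per meal, and a generic-recall respondent who matches each
#' true meal to the most similar generic meal (with a configurable mismatch
#' probability) and the nearest septile portion. All randomness flows from
#' `seed`.
#'
#' @param seed Mandatory integer seed.
#' @param n_foods Number of foods in the composition table.
#' @param n_food_groups Number of food groups (4..8; the last is always the
#'   beverage group).
#' @param n_participants Cohort size (default 161, a typical comparison-study
#'   sample).
#' @param days_per_person Diary days per participant (default 4).
#' @param meal_templates Named integer vector: true meal templates per meal
#'   type. Defaults mirror the image counts of the deployed instrument
#'   (5 breakfasts, 10 light meals, 19 main meals, 5 snacks, 4 beverages).
#' @param snack_prob,beverage_prob Daily probability of a snack / beverage
#'   occasion (breakfast, light and main meals always occur).
#' @param portion_lognormal_sigma SD of log portion weight around the
#'   template mean (default 0.25).
#' @param noise_24hr_sigma SD of the comparator's per-meal multiplicative
#'   lognormal error (default 0.2).
#' @param recall_mismatch_prob Probability a true meal is matched to a
#'   uniformly random same-type generic meal instead of the nearest one.
#' @param bias_factor Systematic multiplier applied to generic-method daily
#'   intakes (1 = unbiased).
#' @param bank_meals_per_type Cap on diary meals per type entering bank
#'   derivation (banks come from a reference survey, not the whole cohort;
#'   also keeps the clustering tractable).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_foods = 60,
                       n_food_groups = 8,
                       n_participants = 161,
                       days_per_person = 4,
                       meal_templates = c(breakfast = 5, light_meal = 10,
                                          main_meal = 19, snack = 5,
                                          beverage = 4),
                       snack_prob = 0.7,
                       beverage_prob = 0.8,
                       portion_lognormal_sigma = 0.25,
                       noise_24hr_sigma = 0.2,
                       recall_mismatch_prob = 0,
                       bias_factor = 1,
                       bank_meals_per_type = 120) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_food_groups < 4 || n_food_groups > 8) stop("n_food_groups must be 4..8")
  if (n_foods < n_food_groups) stop("need at least one food per group")
  stopifnot(all(names(meal_templates) %in% meal_types()),
            all(meal_templates >= 1))
  for (p in c(snack_prob, beverage_prob, recall_mismatch_prob)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (portion_lognormal_sigma < 0 || noise_24hr_sigma < 0) {
    stop("sigmas must be non-negative")
  }
  if (bias_factor <= 0) stop("bias_factor must be positive")
  structure(as.list(environment()), class = "sim_config")
}

synth_food_groups <- function(n) {
  c("cereals", "dairy", "meat_fish", "vegetables", "fruit", "fats_oils",
    "confectionery")[seq_len(n - 1)] |> c("beverages")
}

# Per-100 g group-median composition. Macros in g; energy is recomputed
# exactly from the macros so %TEI invariants hold by construction.
synth_group_medians <- function() {
  list(
    cereals       = c(protein_g = 9,  carbohydrate_g = 60, sugar_frac = 0.1,
                      fat_g = 3,  fiber_g = 6,  vitamin_d_ug = 0.1,
                      folate_ug = 40, vitamin_c_mg = 0.5, calcium_mg = 40,
                      iron_mg = 3, potassium_mg = 250, sodium_mg = 350,
                      thiamin_mg = 0.3, riboflavin_mg = 0.15),
    dairy         = c(protein_g = 6,  carbohydrate_g = 5,  sugar_frac = 0.9,
                      fat_g = 6,  fiber_g = 0.05, vitamin_d_ug = 0.6,
                      folate_ug = 8,  vitamin_c_mg = 1,  calcium_mg = 160,
                      iron_mg = 0.1, potassium_mg = 150, sodium_mg = 90,
                      thiamin_mg = 0.04, riboflavin_mg = 0.25),
    meat_fish     = c(protein_g = 22, carbohydrate_g = 1,  sugar_frac = 0.3,
                      fat_g = 10, fiber_g = 0.05, vitamin_d_ug = 2,
                      folate_ug = 10, vitamin_c_mg = 0.5, calcium_mg = 20,
                      iron_mg = 1.5, potassium_mg = 330, sodium_mg = 300,
                      thiamin_mg = 0.2, riboflavin_mg = 0.2),
    vegetables    = c(protein_g = 2,  carbohydrate_g = 8,  sugar_frac = 0.4,
                      fat_g = 0.4, fiber_g = 3, vitamin_d_ug = 0.01,
                      folate_ug = 60, vitamin_c_mg = 25, calcium_mg = 40,
                      iron_mg = 0.8, potassium_mg = 300, sodium_mg = 20,
                      thiamin_mg = 0.08, riboflavin_mg = 0.06),
    fruit         = c(protein_g = 0.8, carbohydrate_g = 12, sugar_frac = 0.9,
                      fat_g = 0.3, fiber_g = 2, vitamin_d_ug = 0.01,
                      folate_ug = 20, vitamin_c_mg = 30, calcium_mg = 15,
                      iron_mg = 0.3, potassium_mg = 200, sodium_mg = 3,
                      thiamin_mg = 0.04, riboflavin_mg = 0.04),
    fats_oils     = c(protein_g = 0.5, carbohydrate_g = 1, sugar_frac = 0.3,
                      fat_g = 70, fiber_g = 0.05, vitamin_d_ug = 5,
                      folate_ug = 2, vitamin_c_mg = 0.1, calcium_mg = 10,
                      iron_mg = 0.2, potassium_mg = 30, sodium_mg = 500,
                      thiamin_mg = 0.01, riboflavin_mg = 0.02),
    confectionery = c(protein_g = 5,  carbohydrate_g = 55, sugar_frac = 0.7,
                      fat_g = 20, fiber_g = 2, vitamin_d_ug = 0.2,
                      folate_ug = 12, vitamin_c_mg = 0.3, calcium_mg = 80,
                      iron_mg = 1.5, potassium_mg = 200, sodium_mg = 200,
                      thiamin_mg = 0.06, riboflavin_mg = 0.15),
    beverages     = c(protein_g = 0.5, carbohydrate_g = 5, sugar_frac = 0.9,
                      fat_g = 0.3, fiber_g = 0.05, vitamin_d_ug = 0.01,
                      folate_ug = 5, vitamin_c_mg = 8, calcium_mg = 30,
                      iron_mg = 0.1, potassium_mg = 80, sodium_mg = 10,
                      thiamin_mg = 0.02, riboflavin_mg = 0.05)
  )
}

#' Generate a synthetic food composition table
#'
#' Foods are drawn around per-group median profiles with multiplicative
#' lognormal spread (sigma 0.3 on the log scale). Saturated, mono- and
#' polyunsaturated fat are drawn as fractions of total fat and sugar as a
#' fraction of carbohydrate, and `energy_kcal` is computed exactly from the
#' macro grams with the configured energy factors, so energy consistency
#' holds for every food by construction.
#'
#' @param config A [sim_config()].
#' @param factors [energy_factors()] used to set `energy_kcal`.
#' @return Data frame: `food_id`, `food_group`, one column per nutrient key.
#' @export
generate_foods <- function(config, factors = energy_factors()) {
  groups <- synth_food_groups(config$n_food_groups)
  medians <- synth_group_medians()
  with_local_seed(config$seed + 101L, {
    group_of <- rep(groups, length.out = config$n_foods)
    rows <- lapply(seq_len(config$n_foods), function(i) {
      g <- group_of[i]
      med <- medians[[g]]
      jitter <- function(x) x * exp(stats::rnorm(length(x), 0, 0.3))
      protein <- jitter(med[["protein_g"]])
      carb <- jitter(med[["carbohydrate_g"]])
      fat <- jitter(med[["fat_g"]])
      sugar <- carb * min(1, jitter(med[["sugar_frac"]]))
      sat_frac <- stats::runif(1, 0.2, 0.5)
      mufa_frac <- stats::runif(1, 0.2, 0.45)
      pufa_frac <- max(0.05, 1 - sat_frac - mufa_frac - stats::runif(1, 0, 0.2))
      micro_keys <- setdiff(names(med),
                            c("protein_g", "carbohydrate_g", "sugar_frac",
                              "fat_g"))
      micros <- jitter(med[micro_keys])
      data.frame(
        food_id = sprintf("f%03d", i), food_group = g,
        energy_kcal = protein * factors$protein + carb * factors$carbohydrate +
          fat * factors$fat,
        protein_g = protein, carbohydrate_g = carb, sugar_g = sugar,
        fat_g = fat, satfat_g = fat * sat_frac, mufa_g = fat * mufa_frac,
        pufa_g = fat * pufa_frac,
        as.list(micros),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' Per-100 g nutrient vectors from a food composition table
#'
#' @param foods Data frame as returned by [generate_foods()] / [read_foods()].
#' @return Named list of per-100 g [nutrient_vector()]s keyed by `food_id`.
#' @export
foods_to_profiles <- function(foods) {
  nutrient_cols <- setdiff(names(foods), c("food_id", "food_group"))
  profs <- lapply(seq_len(nrow(foods)), function(i) {
    nutrient_vector(stats::setNames(as.numeric(foods[i, nutrient_cols]),
                                    nutrient_cols), "per_100g")
  })
  stats::setNames(profs, foods$food_id)
}

# Meal templates: each template fixes the food ids, their weight fractions
# and a mean total weight; meals sampled from a template share one per-100 g
# profile and differ only in total weight.
synth_templates <- function(foods, config) {
  type_groups <- list(
    breakfast = c("cereals", "dairy", "fruit"),
    light_meal = c("cereals", "vegetables", "dairy", "meat_fish"),
    main_meal = c("meat_fish", "vegetables", "cereals", "fats_oils"),
    snack = c("confectionery", "fruit", "dairy"),
    beverage = "beverages"
  )
  mean_weight <- c(breakfast = 350, light_meal = 400, main_meal = 500,
                   snack = 150, beverage = 330)
  with_local_seed(config$seed + 202L, {
    out <- list()
    for (type in names(config$meal_templates)) {
      allowed <- type_groups[[type]]
      allowed <- allowed[allowed %in% unique(foods$food_group)]
      pool <- foods$food_id[foods$food_group %in% allowed]
      for (t in seq_len(config$meal_templates[[type]])) {
        n_items <- if (type == "beverage") 1L else sample(2:4, 1)
        ids <- sample(pool, min(n_items, length(pool)))
        frac <- stats::runif(length(ids), 0.5, 1.5)
        frac <- frac / sum(frac)
        out[[paste0(type, "_t", t)]] <- list(
          meal_type = type, food_ids = ids, fractions = frac,
          mean_weight_g = mean_weight[[type]]
        )
      }
    }
    out
  })
}

#' Generate a synthetic weighed-food diary with known true intakes
#'
#' Every person-day contains a breakfast, a light meal and a main meal;
#' snacks and beverages occur with their configured probabilities. Each meal
#' instantiates a randomly chosen template of its type at a lognormal total
#' weight. True daily intakes are the exact sums over the diary.
#'
#' @param foods Composition table from [generate_foods()].
#' @param config A [sim_config()].
#' @return List: `meals` (named list of [meal_record()]s), `diary` (long
#'   data frame), `truth` (data frame of true daily intakes: participant_id,
#'   day, one column per nutrient), `templates`, `template_of` (named
#'   character: meal id -> template id).
#' @export
generate_diary <- function(foods, config) {
  profiles <- foods_to_profiles(foods)
  templates <- synth_templates(foods, config)
  tmpl_by_type <- split(names(templates),
                        vapply(templates, `[[`, character(1), "meal_type"))
  slots_always <- c("breakfast", "light_meal", "main_meal")
  with_local_seed(config$seed + 303L, {
    meals <- list()
    template_of <- character()
    diary_rows <- list()
    truth_rows <- list()
    for (p in seq_len(config$n_participants)) {
      pid <- sprintf("p%04d", p)
      for (day in seq_len(config$days_per_person)) {
        types_today <- c(slots_always,
                         if (stats::runif(1) < config$snack_prob) "snack",
                         if (stats::runif(1) < config$beverage_prob) "beverage")
        day_total <- nutrient_vector(numeric(), "per_day")
        for (type in types_today) {
          tid <- if (length(tmpl_by_type[[type]]) == 1) tmpl_by_type[[type]]
                 else sample(tmpl_by_type[[type]], 1)
          tm <- templates[[tid]]
          w <- tm$mean_weight_g *
            exp(stats::rnorm(1, 0, config$portion_lognormal_sigma))
          mid <- sprintf("%s_d%d_%s", pid, day, type)
          rec <- meal_record(
            participant_id = pid, day_index = day, occasion_label = type,
            foods = data.frame(food_id = tm$food_ids,
                               weight_g = tm$fractions * w,
                               stringsAsFactors = FALSE),
            food_profiles = profiles, meal_type = type,
            weekend = day > config$days_per_person - 2
          )
          meals[[mid]] <- rec
          template_of[mid] <- tid
          day_total <- nv_add(day_total,
                              nv_scale(rec$profile_per100g,
                                       rec$total_weight_g / 100,
                                       basis = "per_day"))
          diary_rows[[length(diary_rows) + 1]] <- data.frame(
            participant_id = pid, day = day, occasion_label = type,
            meal_type = type, food_id = tm$food_ids,
            weight_g = tm$fractions * w, stringsAsFactors = FALSE)
        }
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          participant_id = pid, day = day,
          as.list(stats::setNames(as.numeric(day_total), names(day_total))),
          stringsAsFactors = FALSE)
      }
    }
    list(meals = meals,
         diary = do.call(rbind, diary_rows),
         truth = do.call(rbind, truth_rows),
         templates = templates,
         template_of = template_of)
  })
}

#' Comparator-instrument observation of one day
#'
#' Each true meal intake is multiplied by an i.i.d. lognormal factor
#' `exp(N(0, sigma^2))` and the perturbed meals are summed: the classic
#' multiplicative error model for self-reported intake.
#'
#' @param meal_intakes List of `per_day` [nutrient_vector()]s, one per true
#'   meal of the day.
#' @param sigma Non-negative lognormal sigma.
#' @return A `per_day` [nutrient_vector()].
#' @export
observe_24hr <- function(meal_intakes, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  noisy <- lapply(meal_intakes, function(m) {
    nv_scale(m, exp(stats::rnorm(1, 0, sigma)))
  })
  nv_sum(noisy, basis = "per_day")
}

portion_to_image <- function(portion_index) {
  # fixed convention: portions 3 and 5 are reached from images 2 and 6
  switch(portion_index,
         list(image_index = 2L, relative = "image_larger_than_consumed"),
         list(image_index = 2L, relative = "same"),
         list(image_index = 2L, relative = "image_smaller_than_consumed"),
         list(image_index = 4L, relative = "same"),
         list(image_index = 6L, relative = "image_larger_than_consumed"),
         list(image_index = 6L, relative = "same"),
         list(image_index = 6L, relative = "image_smaller_than_consumed"))
}

slot_for_meal_type <- function(type, snack_counter = 1L) {
  switch(type,
         breakfast = "breakfast",
         light_meal = "lunch",
         main_meal = "evening_meal",
         snack = c("morning_snack", "afternoon_snack",
                   "evening_snack")[min(snack_counter, 3L)],
         beverage = "beverage")
}

#' Simulated respondent: map true meals to recall responses
#'
#' With probability `1 - recall_mismatch_prob` the respondent picks the
#' generic meal of the matching type whose per-100 g profile is nearest in
#' standardized-nutrient Euclidean distance (standardization over the
#' candidate generic profiles); otherwise a uniformly random same-type
#' generic meal. The reported portion is the septile whose weight is nearest
#' the true meal weight (ties to the lower septile), emitted as the
#' image/relative pair realizing it; beverages report the nearest of the
#' displayed septiles 2/4/6 with count 1.
#'
#' @param true_meals List of [meal_record()]s for one day.
#' @param bank A [meal_bank()].
#' @param config A [sim_config()].
#' @return List of [recall_response()]s.
#' @export
observe_generic <- function(true_meals, bank, config) {
  responses <- list()
  snack_counter <- 0L
  for (m in true_meals) {
    cands <- bank_meals_of_type(bank, m$meal_type)
    if (length(cands) == 0) {
      stop("bank has no generic meals of type ", m$meal_type)
    }
    if (stats::runif(1) < config$recall_mismatch_prob) {
      gm <- cands[[sample(length(cands), 1)]]
    } else {
      gm <- cands[[nearest_generic(m$profile_per100g, cands)]]
    }
    if (m$meal_type == "snack") snack_counter <- snack_counter + 1L
    slot <- slot_for_meal_type(m$meal_type, snack_counter)
    if (m$meal_type == "beverage") {
      img_opts <- c(2L, 4L, 6L)
      gaps <- abs(gm$portion_weights_g[img_opts] - m$total_weight_g)
      image <- img_opts[which.min(gaps)]
      responses[[length(responses) + 1]] <- recall_response(
        slot, generic_meal_id = gm$id, image_index = image, count = 1L)
    } else {
      gaps <- abs(gm$portion_weights_g - m$total_weight_g)
      portion <- which.min(gaps)  # which.min takes the lower index on ties
      enc <- portion_to_image(portion)
      responses[[length(responses) + 1]] <- recall_response(
        slot, generic_meal_id = gm$id, image_index = enc$image_index,
        relative = enc$relative)
    }
  }
  responses
}

nearest_generic <- function(profile, cands) {
  keys <- Reduce(union, lapply(cands, function(g) names(g$profile_per100g)))
  keys <- union(keys, names(profile))
  mat <- t(vapply(cands, function(g) {
    v <- as.numeric(g$profile_per100g)[match(keys, names(g$profile_per100g))]
    v[is.na(v)] <- 0
    v
  }, numeric(length(keys))))
  target <- as.numeric(profile)[match(keys, names(profile))]
  target[is.na(target)] <- 0
  if (nrow(mat) == 1) return(1L)
  mu <- colMeans(mat)
  sds <- apply(mat, 2, stats::sd)
  use <- !is.na(sds) & sds > 0
  if (!any(use)) return(1L)
  z <- sweep(sweep(mat[, use, drop = FALSE], 2, mu[use]), 2, sds[use], "/")
  zt <- (target[use] - mu[use]) / sds[use]
  which.min(sqrt(colSums((t(z) - zt)^2)))
}

#' Generate a complete synthetic comparison cohort
#'
#' Composes the whole pipeline: composition table, diary with true intakes,
#' a generic-meal bank derived from (a capped subsample of) the diary meals,
#' comparator (24HR-like) observations with multiplicative noise, simulated
#' generic-recall responses scored against the bank, and per-participant
#' mean daily intake tables for the two methods. `bias_factor` multiplies
#' the generic-method intakes after scoring, modelling a systematic
#' instrument bias. Bit-identical under a fixed config.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_cohort`: `foods`, `food_groups`,
#'   `meals`, `diary`, `truth`, `bank`, `responses`, `intakes_24hr`,
#'   `intakes_generic`, `participants`, `config`.
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  factors <- energy_factors()
  foods <- generate_foods(config, factors)
  food_groups <- stats::setNames(foods$food_group, foods$food_id)
  dia <- generate_diary(foods, config)

  # bank derived from a capped, deterministic subsample of the diary meals
  types <- vapply(dia$meals, `[[`, character(1), "meal_type")
  keep <- unlist(lapply(split(names(dia$meals), types), function(ids) {
    ids[seq_len(min(length(ids), config$bank_meals_per_type))]
  }), use.names = FALSE)
  bank <- derive_bank(
    dia$meals[keep],
    food_groups = food_groups,
    config = list(k = as.list(config$meal_templates)),
    seed = config$seed
  )

  meals_by_pd <- split(names(dia$meals), paste(
    vapply(dia$meals, `[[`, character(1), "participant_id"),
    vapply(dia$meals, `[[`, numeric(1), "day_index")))

  pids <- sprintf("p%04d", seq_len(config$n_participants))
  nutrient_cols <- setdiff(names(dia$truth), c("participant_id", "day"))
  responses <- list()
  obs24_rows <- list()
  gen_rows <- list()
  with_local_seed(config$seed + 404L, {
    for (p in pids) {
      for (day in seq_len(config$days_per_person)) {
        key <- paste(p, day)
        day_meals <- dia$meals[meals_by_pd[[key]]]
        intakes <- lapply(day_meals, function(m) {
          nv_scale(m$profile_per100g, m$total_weight_g / 100,
                   basis = "per_day")
        })
        obs <- observe_24hr(intakes, config$noise_24hr_sigma)
        obs24_rows[[key]] <- data.frame(
          participant_id = p, day = day,
          as.list(stats::setNames(
            as.numeric(obs)[match(nutrient_cols, names(obs))],
            nutrient_cols)),
          stringsAsFactors = FALSE)
        resp <- observe_generic(day_meals, bank, config)
        responses[[key]] <- resp
        scored <- score_day(resp, bank, participant_id = p)
        tot <- nv_scale(scored$totals, config$bias_factor)
        v <- as.numeric(tot)[match(nutrient_cols, names(tot))]
        v[is.na(v)] <- 0
        gen_rows[[key]] <- data.frame(
          participant_id = p, day = day,
          as.list(stats::setNames(v, nutrient_cols)),
          stringsAsFactors = FALSE)
      }
    }
  })
  daily_24 <- do.call(rbind, obs24_rows)
  daily_gen <- do.call(rbind, gen_rows)

  participant_mean <- function(daily) {
    agg <- stats::aggregate(daily[nutrient_cols],
                            by = list(participant_id = daily$participant_id),
                            FUN = mean)
    agg[match(pids, agg$participant_id), ]
  }
  parts <- with_local_seed(config$seed + 505L, {
    lapply(pids, function(pid) {
      sex <- if (stats::runif(1) < 0.81) "female" else "male"
      participant(pid, sex,
                  age_years = round(stats::runif(1, 20, 75)),
                  weight_kg = round(stats::rnorm(1,
                    if (sex == "female") 70 else 83, 10), 1),
                  height_m = round(stats::rnorm(1,
                    if (sex == "female") 1.64 else 1.79, 0.06), 2))
    })
  })
  structure(list(
    foods = foods, food_groups = food_groups,
    meals = dia$meals, diary = dia$diary, truth = dia$truth,
    templates = dia$templates, template_of = dia$template_of,
    bank = bank, responses = responses,
    intakes_24hr_daily = daily_24, intakes_generic_daily = daily_gen,
    intakes_24hr = participant_mean(daily_24),
    intakes_generic = participant_mean(daily_gen),
    participants = parts,
    config = config
  ), class = "synthetic_cohort")
}
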
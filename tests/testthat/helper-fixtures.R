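# Shorthand constructors ----------------------------------------------------

nv100 <- function(...) nutrient_vector(c(...), "per_100g")
nvday <- function(...) nutrient_vector(c(...), "per_day")

# A minimal composition table: two groups, four foods.
tiny_foods <- function() {
  data.frame(
    food_id = c("oats", "milk", "apple", "tea"),
    food_group = c("cereals", "dairy", "fruit", "beverages"),
    energy_kcal = c(380, 64, 52, 1),
    protein_g = c(11, 3.4, 0.3, 0.1),
    carbohydrate_g = c(60, 4.8, 12, 0.2),
    sugar_g = c(1, 4.8, 10, 0),
    fat_g = c(8, 3.6, 0.2, 0),
    sodium_mg = c(6, 44, 1, 3),
    stringsAsFactors = FALSE
  )
}

tiny_profiles <- function() foods_to_profiles(tiny_foods())

# A hand-built bank: one generic meal per type, portion weights 100..700.
tiny_bank <- function() {
  mk <- function(id, type, energy) {
    generic_meal(
      id = id, meal_type = type,
      profile_per100g = nv100(energy_kcal = energy, protein_g = energy / 20,
                              sodium_mg = energy),
      portion_weights_g = seq(100, 700, by = 100),
      member_meal_ids = paste0(id, "_m1"),
      medoid_meal_id = paste0(id, "_m1"))
  }
  meal_bank(list(
    mk("gm_bf", "breakfast", 150),
    mk("gm_light", "light_meal", 120),
    mk("gm_main", "main_meal", 180),
    mk("gm_snack", "snack", 400),
    mk("gm_bev", "beverage", 30)
  ))
}

# Independent oracles --------------------------------------------------------

# Exact two-sided signed-rank p by enumeration of all 2^n sign assignments,
# with midranks, matching the convention "V = sum of ranks of positive d".
bf_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  mu <- n * (n + 1) / 4
  # two-sided: doubling the smaller tail, as in the package's exact path
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Spearman rho as Pearson on midranks, from the covariance formula directly.
bf_spearman_rho <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Optimal k-medoids by exhaustive enumeration of all medoid subsets.
bf_pam_cost <- function(d, k) {
  d <- as.matrix(d)
  n <- nrow(d)
  best <- Inf
  best_set <- NULL
  sets <- utils::combn(n, k)
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(d[, sets[, j], drop = FALSE], 1, min))
    if (cost < best - 1e-12) {
      best <- cost
      best_set <- sets[, j]
    }
  }
  list(cost = best, medoids = best_set)
}

# Average silhouette width computed straight from its definition.
bf_silhouette <- function(d, assignment) {
  d <- as.matrix(d)
  n <- nrow(d)
  mean(vapply(seq_len(n), function(i) {
    own <- which(assignment == assignment[i])
    if (length(own) == 1) return(0)
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(assignment), assignment[i]),
                    function(l) mean(d[i, assignment == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

# Build a participant-day of "true" meals drawn exactly from a bank at
# septile portion weights, plus the responses that encode them. Used by the
# round-trip identity tests.
sample_day_from_bank <- function(bank, slots = c("breakfast", "lunch",
                                                 "evening_meal", "beverage")) {
  slot_type <- recall_slots()
  responses <- list()
  truth <- nutrient_vector(numeric(), "per_day")
  for (slot in slots) {
    cands <- bank_meals_of_type(bank, slot_type[[slot]])
    gm <- cands[[sample(length(cands), 1)]]
    if (slot == "beverage") {
      image <- sample(c(2L, 4L, 6L), 1)
      count <- sample(1:3, 1)
      responses[[length(responses) + 1]] <- recall_response(
        slot, generic_meal_id = gm$id, image_index = image, count = count)
      truth <- nv_add(truth, beverage_intake(gm, image, count))
    } else {
      portion <- sample(1:7, 1)
      enc <- list(
        list(image_index = 2L, relative = "image_larger_than_consumed"),
        list(image_index = 2L, relative = "same"),
        list(image_index = 2L, relative = "image_smaller_than_consumed"),
        list(image_index = 4L, relative = "same"),
        list(image_index = 6L, relative = "image_larger_than_consumed"),
        list(image_index = 6L, relative = "same"),
        list(image_index = 6L, relative = "image_smaller_than_consumed")
      )[[portion]]
      responses[[length(responses) + 1]] <- recall_response(
        slot, generic_meal_id = gm$id, image_index = enc$image_index,
        relative = enc$relative)
      truth <- nv_add(truth, meal_intake(gm, portion))
    }
  }
  list(responses = responses, truth = truth)
}

# The worked example shipped with the package: cohort-level medians, printed
# percentage differences and effect sizes from a published 161-participant
# comparison of a generic meal-based recall against a web-based 24HR.
comparison_example <- function() {
  utils::read.csv(system.file("extdata", "comparison_example.csv",
                              package = "mealrecall"),
                  stringsAsFactors = FALSE)
}

synth_group_medians_for_test <- function() mealrecall:::synth_group_medians()
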
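test_that("assign_meal_type follows label map > beverage-only > time band", {
  profiles <- tiny_profiles()
  groups <- setNames(tiny_foods()$food_group, tiny_foods()$food_id)
  mk <- function(label, ids, w) {
    meal_record("p1", 1, label,
                foods = data.frame(food_id = ids, weight_g = w),
                food_profiles = profiles)
  }
  rules <- list(label_map = c(breakfast = "breakfast"),
                occasion_hours = c(elevenses = 11, supper = 19),
                time_bands = data.frame(from = c(10, 17), to = c(12, 22),
                                        type = c("snack", "main_meal")))
  expect_equal(assign_meal_type(mk("breakfast", "oats", 60), rules, groups),
               "breakfast")
  # beverage-only occasion, no matching label
  expect_equal(assign_meal_type(mk("cuppa", "tea", 250), rules, groups),
               "beverage")
  # time band fallback
  expect_equal(assign_meal_type(mk("supper", c("oats", "milk"), c(60, 100)),
                                rules, groups),
               "main_meal")
  # label map beats beverage test
  rules2 <- c(rules, list(label_map = c(cuppa = "snack")))
  rules2$label_map <- c(cuppa = "snack")
  expect_equal(assign_meal_type(mk("cuppa", "tea", 250), rules2, groups),
               "snack")
  expect_error(assign_meal_type(mk("second lunch", "oats", 10), rules, groups),
               "second lunch")
})

test_that("build_features standardizes NRF score and group fractions", {
  profiles <- tiny_profiles()
  groups <- setNames(tiny_foods()$food_group, tiny_foods()$food_id)
  refs <- nrf_references()
  mk <- function(ids, w) {
    meal_record("p", 1, "m", data.frame(food_id = ids, weight_g = w),
                profiles, meal_type = "breakfast")
  }
  # two identical meals: everything constant, collapses to a zero column
  same <- list(a = mk("oats", 50), b = mk("oats", 50))
  expect_message(f0 <- build_features(same, refs, groups), "constant")
  expect_true(all(f0 == 0))
  # mirror-image group fractions give rows symmetric about zero
  mirror <- list(a = mk(c("oats", "milk"), c(100, 50)),
                 b = mk(c("oats", "milk"), c(50, 100)))
  f1 <- build_features(mirror, refs, groups)
  expect_equal(unname(f1[1, ]), unname(-f1[2, ]))
  # hand-standardized oracle on 4 meals
  meals <- list(m1 = mk("oats", 60), m2 = mk(c("oats", "milk"), c(40, 160)),
                m3 = mk("milk", 200), m4 = mk(c("oats", "milk"), c(90, 30)))
  f <- build_features(meals, refs, groups)
  raw_nrf <- vapply(meals, function(m) nrf93(m$profile_per100g, refs),
                    numeric(1))
  expect_equal(unname(f[, "nrf"]),
               unname((raw_nrf - mean(raw_nrf)) / sd(raw_nrf)))
  raw_frac <- vapply(meals, function(m) {
    sum(m$foods$weight_g[m$foods$food_id == "oats"]) / m$total_weight_g
  }, numeric(1))
  expect_equal(unname(f[, "cereals"]),
               unname((raw_frac - mean(raw_frac)) / sd(raw_frac)))
  expect_error(build_features(meals[1], refs, groups), "at least 2")
})

test_that("pam_fit solves small instances exactly", {
  # k = 1 on a line: the middle point is the medoid, cost 2
  x <- matrix(c(0, 1, 2), ncol = 1)
  fit <- pam_fit(x, 1)
  expect_equal(fit$medoids, 2L)
  expect_equal(fit$cost, 2)
  # k = n: every point its own medoid, zero cost
  fit_n <- pam_fit(x, 3)
  expect_equal(sort(fit_n$medoids), 1:3)
  expect_equal(fit_n$cost, 0)
  expect_error(pam_fit(x, 4), "k must satisfy")
  expect_error(pam_fit(x, 0), "k must satisfy")
  # two separated blobs: partition equals brute force over all medoid pairs
  set.seed(5)
  blobs <- rbind(matrix(rnorm(8, 0, 0.3), 4),
                 matrix(rnorm(8, 10, 0.3), 4))
  d <- dist(blobs)
  fit2 <- pam_fit(blobs, 2)
  bf <- bf_pam_cost(d, 2)
  expect_equal(fit2$cost, bf$cost)
  expect_setequal(fit2$medoids, bf$medoids)
  expect_equal(sort(unique(fit2$assignment[1:4])), fit2$medoids[1])
})

test_that("pam_fit equals the brute-force optimum on random instances", {
  set.seed(99)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    k <- sample(1:3, 1)
    x <- matrix(rnorm(n * 2), n)
    fit <- pam_fit(x, k)
    bf <- bf_pam_cost(dist(x), k)
    expect_equal(fit$cost, bf$cost, tolerance = 1e-10)
  }
})

test_that("select_k maximizes average silhouette with ties to smallest k", {
  set.seed(3)
  blobs <- rbind(matrix(rnorm(10, 0, 0.2), 5),
                 matrix(rnorm(10, 8, 0.2), 5))
  expect_equal(select_k(blobs, 2:4), 2L)
  expect_equal(select_k(blobs, 2), 2L)
  expect_error(select_k(blobs, integer()), "empty")
  expect_error(select_k(blobs, 2:20), "within")
  # argmax + first-on-tie verified against the brute-force silhouette
  x <- matrix(rnorm(16), 8)
  kr <- 2:5
  sils <- vapply(kr, function(k) {
    bf_silhouette(dist(x), pam_fit(x, k)$assignment)
  }, numeric(1))
  expect_equal(select_k(x, kr), kr[which.max(sils)])
})

test_that("septile_portions splits ordered weights into 7 median groups", {
  expect_equal(septile_portions(seq(100, 700, 100)), seq(100, 700, 100))
  # n = 14: groups of 2, medians by hand
  expect_equal(septile_portions(seq(10, 140, 10)),
               c(15, 35, 55, 75, 95, 115, 135))
  # n = 10: sizes 2,2,2,1,1,1,1
  expect_equal(septile_portions(1:10), c(1.5, 3.5, 5.5, 7, 8, 9, 10))
  # n < 7: trailing septiles inherit downward
  expect_message(p3 <- septile_portions(c(300, 100, 200)), "fewer than 7")
  expect_equal(p3, c(100, 200, 300, 300, 300, 300, 300))
  expect_error(septile_portions(numeric()), "at least one")
  expect_error(septile_portions(c(10, -5)), "positive")
})

test_that("septile portions are ordered and bounded by the data", {
  set.seed(21)
  for (i in 1:20) {
    w <- rlnorm(sample(c(7, 14, 9, 40, 3), 1), 5, 0.5)
    p <- suppressMessages(septile_portions(w))
    expect_length(p, 7)
    expect_true(all(diff(p) >= 0))
    expect_gte(p[1], min(w))
    expect_lte(p[7], max(w))
  }
})

test_that("derive_bank summarizes clusters per the generic-meal definition", {
  profiles <- tiny_profiles()
  groups <- setNames(tiny_foods()$food_group, tiny_foods()$food_id)
  mk <- function(ids, w, type = "breakfast") {
    meal_record("p", 1, type, data.frame(food_id = ids, weight_g = w),
                profiles, meal_type = type)
  }
  # single-meal type: profile equals that meal, all portions its weight
  single <- list(m1 = mk("oats", 250))
  bank1 <- suppressMessages(
    derive_bank(single, food_groups = groups, config = list(k = list(breakfast = 1))))
  gm <- bank1$generic_meals[[1]]
  expect_equal(as.numeric(gm$profile_per100g[names(single$m1$profile_per100g)]),
               as.numeric(single$m1$profile_per100g))
  expect_equal(gm$portion_weights_g, rep(250, 7))
  expect_equal(gm$medoid_meal_id, "m1")

  # two-meal cluster: per-100g profile is the UNWEIGHTED mean
  two <- list(m1 = mk("oats", 100), m2 = mk("milk", 300))
  bank2 <- suppressMessages(
    derive_bank(two, food_groups = groups, config = list(k = list(breakfast = 1))))
  gm2 <- bank2$generic_meals[[1]]
  expect_equal(gm2$profile_per100g[["energy_kcal"]], (380 + 64) / 2)
  # weighted variant for sensitivity analysis
  bank2w <- suppressMessages(
    derive_bank(two, food_groups = groups,
                config = list(k = list(breakfast = 1),
                              profile_mean = "weighted")))
  expect_equal(bank2w$generic_meals[[1]]$profile_per100g[["energy_kcal"]],
               (100 * 380 + 300 * 64) / 400)
})

test_that("derive_bank recovers the generating templates", {
  cfg <- sim_config(seed = 404, n_participants = 30,
                    meal_templates = c(breakfast = 3, light_meal = 3,
                                       main_meal = 3, snack = 2,
                                       beverage = 2))
  foods <- generate_foods(cfg)
  dia <- generate_diary(foods, cfg)
  groups <- setNames(foods$food_group, foods$food_id)
  bank <- suppressMessages(derive_bank(
    dia$meals, food_groups = groups,
    config = list(k = as.list(cfg$meal_templates)), seed = 404))
  # per type: as many generic meals as templates, and each generic profile
  # equals one template profile exactly (template meals share one profile)
  expect_equal(as.integer(bank$counts[names(cfg$meal_templates)]),
               unname(cfg$meal_templates))
  profiles <- foods_to_profiles(foods)
  for (tm in dia$templates) {
    t_prof <- meal_profile(profiles[tm$food_ids], tm$fractions)
    cands <- bank_meals_of_type(bank, tm$meal_type)
    gaps <- vapply(cands, function(g) {
      keys <- names(t_prof)
      max(abs(as.numeric(g$profile_per100g[keys]) - as.numeric(t_prof)))
    }, numeric(1))
    expect_lt(min(gaps), 1e-8)
  }
})

test_that("derive_bank is reproducible and validates inputs", {
  cfg <- sim_config(seed = 8, n_participants = 6,
                    meal_templates = c(breakfast = 2, light_meal = 2,
                                       main_meal = 2, snack = 2, beverage = 2))
  foods <- generate_foods(cfg)
  dia <- generate_diary(foods, cfg)
  groups <- setNames(foods$food_group, foods$food_id)
  b1 <- suppressMessages(derive_bank(dia$meals, food_groups = groups,
                                     config = list(k = as.list(cfg$meal_templates))))
  b2 <- suppressMessages(derive_bank(dia$meals, food_groups = groups,
                                     config = list(k = as.list(cfg$meal_templates))))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_bank(b1, f1); write_bank(b2, f2)
  expect_identical(readLines(f1), readLines(f2))
  untyped <- dia$meals[1]
  untyped[[1]]$meal_type <- NA_character_
  expect_error(suppressMessages(
    derive_bank(untyped, food_groups = groups, config = list())),
    "meal_type")
})
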
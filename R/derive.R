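#' Assign a meal type to an eating occasion
#'
#' Occasions are mapped onto the five meal types used by the generic-meal
#' method (breakfast, light meal, main meal, snack, beverage) with a fixed
#' precedence: an explicit occasion-label map wins; otherwise an occasion
#' whose foods all belong to the beverage food group is a beverage (beverages
#' consumed alone, without food); otherwise a time-of-day band keyed on the
#' occasion's clock hour applies. An occasion that none of the rules cover is
#' an error naming the label.
#'
#' @param meal A [meal_record()].
#' @param rules List with any of: `label_map` (named character vector,
#'   occasion label -> meal type), `beverage_group` (food-group name, default
#'   `"beverages"`), `occasion_hours` (named numeric vector, occasion label ->
#'   clock hour), `time_bands` (data frame with columns `from`, `to`, `type`;
#'   a band covers hours `from <= h < to`).
#' @param food_groups Named character vector mapping `food_id` to food group.
#' @return One of [meal_types()].
#' @export
assign_meal_type <- function(meal, rules, food_groups = NULL) {
  lbl <- meal$occasion_label
  if (!is.null(rules$label_map) && lbl %in% names(rules$label_map)) {
    return(match.arg(unname(rules$label_map[[lbl]]), meal_types()))
  }
  bev_group <- if (is.null(rules$beverage_group)) "beverages" else rules$beverage_group
  if (!is.null(food_groups)) {
    groups <- food_groups[as.character(meal$foods$food_id)]
    if (length(groups) > 0 && !anyNA(groups) && all(groups == bev_group)) {
      return("beverage")
    }
  }
  if (!is.null(rules$time_bands) && !is.null(rules$occasion_hours) &&
      lbl %in% names(rules$occasion_hours)) {
    h <- rules$occasion_hours[[lbl]]
    hit <- which(rules$time_bands$from <= h & h < rules$time_bands$to)
    if (length(hit) > 0) {
      return(match.arg(rules$time_bands$type[hit[1]], meal_types()))
    }
  }
  stop("cannot assign a meal type to occasion label: '", lbl, "'")
}

#' Clustering features for a set of meals
#'
#' One row per meal: the NRF9.3 score followed by the food-group weight
#' fractions (weight of each group divided by total meal weight). Every
#' column is standardized to mean 0, sd 1; constant columns carry no
#' clustering information and are dropped with a message.
#'
#' @param meals List of [meal_record()]s (at least 2), typically all of one
#'   meal type.
#' @param refs [nrf_references()] used for the NRF9.3 score.
#' @param food_groups Named character vector mapping `food_id` to food group.
#' @return Numeric matrix, rows named by meal id (names of `meals` or
#'   `meal_<i>`).
#' @export
build_features <- function(meals, refs, food_groups) {
  if (length(meals) < 2) stop("build_features needs at least 2 meals")
  ids <- names(meals)
  if (is.null(ids)) ids <- paste0("meal_", seq_along(meals))
  groups <- sort(unique(unname(food_groups)))
  rows <- t(vapply(meals, function(m) {
    g <- food_groups[as.character(m$foods$food_id)]
    if (anyNA(g)) {
      stop("no food group for food(s): ",
           paste(m$foods$food_id[is.na(g)], collapse = ", "))
    }
    frac <- vapply(groups, function(gr) {
      sum(m$foods$weight_g[g == gr]) / m$total_weight_g
    }, numeric(1))
    c(nrf = nrf93(m$profile_per100g, refs), frac)
  }, numeric(1 + length(groups))))
  rownames(rows) <- ids
  sds <- apply(rows, 2, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    message("dropping constant feature column(s): ",
            paste(colnames(rows)[constant], collapse = ", "))
  }
  kept <- rows[, !constant, drop = FALSE]
  if (ncol(kept) == 0) {
    # all meals identical in every feature: keep a single zero column so
    # downstream clustering still sees n rows
    return(matrix(0, nrow(rows), 1,
                  dimnames = list(ids, colnames(rows)[1])))
  }
  scale(kept)[, , drop = FALSE]
}

#' Partitioning around medoids (PAM)
#'
#' Classic BUILD + SWAP k-medoids on Euclidean distances between feature
#' rows. BUILD greedily seeds `k` medoids; SWAP repeatedly applies the single
#' best strictly-improving (medoid, non-medoid) exchange until no exchange
#' lowers the total cost (sum of distances of every point to its assigned
#' medoid). The algorithm is deterministic: ties are broken toward the lowest
#' row index, so `seed` only enters provenance metadata.
#'
#' @param x Numeric feature matrix (rows are observations) or a `dist`.
#' @param k Number of clusters, `1 <= k <= nrow(x)`.
#' @param seed Ignored by the algorithm (kept for call-site uniformity).
#' @return List with `medoids` (row indices, sorted), `assignment` (medoid
#'   index per row), `cost`.
#' @export
pam_fit <- function(x, k, seed = NULL) {
  d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  dimnames(d) <- NULL
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n (n = ", n, ")")

  cost_of <- function(meds) sum(apply(d[, meds, drop = FALSE], 1, min))

  # BUILD: seed with `first`, then greedily add the point with the largest
  # cost reduction.
  build_from <- function(first) {
    medoids <- first
    nearest <- d[, first]
    while (length(medoids) < k) {
      cand <- setdiff(seq_len(n), medoids)
      gain <- vapply(cand, function(j) sum(pmax(nearest - d[, j], 0)),
                     numeric(1))
      best <- cand[which.max(gain)]
      medoids <- c(medoids, best)
      nearest <- pmin(nearest, d[, best])
    }
    medoids
  }

  # SWAP: best-improvement exchanges until a local optimum.
  swap <- function(medoids) {
    cost <- cost_of(medoids)
    repeat {
      best_cost <- cost
      best_meds <- NULL
      for (m in medoids) {
        for (o in setdiff(seq_len(n), medoids)) {
          trial <- c(setdiff(medoids, m), o)
          tc <- cost_of(trial)
          if (tc < best_cost - 1e-12) {
            best_cost <- tc
            best_meds <- trial
          }
        }
      }
      if (is.null(best_meds)) break
      medoids <- best_meds
      cost <- best_cost
    }
    list(medoids = sort(medoids), cost = cost)
  }

  # SWAP can stall in a local optimum; restart BUILD from each of the most
  # central points (deterministic) and keep the cheapest local optimum.
  n_starts <- min(n, 3L)
  starts <- order(colSums(d))[seq_len(n_starts)]
  best <- NULL
  for (s in starts) {
    fit <- swap(build_from(s))
    if (is.null(best) || fit$cost < best$cost - 1e-12) best <- fit
  }

  medoids <- unname(best$medoids)
  assignment <- medoids[apply(d[, medoids, drop = FALSE], 1, which.min)]
  list(medoids = medoids, assignment = unname(assignment),
       cost = cost_of(medoids))
}

#' Average silhouette width of a clustering
#'
#' @param d Distance matrix or `dist`.
#' @param assignment Cluster label per observation (any labels, >= 2 distinct).
#' @return Mean silhouette width over all observations; singleton clusters
#'   contribute 0.
#' @export
avg_silhouette <- function(d, assignment) {
  d <- if (inherits(d, "dist")) as.matrix(d) else as.matrix(d)
  n <- nrow(d)
  labs <- unique(assignment)
  if (length(labs) < 2) stop("silhouette needs at least 2 clusters")
  s <- vapply(seq_len(n), function(i) {
    own <- assignment == assignment[i]
    if (sum(own) == 1) return(0)
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(labs, assignment[i]),
                    function(l) mean(d[i, assignment == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Choose the number of generic meals per meal type
#'
#' Runs [pam_fit()] for each candidate `k` and returns the `k` maximizing the
#' average silhouette width; exact ties go to the smallest `k`.
#'
#' @param x Feature matrix.
#' @param k_range Integer candidates, each in `[2, nrow(x) - 1]`.
#' @param seed Passed to [pam_fit()] (no effect on the result).
#' @return The selected `k`.
#' @export
select_k <- function(x, k_range, seed = NULL) {
  if (length(k_range) == 0) stop("k_range must not be empty")
  n <- if (inherits(x, "dist")) attr(x, "Size") else nrow(x)
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]")
  }
  k_range <- sort(unique(as.integer(k_range)))
  d <- if (inherits(x, "dist")) as.matrix(x) else as.matrix(stats::dist(x))
  sil <- vapply(k_range, function(k) {
    fit <- pam_fit(d_as_dist(d), k, seed)
    avg_silhouette(d, fit$assignment)
  }, numeric(1))
  k_range[which.max(sil)]  # which.max takes the first (smallest k) on ties
}

d_as_dist <- function(m) stats::as.dist(m)

#' Septile portion weights
#'
#' Orders the member-meal weights, splits them into 7 contiguous groups of
#' sizes as equal as possible (when `n mod 7 > 0` the extra items go to the
#' earliest groups), and returns the median weight of each group as that
#' septile's portion size. With fewer than 7 weights the leading groups get
#' one weight each and empty trailing groups inherit the nearest lower
#' non-empty group's median (with a message).
#'
#' @param weights Positive meal weights in grams.
#' @return Numeric vector of 7 non-decreasing portion weights.
#' @export
septile_portions <- function(weights) {
  if (length(weights) == 0) stop("at least one weight required")
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be positive")
  }
  w <- sort(weights)
  n <- length(w)
  base <- n %/% 7L
  extra <- n %% 7L
  sizes <- base + as.integer(seq_len(7L) <= extra)
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  portions <- rep(NA_real_, 7L)
  for (s in seq_len(7L)) {
    if (sizes[s] > 0) portions[s] <- stats::median(w[starts[s]:ends[s]])
  }
  if (anyNA(portions)) {
    message("fewer than 7 meals: empty septiles inherit the previous portion")
    for (s in seq_len(7L)) {
      if (is.na(portions[s])) portions[s] <- portions[s - 1L]
    }
  }
  portions
}

#' A generic meal: one cluster of real meals
#'
#' @param id Unique identifier within the bank.
#' @param meal_type One of [meal_types()].
#' @param profile_per100g Per-100 g [nutrient_vector()] (mean of members).
#' @param portion_weights_g 7 non-decreasing positive portion weights.
#' @param member_meal_ids Ids of the member meals.
#' @param medoid_meal_id Id of the cluster medoid (must be a member).
#' @return Object of class `generic_meal`.
#' @export
generic_meal <- function(id, meal_type, profile_per100g, portion_weights_g,
                         member_meal_ids, medoid_meal_id) {
  meal_type <- match.arg(meal_type, meal_types())
  stop_if_not_nv(profile_per100g, "profile_per100g")
  if (length(portion_weights_g) != 7) stop("exactly 7 portion weights required")
  if (any(portion_weights_g <= 0)) stop("portion weights must be positive")
  if (any(diff(portion_weights_g) < 0)) {
    stop("portion weights must be non-decreasing")
  }
  if (!medoid_meal_id %in% member_meal_ids) {
    stop("medoid must be one of the member meals")
  }
  structure(list(id = id, meal_type = meal_type,
                 profile_per100g = profile_per100g,
                 portion_weights_g = as.numeric(portion_weights_g),
                 member_meal_ids = member_meal_ids,
                 medoid_meal_id = medoid_meal_id),
            class = "generic_meal")
}

#' Assemble a bank of generic meals
#'
#' @param generic_meals List of [generic_meal()]s with unique ids.
#' @param provenance List of metadata (source id, config hash, seed).
#' @return Object of class `meal_bank`.
#' @export
meal_bank <- function(generic_meals, provenance = list()) {
  ids <- vapply(generic_meals, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate generic meal ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  types <- vapply(generic_meals, `[[`, character(1), "meal_type")
  structure(list(generic_meals = stats::setNames(generic_meals, ids),
                 counts = table(factor(types, levels = meal_types())),
                 provenance = provenance),
            class = "meal_bank")
}

#' @export
print.meal_bank <- function(x, ...) {
  cat("<meal_bank: ", length(x$generic_meals), " generic meals>\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @rdname meal_bank
#' @param bank A `meal_bank`.
#' @param type A meal type.
#' @export
bank_meals_of_type <- function(bank, type) {
  type <- match.arg(type, meal_types())
  Filter(function(gm) gm$meal_type == type, bank$generic_meals)
}

# 32-bit FNV-1a over the JSON serialization: a stable, dependency-free
# fingerprint for provenance headers (not cryptographic).
config_hash <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

#' Derive a generic-meal bank from typed diary meals
#'
#' Within each meal type present in `meals`: builds clustering features
#' ([build_features()]), clusters with [pam_fit()] (using the configured `k`
#' for that type, or [select_k()] over `k_range` when no `k` is given), and
#' summarizes each cluster as a generic meal whose per-100 g profile is the
#' unweighted mean of the member meals' per-100 g profiles and whose 7
#' portion weights are [septile_portions()] of the member total weights.
#' With `split_weekend = TRUE` the derivation runs separately on weekday and
#' weekend meals and generic meals identical in profile and portions (within
#' 1e-9) are de-duplicated across the two strata.
#'
#' @param meals Named list of typed [meal_record()]s.
#' @param refs [nrf_references()].
#' @param food_groups Named character vector, `food_id` -> group.
#' @param config List: `k` (named list meal type -> cluster count) and/or
#'   `k_range` (candidates for [select_k()]); optional
#'   `profile_mean = "unweighted"|"weighted"` (default unweighted; weighted
#'   uses meal total weights, for sensitivity analysis);
#'   `split_weekend` flag.
#' @param seed Recorded in provenance and forwarded to the clustering (which
#'   is itself deterministic).
#' @return A [meal_bank()].
#' @export
derive_bank <- function(meals, refs = nrf_references(), food_groups, config,
                        seed = 1L) {
  if (length(meals) == 0) stop("no meals supplied")
  if (is.null(names(meals))) names(meals) <- paste0("meal_", seq_along(meals))
  types <- vapply(meals, `[[`, character(1), "meal_type")
  if (anyNA(types)) stop("all meals must have an assigned meal_type")
  profile_mean <- if (is.null(config$profile_mean)) "unweighted" else config$profile_mean
  profile_mean <- match.arg(profile_mean, c("unweighted", "weighted"))

  derive_stratum <- function(stratum_meals, tag) {
    out <- list()
    for (type in intersect(meal_types(), unique(
      vapply(stratum_meals, `[[`, character(1), "meal_type")))) {
      tm <- Filter(function(m) m$meal_type == type, stratum_meals)
      res <- tryCatch(
        derive_type(tm, type, tag),
        error = function(e) stop("deriving '", type, "' meals: ",
                                 conditionMessage(e), call. = FALSE)
      )
      out <- c(out, res)
    }
    out
  }

  derive_type <- function(tm, type, tag) {
    n <- length(tm)
    if (n == 1) {
      cluster_ids <- stats::setNames(1L, names(tm))
      medoids <- names(tm)
    } else {
      feats <- build_features(tm, refs, food_groups)
      k <- config$k[[type]]
      if (is.null(k)) {
        if (is.null(config$k_range)) {
          stop("config must give k[['", type, "']] or k_range")
        }
        kr <- config$k_range[config$k_range <= n - 1 & config$k_range >= 2]
        k <- if (length(kr) == 0) 1L else select_k(feats, kr, seed)
      }
      if (k > n) {
        message("clamping k = ", k, " to ", n, " meals for type ", type)
        k <- n
      }
      fit <- pam_fit(feats, k, seed)
      cluster_ids <- stats::setNames(match(fit$assignment, fit$medoids),
                                     names(tm))
      medoids <- names(tm)[fit$medoids]
    }
    lapply(sort(unique(cluster_ids)), function(ci) {
      members <- names(cluster_ids)[cluster_ids == ci]
      profs <- lapply(meals[members], `[[`, "profile_per100g")
      wts <- if (profile_mean == "weighted") {
        vapply(meals[members], `[[`, numeric(1), "total_weight_g")
      } else {
        rep(1, length(members))
      }
      generic_meal(
        id = paste0(tag, type, "_", ci),
        meal_type = type,
        profile_per100g = meal_profile(profs, wts),
        portion_weights_g = septile_portions(
          vapply(meals[members], `[[`, numeric(1), "total_weight_g")),
        member_meal_ids = members,
        medoid_meal_id = medoids[ci]
      )
    })
  }

  if (isTRUE(config$split_weekend)) {
    wk <- vapply(meals, `[[`, logical(1), "weekend")
    gms <- c(derive_stratum(meals[!wk], "wd_"), derive_stratum(meals[wk], "we_"))
    gms <- dedupe_generic_meals(gms, tol = 1e-9)
  } else {
    gms <- derive_stratum(meals, "")
  }
  meal_bank(gms, provenance = list(
    n_meals = length(meals),
    config_hash = config_hash(config[setdiff(names(config), "food_groups")]),
    seed = seed
  ))
}

dedupe_generic_meals <- function(gms, tol = 1e-9) {
  keep <- list()
  for (gm in gms) {
    dup <- FALSE
    for (kept in keep) {
      if (kept$meal_type != gm$meal_type) next
      if (!setequal(names(kept$profile_per100g), names(gm$profile_per100g))) next
      a <- as.numeric(kept$profile_per100g[names(gm$profile_per100g)])
      if (max(abs(a - as.numeric(gm$profile_per100g))) <= tol &&
          max(abs(kept$portion_weights_g - gm$portion_weights_g)) <= tol) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, list(gm))
  }
  keep
}
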
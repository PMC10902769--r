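#' Wilcoxon signed rank test for paired intakes
#'
#' Implements the signed-rank test with the conventions needed downstream:
#' zero differences are discarded, absolute differences are ranked with
#' midranks for ties, and the statistic is the sum of ranks of positive
#' differences. The p value is exact (signed-rank distribution) when at most
#' 25 non-zero differences remain and the absolute differences are untied;
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. The normal-approximation Z is always computed and
#' returned so an effect size can be derived regardless of which path
#' produced the p value.
#'
#' @param a,b Paired numeric vectors (method A and method B).
#' @return List: `statistic` (V, sum of positive ranks), `p`, `z`,
#'   `n_nonzero`, `n_pairs`, `exact` (logical).
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  d <- a - b
  if (anyNA(d)) stop("missing values in paired differences")
  n_pairs <- length(d)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    stop("all paired differences are zero: signed rank test undefined")
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  ties <- table(r)
  has_ties <- any(ties > 1)

  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  cc <- if (V == mu) 0 else sign(V - mu) * 0.5
  z <- if (sigma2 > 0) (V - mu - cc) / sqrt(sigma2) else 0

  exact <- n <= 25 && !has_ties
  if (exact) {
    p <- if (V > mu) {
      2 * stats::psignrank(V - 1, n, lower.tail = FALSE)
    } else {
      2 * stats::psignrank(V, n)
    }
    p <- min(1, p)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(statistic = V, p = p, z = z, n_nonzero = n, n_pairs = n_pairs,
       exact = exact)
}

#' Wilcoxon effect size r
#'
#' `r = |Z| / sqrt(n)` where, by default, `n` is the total number of pairs
#' entering the test (switchable to the non-zero-difference count). Labels:
#' r < 0.1 negligible, 0.1 <= r < 0.3 small, 0.3 <= r < 0.5 moderate,
#' r >= 0.5 large.
#'
#' @param z Normal-approximation Z of the signed rank test.
#' @param n_pairs Number of pairs.
#' @return List: `r`, `label`.
#' @export
effect_size <- function(z, n_pairs) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  r <- abs(z) / sqrt(n_pairs)
  list(r = r, label = effect_label(r))
}

#' @rdname effect_size
#' @param r Effect size value (vectorised).
#' @export
effect_label <- function(r) {
  cut(r, breaks = c(-Inf, 0.1, 0.3, 0.5, Inf), right = FALSE,
      labels = c("negligible", "small", "moderate", "large"))
}

#' Bland-Altman agreement analysis
#'
#' Differences are `A - B` (reference method minus test method). Limits of
#' agreement are `mean(d) +/- 1.96 * sd(d)` with the sample (n-1) standard
#' deviation; the within-limits count is inclusive of the boundaries.
#'
#' @param a,b Paired numeric vectors; `a` is the reference method.
#' @return List: `mean_diff`, `sd_diff`, `loa_lo`, `loa_hi`, `n_within`,
#'   `prop_within`, `n`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must be paired")
  n <- length(a)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - 1.96 * s
  hi <- m + 1.96 * s
  within <- sum(d >= lo & d <= hi)
  list(mean_diff = m, sd_diff = s, loa_lo = lo, loa_hi = hi,
       n_within = within, prop_within = within / n, n = n)
}

#' Basic Bland-Altman plot
#'
#' @param a,b Paired numeric vectors (`a` = reference method).
#' @param main Plot title.
#' @return Invisibly, the [bland_altman()] result.
#' @export
bland_altman_plot <- function(a, b, main = "Bland-Altman") {
  ba <- bland_altman(a, b)
  graphics::plot((a + b) / 2, a - b, xlab = "mean of methods",
                 ylab = "difference (A - B)", main = main)
  graphics::abline(h = c(ba$loa_lo, ba$mean_diff, ba$loa_hi), lty = 2)
  invisible(ba)
}

#' Spearman rank correlation with agreement labels
#'
#' Rho is the Pearson correlation of midranks; the p value uses the
#' t approximation with n - 2 degrees of freedom. Labels: rho < 0.20 poor,
#' 0.20 <= rho < 0.50 acceptable, rho >= 0.50 good (label on the absolute
#' value of rho).
#'
#' @param a,b Paired numeric vectors, n >= 3, neither constant.
#' @return List: `rho`, `p`, `label`, `n`.
#' @export
spearman_cor <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop("a and b must be paired")
  if (n < 3) stop("Spearman correlation needs n >= 3")
  ra <- rank(a)
  rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    stop("Spearman correlation undefined for a constant method column")
  }
  rho <- stats::cor(ra, rb)
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, label = correlation_label(rho), n = n)
}

#' @rdname spearman_cor
#' @param rho Correlation value (vectorised).
#' @export
correlation_label <- function(rho) {
  cut(abs(rho), breaks = c(-Inf, 0.20, 0.50, Inf), right = FALSE,
      labels = c("poor", "acceptable", "good"))
}

#' Cross-classification of intake quartiles
#'
#' Each method's values are cut at their own type-7 quartile cut points
#' (25th, 50th, 75th percentiles); a value equal to a cut point falls in the
#' lower quartile. Participants are then tabulated by how many quartiles
#' apart the two methods place them: 0 (exact agreement), <= 1 (exact +
#' adjacent), exactly 2 (disagreement), exactly 3 (extreme disagreement).
#'
#' @param a,b Paired numeric vectors, n >= 4.
#' @return List: `exact`, `exact_adjacent`, `disagreement`, `extreme`, `n`,
#'   plus `quartile_a`, `quartile_b` (per-participant quartiles 1..4).
#' @export
cross_classify_quartiles <- function(a, b) {
  n <- length(a)
  if (length(b) != n) stop("a and b must be paired")
  if (n < 4) stop("quartile cross-classification needs n >= 4")
  qa <- quartile_of(a)
  qb <- quartile_of(b)
  gap <- abs(qa - qb)
  list(exact = sum(gap == 0),
       exact_adjacent = sum(gap <= 1),
       disagreement = sum(gap == 2),
       extreme = sum(gap == 3),
       n = n, quartile_a = qa, quartile_b = qb)
}

quartile_of <- function(x) {
  cuts <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (x > cuts[1]) + (x > cuts[2]) + (x > cuts[3])
}

#' Guideline category definitions
#'
#' Cut points for nutrient-based dietary guidelines are not universal; they
#' are supplied as configuration. Each entry names the nutrient key, the
#' unit the cut points are expressed in, the strictly increasing cut points
#' and the ordered category labels (one more label than cut points; 2 or 3
#' of low/adequate/high).
#'
#' @param nutrient Canonical nutrient key (e.g. `protein_g`).
#' @param unit One of `"absolute"` (the key's native unit),
#'   `"percent_tei"`, `"g_per_kg_bw"`, `"salt_g"` (sodium converted to grams
#'   of salt).
#' @param cut_points Strictly increasing numeric cut points.
#' @param labels Ordered category labels, `length(cut_points) + 1` of them.
#' @return Object of class `guideline_entry`.
#' @export
guideline_entry <- function(nutrient, unit, cut_points, labels) {
  unit <- match.arg(unit, c("absolute", "percent_tei", "g_per_kg_bw",
                            "salt_g"))
  if (any(diff(cut_points) <= 0)) stop("cut points must be strictly increasing")
  if (length(labels) != length(cut_points) + 1) {
    stop("need exactly one more label than cut points")
  }
  if (!all(labels %in% c("low", "adequate", "high"))) {
    stop("labels must be drawn from low/adequate/high")
  }
  structure(list(nutrient = nutrient, unit = unit,
                 cut_points = as.numeric(cut_points),
                 labels = as.character(labels)),
            class = "guideline_entry")
}

#' Classify a daily intake against a guideline
#'
#' The intake is first transformed into the guideline's unit — `%TEI` via
#' [percent_tei()], g/kg body weight via the participant's weight, grams of
#' salt via [salt_from_sodium()] — and then binned by the cut points, with a
#' value exactly on a cut point belonging to the lower category. `day` may
#' also be a bare number already in the guideline's unit.
#'
#' @param day A `per_day` [nutrient_vector()], or a single number.
#' @param entry A [guideline_entry()].
#' @param participant A [participant()] (required for g/kg body weight).
#' @param factors [energy_factors()] (for %TEI).
#' @return The category label as character.
#' @export
classify_guidelines <- function(day, entry, participant = NULL,
                                factors = energy_factors()) {
  if (!inherits(entry, "guideline_entry")) stop("entry must be a guideline_entry")
  value <- if (is.numeric(day) && !is_nutrient_vector(day)) {
    as.numeric(day)
  } else {
    switch(entry$unit,
      absolute = get_amount(day, entry$nutrient),
      percent_tei = {
        tei <- percent_tei(day, factors)
        if (!entry$nutrient %in% names(tei)) {
          stop("no %TEI value for nutrient ", entry$nutrient)
        }
        tei[[entry$nutrient]]
      },
      g_per_kg_bw = {
        if (is.null(participant) || is.na(participant$weight_kg)) {
          stop("participant weight required for g/kg body weight guideline")
        }
        get_amount(day, entry$nutrient) / participant$weight_kg
      },
      salt_g = salt_from_sodium(get_amount(day, "sodium_mg"))
    )
  }
  entry$labels[1L + sum(value > entry$cut_points)]
}

get_amount <- function(day, key) {
  stop_if_not_nv(day, "day")
  if (!key %in% names(day)) return(0)
  as.numeric(day[[key]])
}

#' Agreement of guideline categories between two methods
#'
#' @param cat_a,cat_b Paired category labels from the two methods.
#' @return List: `n_same`, `prop_same`, `n`.
#' @export
guideline_agreement <- function(cat_a, cat_b) {
  if (length(cat_a) != length(cat_b)) stop("category vectors must be paired")
  n <- length(cat_a)
  same <- sum(cat_a == cat_b)
  list(n_same = same, prop_same = if (n > 0) same / n else NA_real_, n = n)
}

#' Percentage difference of method medians
#'
#' `100 * (median_B - median_A) / median_A`, signed: positive when the test
#' method (B) estimates higher than the reference (A). Note the sign
#' convention differs from [bland_altman()], whose differences are `A - B`.
#'
#' @param median_a Reference-method median (> 0).
#' @param median_b Test-method median.
#' @return Signed percentage difference.
#' @export
percent_difference <- function(median_a, median_b) {
  if (any(median_a <= 0)) stop("reference median must be positive")
  100 * (median_b - median_a) / median_a
}

#' Summarize a set of percentage differences
#'
#' Takes absolute values and returns the median and interquartile range
#' under type-7 (linear interpolation) quantiles.
#'
#' @param pct Numeric vector of signed percentage differences.
#' @return List: `median`, `q1`, `q3`.
#' @export
summarize_differences <- function(pct) {
  if (length(pct) == 0) stop("no differences to summarize")
  q <- stats::quantile(abs(pct), c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

#' Append %TEI columns to a wide intake table
#'
#' @param intakes Wide data frame: `participant_id` plus one column per
#'   nutrient key, including `energy_kcal`.
#' @param macros Macronutrient keys to convert (default the seven %TEI
#'   variables usually reported).
#' @param factors [energy_factors()].
#' @return The table with extra `<macro>_pcttei` columns.
#' @export
add_tei_columns <- function(intakes,
                            macros = c("protein_g", "carbohydrate_g",
                                       "sugar_g", "fat_g", "satfat_g",
                                       "mufa_g", "pufa_g"),
                            factors = energy_factors()) {
  if (!"energy_kcal" %in% names(intakes)) stop("intakes must have energy_kcal")
  if (any(intakes$energy_kcal <= 0)) stop("non-positive energy for some rows")
  fac <- c(protein_g = factors$protein, carbohydrate_g = factors$carbohydrate,
           sugar_g = factors$carbohydrate, fat_g = factors$fat,
           satfat_g = factors$fat, mufa_g = factors$fat, pufa_g = factors$fat,
           alcohol_g = factors$alcohol)
  for (m in intersect(macros, names(intakes))) {
    intakes[[paste0(sub("_g$", "", m), "_pcttei")]] <-
      100 * intakes[[m]] * fac[[m]] / intakes$energy_kcal
  }
  intakes
}

#' Run the full paired-method comparison battery
#'
#' For every requested nutrient column: method medians and IQRs, percentage
#' difference of medians, Wilcoxon signed rank p, effect size r with label,
#' Bland-Altman mean difference and limits of agreement with the
#' within-limits count, Spearman rho with p and label, and the quartile
#' cross-classification counts. Method A is the reference (e.g. a 24-hour
#' recall), method B the instrument under evaluation.
#'
#' @param intakes_a,intakes_b Wide data frames (`participant_id` + nutrient
#'   columns) covering the same participants.
#' @param nutrients Columns to compare; default all shared numeric columns.
#' @param effect_denominator `"all"` pairs (default) or `"nonzero"`.
#' @param exclude Optional participant ids to drop (e.g. flagged
#'   misreporters).
#' @return List with `rows` (one data frame row per nutrient) and `summary`
#'   (median/IQR of |pct_diff|, effect-label counts, number of significant
#'   correlations at p < .05).
#' @export
run_comparison <- function(intakes_a, intakes_b, nutrients = NULL,
                           effect_denominator = c("all", "nonzero"),
                           exclude = NULL) {
  effect_denominator <- match.arg(effect_denominator)
  for (tab in list(intakes_a, intakes_b)) {
    if (!"participant_id" %in% names(tab)) {
      stop("intake tables need a participant_id column")
    }
  }
  if (!is.null(exclude)) {
    intakes_a <- intakes_a[!intakes_a$participant_id %in% exclude, ]
    intakes_b <- intakes_b[!intakes_b$participant_id %in% exclude, ]
  }
  only_a <- setdiff(intakes_a$participant_id, intakes_b$participant_id)
  only_b <- setdiff(intakes_b$participant_id, intakes_a$participant_id)
  if (length(only_a) || length(only_b)) {
    stop("participant sets differ between methods; only in A: ",
         paste(only_a, collapse = ", "), "; only in B: ",
         paste(only_b, collapse = ", "))
  }
  intakes_b <- intakes_b[match(intakes_a$participant_id,
                               intakes_b$participant_id), ]
  if (is.null(nutrients)) {
    shared <- intersect(names(intakes_a), names(intakes_b))
    nutrients <- shared[shared != "participant_id" &
                          vapply(intakes_a[shared], is.numeric, logical(1))]
  }
  missing <- setdiff(nutrients, intersect(names(intakes_a), names(intakes_b)))
  if (length(missing)) {
    stop("nutrient column(s) absent from one method: ",
         paste(missing, collapse = ", "))
  }
  n <- nrow(intakes_a)
  if (n < 4) stop("comparison battery needs at least 4 participants")

  rows <- lapply(nutrients, function(nu) {
    a <- intakes_a[[nu]]
    b <- intakes_b[[nu]]
    qa <- stats::quantile(a, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    qb <- stats::quantile(b, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    w <- tryCatch(wilcoxon_signed_rank(a, b), error = function(e) NULL)
    n_eff <- if (is.null(w)) n
             else if (effect_denominator == "all") w$n_pairs else w$n_nonzero
    ef <- if (is.null(w)) list(r = 0, label = effect_label(0))
          else effect_size(w$z, n_eff)
    ba <- bland_altman(a, b)
    sp <- spearman_cor(a, b)
    cc <- cross_classify_quartiles(a, b)
    data.frame(
      nutrient = nu,
      median_a = qa[2], q1_a = qa[1], q3_a = qa[3],
      median_b = qb[2], q1_b = qb[1], q3_b = qb[3],
      pct_diff = percent_difference(qa[2], qb[2]),
      wilcoxon_p = if (is.null(w)) NA_real_ else w$p,
      effect_r = ef$r, effect_label = as.character(ef$label),
      ba_mean_diff = ba$mean_diff, ba_loa_lo = ba$loa_lo,
      ba_loa_hi = ba$loa_hi, n_within_loa = ba$n_within,
      prop_within_loa = ba$prop_within,
      spearman_rho = sp$rho, spearman_p = sp$p,
      spearman_label = as.character(sp$label),
      q_exact = cc$exact, q_exact_adjacent = cc$exact_adjacent,
      q_disagreement = cc$disagreement, q_extreme = cc$extreme,
      n = n,
      stringsAsFactors = FALSE
    )
  })
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL
  sm <- summarize_differences(rows$pct_diff)
  list(rows = rows,
       summary = list(
         n_participants = n,
         n_nutrients = nrow(rows),
         abs_pct_diff_median = sm$median,
         abs_pct_diff_q1 = sm$q1,
         abs_pct_diff_q3 = sm$q3,
         effect_label_counts = table(factor(rows$effect_label,
           levels = c("negligible", "small", "moderate", "large"))),
         n_significant_correlations = sum(rows$spearman_p < 0.05)
       ))
}
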
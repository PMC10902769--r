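test_that("wilcoxon signed rank matches enumeration and closed forms", {
  # antisymmetric differences: statistic n(n+1)/4, p = 1
  a <- c(10, 20, 30, 40)
  b <- a + c(2, -2, 5, -5)
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$statistic, 4 * 5 / 4)
  expect_equal(w$p, 1)
  expect_equal(w$z, 0)

  # n = 5, all differences positive, no ties: exact two-sided p = 1/16
  w5 <- wilcoxon_signed_rank(c(2, 4, 7, 11, 16), rep(1, 5))
  expect_true(w5$exact)
  expect_equal(w5$p, 1 / 16)

  # n = 6 fixed vector vs sign-assignment enumeration
  d6 <- c(3, -1, 4, -7, 2, 9)
  w6 <- wilcoxon_signed_rank(d6 + 50, rep(50, 6))
  expect_equal(w6$p, bf_signed_rank_p(d6))

  # zero differences are discarded; all-zero is an error
  wz <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 5))
  expect_equal(wz$n_nonzero, 1)
  expect_equal(wz$n_pairs, 3)
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "all paired differences")
})

test_that("wilcoxon exact path agrees with enumeration on random instances", {
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:9, 1)
    d <- round(rnorm(n, 0, 5), 2)
    d <- d[d != 0]
    if (length(d) < 2 || any(duplicated(abs(d)))) next
    w <- wilcoxon_signed_rank(d, rep(0, length(d)))
    expect_equal(w$p, bf_signed_rank_p(d), info = paste("case", i))
    # and with the reference implementation as a second, independent route
    expect_equal(w$p, wilcox.test(d, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("normal approximation tracks the exact p for moderate n", {
  set.seed(17)
  for (i in 1:15) {
    d <- rnorm(15, 0.3, 1)
    w <- wilcoxon_signed_rank(d, rep(0, 15))
    expect_true(w$exact)
    p_normal <- 2 * pnorm(-abs(w$z))
    expect_lt(abs(w$p - p_normal), 0.02)
  }
})

test_that("effect sizes and labels follow the 0.1/0.3/0.5 rule", {
  e <- effect_size(0, 10)
  expect_equal(e$r, 0)
  expect_equal(as.character(e$label), "negligible")
  expect_equal(as.character(effect_label(c(0.05, 0.1, 0.299, 0.3, 0.499, 0.5))),
               c("negligible", "small", "small", "moderate", "moderate",
                 "large"))
  # r = |Z|/sqrt(n)
  expect_equal(effect_size(-2, 100)$r, 0.2)
  expect_error(effect_size(1, 0), "n_pairs")
})

test_that("bland_altman computes mean difference and 1.96 SD limits", {
  x <- c(3, 1, 4, 1, 5)
  ident <- bland_altman(x, x)
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$loa_hi - ident$loa_lo, 0)
  expect_equal(ident$n_within, 5)

  b <- c(10, 10, 10)
  a <- b + c(-1, 0, 1)  # d = (-1, 0, 1): mean 0, sd 1
  ba <- bland_altman(a, b)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_lo, ba$loa_hi), c(-1.96, 1.96))
  expect_equal(ba$n_within, 3)
  expect_error(bland_altman(1, 2), "at least 2")

  # midpoint identity on random input
  set.seed(9)
  for (i in 1:10) {
    aa <- rnorm(20); bb <- rnorm(20)
    r <- bland_altman(aa, bb)
    expect_equal((r$loa_lo + r$loa_hi) / 2, r$mean_diff)
  }
})

test_that("spearman correlation equals midrank Pearson with t-based p", {
  up <- 1:10
  expect_equal(spearman_cor(up, up^3)$rho, 1)
  expect_equal(spearman_cor(up, rev(up))$rho, -1)
  # fixed vectors with a tie vs the direct formula and cor()
  a <- c(1, 2, 2, 5, 7)
  b <- c(3, 1, 4, 4, 9)
  s <- spearman_cor(a, b)
  expect_equal(s$rho, bf_spearman_rho(a, b))
  expect_equal(s$rho, cor(a, b, method = "spearman"))
  tstat <- s$rho * sqrt((5 - 2) / (1 - s$rho^2))
  expect_equal(s$p, 2 * pt(-abs(tstat), 3))
  expect_error(spearman_cor(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_cor(1:2, 1:2), "n >= 3")
  expect_equal(as.character(correlation_label(c(0.1, 0.2, 0.49, 0.5))),
               c("poor", "acceptable", "acceptable", "good"))
})

test_that("quartile cross-classification matches brute-force tabulation", {
  x <- c(2, 4, 6, 8, 10, 12, 14, 16)
  same <- cross_classify_quartiles(x, x * 3 + 1)  # monotone transform
  expect_equal(same$exact, 8)
  expect_equal(same$exact_adjacent, 8)
  # reversed ranking, n = 8 distinct: quartiles flip 1<->4, 2<->3
  rev8 <- cross_classify_quartiles(x, rev(x))
  expect_equal(rev8$exact, 0)
  expect_equal(rev8$extreme, 4)
  expect_equal(rev8$disagreement, 0)
  expect_equal(rev8$exact_adjacent, 4)
  expect_error(cross_classify_quartiles(1:3, 1:3), "n >= 4")
  # marginals: with distinct values every quartile holds floor/ceil(n/4)
  set.seed(13)
  for (i in 1:10) {
    n <- sample(8:30, 1)
    aa <- sample(seq_len(100), n)
    bb <- sample(seq_len(100), n)
    cc <- cross_classify_quartiles(aa, bb)
    expect_gte(cc$exact_adjacent, cc$exact)
    tab <- table(cc$quartile_a)
    expect_true(all(tab >= floor(n / 4) & tab <= ceiling(n / 4)))
  }
})

test_that("guideline classification transforms units and bins on cut points", {
  entry <- guideline_entry("fiber_g", "absolute", c(10, 20),
                           c("low", "adequate", "high"))
  expect_equal(classify_guidelines(15, entry), "adequate")
  expect_equal(classify_guidelines(10, entry), "low")  # boundary -> lower
  day <- nvday(energy_kcal = 2000, protein_g = 70, fat_g = 80,
               sodium_mg = 2400, fiber_g = 15)
  expect_equal(classify_guidelines(day, entry), "adequate")
  # g/kg body weight: 70 g at 70 kg = 1.0
  gkg <- guideline_entry("protein_g", "g_per_kg_bw", c(0.8, 2.0),
                         c("low", "adequate", "high"))
  p70 <- participant("p", "female", 30, 70)
  expect_equal(classify_guidelines(day, gkg, p70), "adequate")
  expect_error(classify_guidelines(day, gkg), "weight")
  # salt: 2400 mg sodium = 6 g salt, boundary belongs to lower
  salt <- guideline_entry("sodium_mg", "salt_g", 6, c("adequate", "high"))
  expect_equal(classify_guidelines(day, salt), "adequate")
  # %TEI: fat 80 g * 9 / 2000 = 36%
  ftei <- guideline_entry("fat_g", "percent_tei", c(20, 35),
                          c("low", "adequate", "high"))
  expect_equal(classify_guidelines(day, ftei), "high")
  expect_error(guideline_entry("x", "absolute", c(2, 1), c("low", "adequate",
                                                           "high")),
               "strictly increasing")
})

test_that("guideline agreement counts matching categories", {
  expect_equal(guideline_agreement(rep("low", 4), rep("low", 4))$prop_same, 1)
  expect_equal(guideline_agreement(rep("low", 4), rep("high", 4))$prop_same, 0)
  a <- c(rep("low", 7), rep("high", 3))
  b <- c(rep("low", 7), rep("adequate", 3))
  expect_equal(guideline_agreement(a, b)$n_same, 7)
  expect_equal(guideline_agreement(a, b)$prop_same, 0.7)
})

test_that("percent difference and its summary use the stated conventions", {
  expect_equal(round(percent_difference(1569.9, 1715.3), 1), 9.3)
  expect_equal(percent_difference(50, 50), 0)
  expect_equal(round(percent_difference(71.8, 84.8), 1), 18.1)
  expect_error(percent_difference(0, 1), "positive")
  expect_equal(summarize_differences(c(-5)), list(median = 5, q1 = 5, q3 = 5))
  expect_equal(summarize_differences(1:9), list(median = 5, q1 = 3, q3 = 7))
  expect_error(summarize_differences(numeric()), "no differences")
})

test_that("run_comparison drives the whole battery per nutrient", {
  set.seed(123)
  n <- 24
  a <- data.frame(participant_id = paste0("p", 1:n),
                  energy_kcal = rlnorm(n, 7.4, 0.3),
                  protein_g = rlnorm(n, 4.2, 0.3))
  # identical methods: perfect agreement everywhere
  res <- run_comparison(a, a)
  expect_equal(nrow(res$rows), 2)
  expect_true(all(res$rows$pct_diff == 0))
  expect_equal(res$rows$spearman_rho, rep(1, 2))
  expect_true(all(res$rows$q_exact == n))
  expect_equal(res$summary$abs_pct_diff_median, 0)

  # known multiplicative bias: Bland-Altman sign matches A - B
  b <- a
  b$energy_kcal <- a$energy_kcal * 1.2
  b$protein_g <- a$protein_g * 1.2
  res2 <- run_comparison(a, b)
  expect_true(all(res2$rows$ba_mean_diff < 0))
  expect_true(all(res2$rows$pct_diff > 0))

  # participant mismatch names the offending ids
  b2 <- b
  b2$participant_id[1] <- "intruder"
  expect_error(run_comparison(a, b2), "intruder")
  expect_error(run_comparison(a, b, nutrients = "missing_col"), "missing_col")

  # exclusion mask drops flagged participants
  res3 <- run_comparison(a, b, exclude = paste0("p", 1:4))
  expect_equal(res3$summary$n_participants, n - 4)
})

test_that("run_comparison recovers an induced mean shift", {
  set.seed(55)
  n <- 200
  truth <- rlnorm(n, 7.4, 0.25)
  a <- data.frame(participant_id = seq_len(n),
                  energy_kcal = truth * exp(rnorm(n, 0, 0.1)))
  b <- data.frame(participant_id = seq_len(n),
                  energy_kcal = truth * 1.15 * exp(rnorm(n, 0, 0.1)))
  res <- run_comparison(a, b)
  induced <- mean(a$energy_kcal - b$energy_kcal)
  expect_equal(res$rows$ba_mean_diff, induced)  # same data, same statistic
  # Monte-Carlo check of the sign and rough magnitude of the shift
  expect_lt(res$rows$ba_mean_diff, 0)
  expect_equal(res$rows$ba_mean_diff / mean(truth), -0.15, tolerance = 0.25)
})

test_that("add_tei_columns appends percent-of-energy variables", {
  tab <- data.frame(participant_id = 1:3, energy_kcal = c(2000, 1800, 2200),
                    protein_g = c(75, 60, 90), fat_g = c(70, 80, 60))
  out <- add_tei_columns(tab)
  expect_equal(out$protein_pcttei, 100 * tab$protein_g * 4 / tab$energy_kcal)
  expect_equal(out$fat_pcttei, 100 * tab$fat_g * 9 / tab$energy_kcal)
  expect_error(add_tei_columns(data.frame(participant_id = 1, protein_g = 2)),
               "energy_kcal")
})
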
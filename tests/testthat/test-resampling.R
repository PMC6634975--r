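test_that("permutation test matches exhaustive enumeration", {
  # identical samples: every regrouping ties the observed difference
  expect_equal(permutation_test(c(3, 3, 3), c(3, 3, 3))$p_value, 1)
  # fully separated triples: only the 2 extreme regroupings of C(6,3) = 20
  res <- permutation_test(c(1, 2, 3), c(101, 102, 103))
  expect_true(res$exact)
  expect_equal(res$n_repeats, 20)
  expect_equal(res$p_value, 2 / 20)
  expect_equal(res$statistic, 100)
  expect_error(permutation_test(1, c(2, 3)), ">= 2")
})

test_that("Monte-Carlo permutation p agrees with exhaustive within binomial error", {
  set.seed(77)
  for (case in 1:8) {
    x <- rnorm(6); y <- rnorm(6, mean = runif(1, 0, 1.5))
    exact <- permutation_test(x, y, n_rep = 2000)$p_value   # C(12,6) = 924
    # force Monte-Carlo by keeping n_rep below the 924 distinct regroupings
    mc <- permutation_test(x, y, n_rep = 800, seed = case)
    expect_false(mc$exact)
    se <- sqrt(exact * (1 - exact) / 800)
    expect_lt(abs(mc$p_value - exact), 3 * se + 2 / 800)
  }
})

test_that("paired permutation test enumerates sign flips exactly", {
  expect_equal(paired_permutation_test(rep(0, 6))$p_value, 1)
  res <- paired_permutation_test(c(1, 1, 1, 1, 1))
  expect_true(res$exact)
  expect_equal(res$n_repeats, 32)
  expect_equal(res$p_value, 2 / 32)
  # p-values never 0 and floored at 1/(n_rep + 1) in Monte-Carlo mode
  big <- paired_permutation_test(rnorm(40, 5), n_rep = 500, seed = 3)
  expect_gte(big$p_value, 1 / 501)
})

test_that("bootstrap CI collapses for constants and brackets the sample mean", {
  expect_equal(unname(bootstrap_ci_mean(rep(2.5, 8), seed = 1)), c(2.5, 2.5))
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(30)
    ci <- bootstrap_ci_mean(x, n_rep = 1000, seed = i)
    expect_lte(ci[1], mean(x))
    expect_gte(ci[2], mean(x))
  }
})

test_that("Cohen's d matches the closed-form oracle", {
  # means differ by 2, pooled SD 1
  x <- c(4, 6); y <- c(2, 4)
  expect_equal(cohens_d(x, y), 2 / sqrt(2))  # pooled SD is sqrt(2) here
  x2 <- c(0, 1, 2); y2 <- c(2, 3, 4)
  expect_equal(cohens_d(x2, x2 + rnorm(3) * 0), 0)
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(12); b <- rnorm(15, 1)
    sp <- sqrt(((11) * var(a) + (14) * var(b)) / 25)
    expect_lt(abs(cohens_d(a, b) - (mean(a) - mean(b)) / sp), 1e-12)
    p1 <- rnorm(10); p2 <- rnorm(10)
    expect_lt(abs(cohens_d(p1, p2, paired = TRUE) -
                    mean(p1 - p2) / sd(p1 - p2)), 1e-12)
  }
  expect_error(cohens_d(c(1, 1, 1), c(1, 1, 1)), "variance")
})

test_that("mixed ANOVA interaction detects a crossed effect and rejects bad input", {
  mk <- function(effect, n = 10, seed = 1) {
    set.seed(seed)
    subj <- factor(rep(seq_len(2 * n), each = 2))
    between <- rep(c("ChR2", "control"), each = 2 * n)
    within <- rep(c("off", "on"), 2 * n)
    base <- rep(rnorm(2 * n, 0.85, 0.05), each = 2)
    y <- base + ifelse(between == "ChR2" & within == "on", -effect, 0) +
      rnorm(4 * n, 0, 0.03)
    data.frame(subject = subj, between = between, within = within, value = y)
  }
  strong <- mixed_anova_interaction(mk(0.15))
  expect_lt(strong$p_value, 0.001)
  expect_gt(strong$statistic, 10)
  # one subject in a group -> error
  bad <- mk(0)[c(1, 2, 21, 22), ]
  bad$subject <- factor(bad$subject)
  expect_error(mixed_anova_interaction(bad), ">= 2 subjects")
  # incomplete within data -> error
  expect_error(mixed_anova_interaction(mk(0)[-1, ]), "unbalanced")
})

test_that("crossed laser-by-genotype effects are detected with adequate power", {
  detect <- 0
  n_sim <- 25
  for (s in seq_len(n_sim)) {
    set.seed(6000 + s)
    subj <- factor(rep(1:20, each = 2))
    between <- rep(c("ChR2", "control"), each = 20)
    within <- rep(c("off", "on"), 20)
    base <- rep(rnorm(20, 0, 1), each = 2)
    y <- base + ifelse(between == "ChR2" & within == "on", -1, 0) +
      rnorm(40, 0, 0.5)
    p <- mixed_anova_interaction(
      data.frame(subject = subj, between = between, within = within,
                 value = y))$p_value
    if (p < 0.05) detect <- detect + 1
  }
  expect_gte(detect / n_sim, 0.8)
})

test_that("outlier detection flags IQR violations and respects symmetry", {
  x <- c(1, 2, 3, 100)
  expect_equal(detect_outliers(x, "quantile"), c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(detect_outliers(-x, "quantile"),
               detect_outliers(x, "quantile"))
  set.seed(8)
  y <- rnorm(30)
  expect_equal(detect_outliers(y, "grubbs"), detect_outliers(-y, "grubbs"))
  # a gross contaminant is caught by Grubbs
  expect_true(detect_outliers(c(rnorm(20), 50), "grubbs")[21])
  expect_error(detect_outliers(c(1, 2, 3), "quantile"), ">= 4")
  expect_error(detect_outliers(c(1, 2), "grubbs"), ">= 3")
})

test_that("Grubbs false-positive rate stays near its nominal level", {
  set.seed(99)
  flags <- vapply(seq_len(500), function(i)
    any(detect_outliers(rnorm(15), "grubbs")), logical(1))
  expect_lte(mean(flags), 0.08)
})

test_that("2x2 chi-square matches the closed form and base R", {
  res <- chisq_fraction_test(40, 100, 10, 100)
  expect_equal(res$statistic, 24)
  expect_equal(res$p_value, pchisq(24, 1, lower.tail = FALSE))
  # equal fractions -> statistic 0, p = 1
  eq <- chisq_fraction_test(30, 60, 15, 30)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # symmetric in the two groups
  expect_equal(chisq_fraction_test(7, 30, 19, 40)$statistic,
               chisq_fraction_test(19, 40, 7, 30)$statistic)
  # cross-check against stats::chisq.test without continuity correction
  ct <- chisq.test(matrix(c(40, 60, 10, 90), 2, byrow = TRUE),
                   correct = FALSE)
  expect_equal(res$statistic, unname(ct$statistic))
  # degenerate margins do not produce NaN
  expect_equal(chisq_fraction_test(0, 10, 0, 12)$statistic, 0)
})

test_that("Bonferroni adjustment multiplies and clamps", {
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
  expect_equal(bonferroni_adjust(0.9), 0.9)
  expect_true(all(bonferroni_adjust(runif(20, 0.01, 1)) <= 1))
  expect_error(bonferroni_adjust(c(0.5, 0)), "\\(0, 1\\]")
})
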
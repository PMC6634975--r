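#' Two-sample permutation test on the absolute mean difference
#'
#' The statistic is `|mean(x) - mean(y)|`. The pooled data are repeatedly
#' regrouped into two subsets matching the original group sizes; the p-value
#' is the probability that a regrouped absolute difference is at least the
#' observed one. When the number of distinct regroupings `choose(nx+ny, nx)`
#' does not exceed `n_rep`, all regroupings are enumerated and the exact p is
#' reported; otherwise Monte-Carlo sampling with the `(count + 1)/(n_rep + 1)`
#' correction is used, so Monte-Carlo p-values are never 0.
#'
#' @param x,y Numeric samples (each of length >= 2).
#' @param n_rep Number of Monte-Carlo permutations (and the exhaustiveness
#'   threshold).
#' @param seed Optional integer seed.
#' @return A `wm_test` list: `statistic`, `p_value`, `n_repeats`, `method`,
#'   `exact`.
#' @export
permutation_test <- function(x, y, n_rep = 1000, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) stopf("each sample needs >= 2 values")
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  nx <- length(x); n <- length(pool)
  n_comb <- choose(n, nx)
  if (n_comb <= n_rep) {
    idx <- utils::combn(n, nx)
    diffs <- apply(idx, 2, function(ii)
      abs(mean(pool[ii]) - mean(pool[-ii])))
    p <- sum(diffs >= obs - 1e-12) / n_comb
    return(wm_test(obs, p, n_comb, "permutation (exhaustive)", exact = TRUE))
  }
  diffs <- with_seed(seed, vapply(seq_len(n_rep), function(i) {
    ii <- sample.int(n, nx)
    abs(mean(pool[ii]) - mean(pool[-ii]))
  }, numeric(1)))
  p <- (sum(diffs >= obs - 1e-12) + 1) / (n_rep + 1)
  wm_test(obs, p, n_rep, "permutation (Monte-Carlo)", exact = FALSE)
}

#' Paired permutation test by sign flipping
#'
#' The statistic is `|mean(diffs)|`; the null is generated by independently
#' flipping the sign of each paired difference. All `2^n` sign patterns are
#' enumerated when feasible (`2^n <= n_rep`). All-zero differences give
#' p = 1 by convention.
#'
#' @param diffs Paired differences (length >= 2).
#' @inheritParams permutation_test
#' @export
paired_permutation_test <- function(diffs, n_rep = 1000, seed = NULL) {
  diffs <- as.numeric(diffs)
  n <- length(diffs)
  if (n < 2) stopf("need >= 2 paired differences")
  obs <- abs(mean(diffs))
  if (all(diffs == 0))
    return(wm_test(0, 1, 0, "paired permutation (degenerate)", exact = TRUE))
  if (2^n <= n_rep) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    null <- abs(as.vector(signs %*% diffs) / n)
    p <- sum(null >= obs - 1e-12) / nrow(signs)
    return(wm_test(obs, p, nrow(signs), "paired permutation (exhaustive)",
                   exact = TRUE))
  }
  null <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n * n_rep, replace = TRUE), nrow = n_rep)
    abs(signs %*% diffs / n)
  })
  p <- (sum(null >= obs - 1e-12) + 1) / (n_rep + 1)
  wm_test(obs, p, n_rep, "paired permutation (Monte-Carlo)", exact = FALSE)
}

wm_test <- function(statistic, p_value, n_repeats, method, exact = FALSE,
                    df = NULL) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 n_repeats = n_repeats, method = method, exact = exact,
                 df = df, adjusted_p = NULL),
            class = "wm_test")
}

#' @export
print.wm_test <- function(x, ...) {
  cat(sprintf("<wm_test> %s: statistic %.4g, p = %.4g (%s repeats)\n",
              x$method, x$statistic, x$p_value,
              format(x$n_repeats, big.mark = ",")))
  invisible(x)
}

#' Bootstrap percentile confidence interval for a mean
#'
#' @param x Numeric sample (length >= 1).
#' @param n_rep Number of bootstrap resamples (default 1000).
#' @param alpha Two-sided miscoverage (default 0.05 for a 95% CI).
#' @param seed Optional integer seed.
#' @return Numeric length-2 `c(low, high)`: the `alpha/2` and `1 - alpha/2`
#'   percentiles of the resampled means.
#' @export
bootstrap_ci_mean <- function(x, n_rep = 1000, alpha = 0.05, seed = NULL) {
  x <- as.numeric(x)
  if (length(x) < 1) stopf("empty sample")
  if (length(x) == 1) return(c(low = x, high = x))
  means <- with_seed(seed, {
    idx <- matrix(sample.int(length(x), length(x) * n_rep, replace = TRUE),
                  nrow = n_rep)
    rowMeans(matrix(x[idx], nrow = n_rep))
  })
  q <- stats::quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(low = q[1], high = q[2])
}

#' Cohen's d effect size
#'
#' Unpaired: mean difference over the pooled SD; paired: mean of the
#' differences over their SD.
#'
#' @param x,y Numeric samples; with `paired = TRUE` they must be equal length.
#' @param paired Logical.
#' @export
cohens_d <- function(x, y, paired = FALSE) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) stopf("each sample needs >= 2 values")
  if (paired) {
    if (length(x) != length(y)) stopf("paired samples must have equal length")
    d <- x - y
    s <- stats::sd(d)
    if (s == 0) stopf("zero variance of paired differences")
    return(mean(d) / s)
  }
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  if (sp2 == 0) stopf("zero pooled variance")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Mixed between-within ANOVA interaction test
#'
#' Split-plot ANOVA with one between-subjects factor (e.g. genotype) and one
#' within-subjects factor (e.g. laser on/off); the reported statistic is the
#' F test of the between x within interaction, the study-level significance
#' criterion for an optogenetic effect.
#'
#' @param data A data.frame with columns `subject`, `between`, `within`,
#'   `value` (one value per subject x within cell).
#' @return A `wm_test` with the interaction F, degrees of freedom and p.
#' @export
mixed_anova_interaction <- function(data) {
  req <- c("subject", "between", "within", "value")
  if (!all(req %in% names(data)))
    stopf("data must have columns %s", paste(req, collapse = ", "))
  data$subject <- factor(data$subject)
  data$between <- factor(data$between)
  data$within <- factor(data$within)
  # each subject must sit in exactly one between level, with complete within data
  bt <- unique(data[c("subject", "between")])
  if (anyDuplicated(bt$subject)) stopf("a subject appears in two between-levels")
  counts <- table(data$subject, data$within)
  if (any(counts != 1))
    stopf("unbalanced design: each subject needs exactly one value per within-level")
  if (any(table(bt$between) < 2)) stopf("need >= 2 subjects per between-level")
  fit <- stats::aov(value ~ between * within + Error(subject / within),
                    data = data)
  sm <- summary(fit)
  stratum <- sm[["Error: subject:within"]]
  if (is.null(stratum)) stratum <- sm[["Error: Within"]]
  tab <- stratum[[1]]
  row <- grep("between:within", trimws(rownames(tab)), fixed = TRUE)
  wm_test(tab[row, "F value"], tab[row, "Pr(>F)"], NA_integer_,
          "mixed between-within ANOVA interaction", exact = TRUE,
          df = c(tab[row, "Df"], tab[nrow(tab), "Df"]))
}

# Grubbs critical value for the two-sided test at level alpha.
grubbs_critical <- function(n, alpha) {
  t2 <- stats::qt(1 - alpha / (2 * n), n - 2)^2
  (n - 1) / sqrt(n) * sqrt(t2 / (n - 2 + t2))
}

#' Outlier detection
#'
#' `method = "quantile"`: flags values above `Q3 + 1.5 IQR` or below
#' `Q1 - 1.5 IQR`. `method = "grubbs"`: iterative two-sided Grubbs test at
#' `alpha = 0.05`, removing the most extreme value while significant.
#'
#' @param x Numeric sample (>= 4 values for quantile, >= 3 for grubbs).
#' @param method `"quantile"` or `"grubbs"`.
#' @param alpha Grubbs significance level.
#' @return Logical mask, TRUE for outliers.
#' @export
detect_outliers <- function(x, method = c("quantile", "grubbs"), alpha = 0.05) {
  method <- match.arg(method)
  x <- as.numeric(x)
  if (method == "quantile") {
    if (length(x) < 4) stopf("quantile method needs >= 4 values")
    q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    return(x > q[2] + 1.5 * iqr | x < q[1] - 1.5 * iqr)
  }
  if (length(x) < 3) stopf("grubbs method needs >= 3 values")
  mask <- rep(FALSE, length(x))
  active <- seq_along(x)
  while (length(active) >= 3) {
    xa <- x[active]
    s <- stats::sd(xa)
    if (s == 0) break
    dev <- abs(xa - mean(xa))
    g <- max(dev) / s
    if (g > grubbs_critical(length(xa), alpha)) {
      worst <- active[which.max(dev)]
      mask[worst] <- TRUE
      active <- setdiff(active, worst)
    } else break
  }
  mask
}

#' Chi-square test comparing two fractions
#'
#' 2x2 chi-square statistic without continuity correction, with p from the
#' chi-square distribution with 1 df. Equal fractions give statistic 0 and
#' p = 1; a degenerate margin (all successes or all failures overall) does
#' too.
#'
#' @param k1,n1 Successes and total in group 1.
#' @param k2,n2 Successes and total in group 2.
#' @export
chisq_fraction_test <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  a <- k1; b <- n1 - k1; c_ <- k2; d <- n2 - k2
  n <- n1 + n2
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  stat <- if (denom == 0) 0 else n * (a * d - b * c_)^2 / denom
  wm_test(stat, stats::pchisq(stat, df = 1, lower.tail = FALSE), NA_integer_,
          "2x2 chi-square (no continuity correction)", exact = TRUE, df = 1)
}

#' Bonferroni multiple-comparison adjustment
#'
#' @param p_values Vector of p-values in (0, 1].
#' @return `pmin(1, p * m)` with `m = length(p_values)`.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1)) stopf("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "bonferroni")
}
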
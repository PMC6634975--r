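# labels must have exactly two levels; the first sorted level (e.g. S1) is
# the positive class throughout this module.
two_class_labels <- function(labels, n_trials) {
  if (length(labels) != n_trials)
    stopf("labels length (%d) != number of trials (%d)", length(labels), n_trials)
  lev <- sort(unique(as.character(labels)))
  if (length(lev) != 2) stopf("exactly two sample labels required, got %d",
                              length(lev))
  counts <- table(factor(labels, lev))
  if (any(counts == 0)) stopf("a label has zero trials")
  list(levels = lev, pos = labels == lev[1])
}

#' Firing-rate selectivity index
#'
#' `(FR_pos - FR_neg) / (FR_pos + FR_neg)` per unit and bin, where the FRs are
#' mean rates over the trials of each sample label (the alphabetically first
#' label, e.g. S1, is positive). Bounded in [-1, 1]; defined as 0 when both
#' means are 0.
#'
#' @param binned A `binned_rates` object (raw Hz; rates must be nonnegative).
#' @param labels Sample label per trial of `binned`.
#' @return Matrix units x bins.
#' @export
selectivity_index <- function(binned, labels) {
  lab <- two_class_labels(labels, length(binned$trial_ids))
  if (binned$normalized)
    stopf("selectivity_index expects raw (nonnegative) rates, not Z-scores")
  m1 <- apply(binned$rates[, lab$pos, , drop = FALSE], c(1, 3), mean)
  m2 <- apply(binned$rates[, !lab$pos, , drop = FALSE], c(1, 3), mean)
  num <- m1 - m2
  den <- m1 + m2
  out <- ifelse(den == 0, 0, num / den)
  dimnames(out) <- list(binned$unit_ids, NULL)
  out
}

# Trapezoidal ROC area for positive-class scores vs negative-class scores,
# sweeping thresholds over the pooled unique values (ties contribute
# trapezoids, matching the average-rank convention).
roc_auc <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- c(0, vapply(thr, function(t) mean(pos >= t), numeric(1)))
  fpr <- c(0, vapply(thr, function(t) mean(neg >= t), numeric(1)))
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Area under the ROC for single-trial sample discrimination
#'
#' Per unit and bin, the area under the ROC curve for discriminating the
#' sample label from single-trial rates (alphabetically first label positive;
#' tied rates handled by the trapezoidal convention, equivalent to the
#' Mann-Whitney U statistic divided by `n1 * n2`). 0.5 means no
#' discrimination.
#'
#' @param binned A `binned_rates` (raw or Z-scored).
#' @param labels Sample label per trial.
#' @param trial_subset Optional trial-id subset (e.g. correct or error trials).
#' @return Matrix units x bins of auROC values in [0, 1].
#' @export
auroc <- function(binned, labels, trial_subset = NULL) {
  keep <- if (is.null(trial_subset)) seq_along(binned$trial_ids)
          else match(trial_subset, binned$trial_ids)
  if (anyNA(keep)) stopf("trial_subset contains unknown trial ids")
  labels <- labels[keep]
  lab <- two_class_labels(labels, length(keep))
  if (sum(lab$pos) < 2 || sum(!lab$pos) < 2)
    stopf("need >= 2 trials per label")
  rates <- binned$rates[, keep, , drop = FALSE]
  n_units <- dim(rates)[1]; n_bins <- dim(rates)[3]
  out <- matrix(NA_real_, n_units, n_bins,
                dimnames = list(binned$unit_ids, NULL))
  for (u in seq_len(n_units)) for (b in seq_len(n_bins))
    out[u, b] <- roc_auc(rates[u, lab$pos, b], rates[u, !lab$pos, b])
  out
}

#' Time course of the selective-neuron fraction
#'
#' A unit is selective in a bin when its label-permutation p-value (absolute
#' mean-rate difference statistic, shared label permutations across units and
#' bins, `(count + 1)/(n_perm + 1)` correction) is below `alpha`. The
#' per-bin fraction of selective units is compared to the pre-sample baseline
#' bin with the 2x2 chi-square test.
#'
#' @param binned A `binned_rates`.
#' @param labels Sample label per trial.
#' @param alpha Per-unit selectivity criterion (default 0.05).
#' @param n_perm Label permutations (>= 100; default 1000).
#' @param seed Optional integer seed.
#' @param baseline_window Window identifying the baseline bin (default the 1 s
#'   before sample onset); the first fully contained bin is used.
#' @return List: `fraction` per bin, `selective` (units x bins logical),
#'   `p_values` (units x bins), `baseline_bin`, `chisq_vs_baseline`
#'   (data.frame with per-bin statistic and p).
#' @export
selective_fraction_timecourse <- function(binned, labels, alpha = 0.05,
                                          n_perm = 1000, seed = NULL,
                                          baseline_window = c(-1, 0)) {
  if (n_perm < 100) stopf("n_perm must be >= 100 for stable p-values")
  lab <- two_class_labels(labels, length(binned$trial_ids))
  n_units <- dim(binned$rates)[1]
  n_trials <- dim(binned$rates)[2]
  n_bins <- dim(binned$rates)[3]
  # flatten to (units*bins) x trials for fast permutation via matrix products
  R <- matrix(aperm(binned$rates, c(1, 3, 2)), nrow = n_units * n_bins,
              ncol = n_trials)
  contrast <- ifelse(lab$pos, 1 / sum(lab$pos), -1 / sum(!lab$pos))
  obs <- abs(R %*% contrast)
  exceed <- matrix(0, n_units * n_bins, 1)
  with_seed(seed, {
    for (p in seq_len(n_perm)) {
      null <- abs(R %*% contrast[sample.int(n_trials)])
      exceed <- exceed + (null >= obs - 1e-12)
    }
  })
  p_flat <- (exceed + 1) / (n_perm + 1)
  p_values <- matrix(p_flat, n_units, n_bins,
                     dimnames = list(binned$unit_ids, NULL))
  selective <- p_values < alpha
  fraction <- colMeans(selective)
  bl_bins <- bins_in_window(binned, baseline_window)
  if (length(bl_bins) == 0) stopf("no bin lies inside the baseline window")
  baseline_bin <- bl_bins[1]
  k_base <- sum(selective[, baseline_bin])
  chisq <- lapply(seq_len(n_bins), function(b)
    chisq_fraction_test(sum(selective[, b]), n_units, k_base, n_units))
  list(fraction = fraction, selective = selective, p_values = p_values,
       baseline_bin = baseline_bin,
       chisq_vs_baseline = data.frame(
         bin = seq_len(n_bins), bin_start_s = binned$bin_starts,
         statistic = vapply(chisq, `[[`, numeric(1), "statistic"),
         p_value = vapply(chisq, `[[`, numeric(1), "p_value")))
}

#' Classify selectivity persistence
#'
#' Total significant time (all significant bins counted, not only the longest
#' run) above 5 s makes a unit persistent, above 0.5 s transient, otherwise
#' nonselective. A persistent unit also meets the transient criterion.
#'
#' @param sig_mask Logical significance mask over contiguous bins (one unit),
#'   or a units x bins matrix.
#' @param bin_duration_s Duration credited to each significant bin. For
#'   non-overlapping bins this is the bin width; for overlapping bins pass the
#'   step.
#' @return Character class(es): `"nonselective"`, `"transient"`, `"persistent"`.
#' @export
classify_persistence <- function(sig_mask, bin_duration_s) {
  classify_one <- function(mask) {
    total <- sum(mask) * bin_duration_s
    if (total > 5) "persistent" else if (total > 0.5) "transient" else "nonselective"
  }
  if (is.matrix(sig_mask)) apply(sig_mask, 1, classify_one)
  else classify_one(sig_mask)
}

#' Heat-map ordering of units by delay-period selectivity
#'
#' Returns the unit ordering (an index vector) by decreasing
#' `FR_pos - FR_neg` computed over the delay-period bins, the convention used
#' to sort population activity heat maps.
#'
#' @param binned A `binned_rates`.
#' @param labels Sample label per trial.
#' @param delay_window Length-2 window over which delay-period rates are
#'   averaged.
#' @export
order_units_by_selectivity <- function(binned, labels, delay_window) {
  lab <- two_class_labels(labels, length(binned$trial_ids))
  bins <- bins_in_window(binned, delay_window)
  if (length(bins) == 0) stopf("no bins inside the delay window")
  m1 <- apply(binned$rates[, lab$pos, bins, drop = FALSE], 1, mean)
  m2 <- apply(binned$rates[, !lab$pos, bins, drop = FALSE], 1, mean)
  order(m1 - m2, decreasing = TRUE)
}
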
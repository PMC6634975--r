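#' Bin spike trains into a units x trials x bins rate array
#'
#' Spike counts are taken in half-open bins `[t0 + b*step, t0 + b*step + width)`
#' and divided by the bin width to give rates in Hz. The number of bins is
#' `floor((t1 - t0 - width)/step) + 1`; overlapping bins (`step < width`) are
#' allowed. Time 0 is sample-odor onset. A (unit, trial) pair with no row in
#' the spike table contributes zero counts.
#'
#' @param spikes A [spike_table()].
#' @param trials The companion [trial_table()].
#' @param bin_width_s Bin width in seconds (> 0).
#' @param step_s Step between bin starts in seconds (> 0).
#' @param window Numeric length-2, the half-open analysis window `[t0, t1)`.
#' @param trial_ids Optional subset of trials to bin (default: all).
#' @return A `binned_rates` object: list with `rates` (array units x trials x
#'   bins, Hz), `bin_starts`, `bin_width_s`, `step_s`, `window`, `unit_ids`,
#'   `trial_ids`, `normalized` and (after [zscore_to_baseline()])
#'   `baseline_window` and `baseline_stats`.
#' @export
bin_spikes <- function(spikes, trials, bin_width_s, step_s, window,
                       trial_ids = NULL) {
  stopifnot(bin_width_s > 0, step_s > 0, length(window) == 2)
  t0 <- window[1]; t1 <- window[2]
  if (t1 - t0 < bin_width_s)
    stopf("window [%g, %g) is shorter than one bin", t0, t1)
  trial_ids <- trial_ids %||% trials$trial_id
  trials_sub <- trials[match(trial_ids, trials$trial_id), , drop = FALSE]
  if (anyNA(trials_sub$trial_id)) stopf("trial_ids not present in trial table")
  span <- trial_span(trials_sub)
  short <- which(span[, "start"] > t0 | span[, "end"] < t1)
  if (length(short) > 0)
    stopf("analysis window [%g, %g) exceeds the recorded span of trial(s): %s",
          t0, t1, paste(utils::head(trials_sub$trial_id[short], 10), collapse = ", "))
  n_bins <- floor((t1 - t0 - bin_width_s) / step_s) + 1
  bin_starts <- t0 + (seq_len(n_bins) - 1) * step_s
  unit_ids <- sort(unique(spikes$unit_id))
  rates <- array(0, dim = c(length(unit_ids), length(trial_ids), n_bins),
                 dimnames = list(unit_ids, as.character(trial_ids), NULL))
  keep <- spikes$trial_id %in% trial_ids
  ui <- match(spikes$unit_id[keep], unit_ids)
  ti <- match(spikes$trial_id[keep], trial_ids)
  sts <- spikes$spike_times_s[keep]
  for (r in seq_along(ui)) {
    st <- sts[[r]]
    if (length(st) == 0) next
    counts <- vapply(bin_starts,
                     function(s) sum(st >= s & st < s + bin_width_s), numeric(1))
    rates[ui[r], ti[r], ] <- counts / bin_width_s
  }
  structure(list(rates = rates, bin_starts = bin_starts,
                 bin_width_s = bin_width_s, step_s = step_s, window = window,
                 unit_ids = unit_ids, trial_ids = trial_ids,
                 normalized = FALSE, baseline_window = NULL,
                 baseline_stats = NULL),
            class = "binned_rates")
}

#' @export
print.binned_rates <- function(x, ...) {
  cat(sprintf(
    "<binned_rates> %d units x %d trials x %d bins; width %g s, step %g s, window [%g, %g)%s\n",
    dim(x$rates)[1], dim(x$rates)[2], dim(x$rates)[3],
    x$bin_width_s, x$step_s, x$window[1], x$window[2],
    if (x$normalized) "; Z-scored" else ""))
  invisible(x)
}

# Indices of bins lying fully inside a window.
bins_in_window <- function(binned, window) {
  which(binned$bin_starts >= window[1] - 1e-9 &
          binned$bin_starts + binned$bin_width_s <= window[2] + 1e-9)
}

#' Z-score binned rates against a pre-sample baseline
#'
#' For each unit, the per-trial baseline rate (mean rate over the bins inside
#' `baseline_window`, one value per trial) is computed across `baseline_trials`;
#' its mean and SD convert all of the unit's rates to Z-scores. A unit whose
#' baseline SD is zero gets SD substituted by 1 and is reported in the
#' `degenerate_units` attribute (its Z-scores stay finite and flag the unit).
#' The stored baseline statistics make the transform invertible.
#'
#' @param binned A `binned_rates` object (not yet normalized).
#' @param baseline_window Length-2 window inside `binned$window`, canonically
#'   the 1 s before sample onset, `c(-1, 0)`.
#' @param baseline_trials Optional trial ids over which baseline statistics are
#'   computed (default: all trials in `binned`).
#' @return A normalized `binned_rates` with `baseline_stats` (per-unit mean/SD).
#' @export
zscore_to_baseline <- function(binned, baseline_window = c(-1, 0),
                               baseline_trials = NULL) {
  stopifnot(inherits(binned, "binned_rates"))
  if (binned$normalized) stopf("rates are already normalized")
  if (baseline_window[1] < binned$window[1] - 1e-9 ||
      baseline_window[2] > binned$window[2] + 1e-9)
    stopf("baseline window must lie within the binned window")
  bl_bins <- bins_in_window(binned, baseline_window)
  if (length(bl_bins) == 0) stopf("no bins fall inside the baseline window")
  tr_idx <- if (is.null(baseline_trials)) seq_along(binned$trial_ids)
            else match(baseline_trials, binned$trial_ids)
  if (anyNA(tr_idx)) stopf("baseline_trials not present in binned data")
  n_units <- dim(binned$rates)[1]
  mu <- numeric(n_units); sd_ <- numeric(n_units)
  degenerate <- character(0)
  for (u in seq_len(n_units)) {
    # per-trial baseline rate vector: one mean over the baseline bins per trial
    bl <- apply(binned$rates[u, tr_idx, bl_bins, drop = FALSE], 2, mean)
    mu[u] <- mean(bl)
    s <- stats::sd(bl)
    if (is.na(s) || s == 0) {
      s <- 1
      degenerate <- c(degenerate, binned$unit_ids[u])
    }
    sd_[u] <- s
  }
  if (length(degenerate) > 0)
    warnf("baseline SD is 0 for unit(s) %s; SD of 1 substituted",
          paste(degenerate, collapse = ", "))
  out <- binned
  out$rates <- sweep(sweep(binned$rates, 1, mu, "-"), 1, sd_, "/")
  out$normalized <- TRUE
  out$baseline_window <- baseline_window
  out$baseline_stats <- data.frame(unit_id = binned$unit_ids,
                                   baseline_mean = mu, baseline_sd = sd_,
                                   degenerate = binned$unit_ids %in% degenerate,
                                   stringsAsFactors = FALSE)
  out
}

#' Invert a baseline Z-scoring
#'
#' @param binned A normalized `binned_rates` from [zscore_to_baseline()].
#' @return The `binned_rates` on the original Hz scale.
#' @export
unzscore <- function(binned) {
  stopifnot(inherits(binned, "binned_rates"), isTRUE(binned$normalized))
  out <- binned
  out$rates <- sweep(sweep(binned$rates, 1, binned$baseline_stats$baseline_sd, "*"),
                     1, binned$baseline_stats$baseline_mean, "+")
  out$normalized <- FALSE
  out$baseline_window <- NULL
  out$baseline_stats <- NULL
  out
}

#' Single-unit quality control
#'
#' One report per unit: total spike count, fraction of inter-spike intervals
#' shorter than the 2 ms refractory period (the spike-sorting false-alarm
#' rate), and mean firing rate over the total recorded trial time. A unit
#' passes when the ISI-violation fraction is at most 0.15% and its mean rate
#' exceeds 2 Hz. Units with fewer than 2 spikes have an ISI-violation fraction
#' of 0 and are still evaluated.
#'
#' @param spikes A [spike_table()].
#' @param trials The companion [trial_table()]; the recorded time is the sum of
#'   per-trial recording windows (1 s pre-sample through response-window end).
#' @param refractory_s Refractory period in seconds (default 0.002).
#' @param max_isi_violation Maximum tolerated ISI-violation fraction (0.0015).
#' @param min_rate_hz Minimum mean rate in Hz (2).
#' @return A data.frame with one row per unit: `unit_id`, `n_spikes`,
#'   `isi_violation_fraction`, `mean_rate_hz`, `passes`.
#' @export
qc_filter_units <- function(spikes, trials, refractory_s = 0.002,
                            max_isi_violation = 0.0015, min_rate_hz = 2) {
  span <- trial_span(trials)
  total_time <- sum(span[, "end"] - span[, "start"])
  unit_ids <- sort(unique(spikes$unit_id))
  res <- lapply(unit_ids, function(uid) {
    rows <- which(spikes$unit_id == uid)
    n_spk <- 0L; n_isi <- 0L; n_viol <- 0L
    for (r in rows) {
      st <- spikes$spike_times_s[[r]]
      n_spk <- n_spk + length(st)
      if (length(st) >= 2) {
        isi <- diff(st)
        n_isi <- n_isi + length(isi)
        n_viol <- n_viol + sum(isi < refractory_s)
      }
    }
    viol <- if (n_isi > 0) n_viol / n_isi else 0
    rate <- n_spk / total_time
    data.frame(unit_id = uid, n_spikes = n_spk,
               isi_violation_fraction = viol, mean_rate_hz = rate,
               passes = (viol <= max_isi_violation) && (rate > min_rate_hz),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
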
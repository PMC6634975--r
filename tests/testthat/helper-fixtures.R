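# Shared fixture builders; everything is generated in code at test time.

# Minimal hand-built DNMS trial table (n trials cycling the four
# sample-test combinations), delay 4 s, no laser.
fixture_trials <- function(n = 4, delay_s = 4, subject_id = "M01",
                           genotype = "control", lick = NULL) {
  combos <- data.frame(sample_odor = c("S1", "S1", "S2", "S2"),
                       test_odor = c("T1", "T2", "T1", "T2"),
                       stringsAsFactors = FALSE)
  idx <- rep_len(seq_len(4), n)
  tm <- trial_timing_fixture(delay_s)
  df <- data.frame(
    trial_id = seq_len(n), task = "DNMS", subject_id = subject_id,
    genotype = genotype,
    sample_odor = combos$sample_odor[idx], test_odor = combos$test_odor[idx],
    relation = ifelse(combos$sample_odor[idx] ==
                        sub("T", "S", combos$test_odor[idx]),
                      "match", "nonmatch"),
    delay_s = delay_s, distractor = NA_character_, laser_on = FALSE,
    laser_onset_s = NA_real_, laser_duration_s = NA_real_,
    perturb_epoch = "none",
    resp_win_start_s = tm$resp0, resp_win_end_s = tm$resp1,
    stringsAsFactors = FALSE)
  df$lick_times_s <- if (is.null(lick)) replicate(n, numeric(0), simplify = FALSE)
                     else lick
  df$outcome <- NA_character_
  trial_table(df)
}

trial_timing_fixture <- function(delay_s) {
  list(resp0 = 3 + delay_s, resp1 = 3.5 + delay_s)
}

# Construct a binned_rates object directly from a units x trials x bins array.
make_binned <- function(rates, bin_width_s = 0.5, step_s = 0.5, t0 = -1) {
  n_bins <- dim(rates)[3]
  unit_ids <- sprintf("u%03d", seq_len(dim(rates)[1]))
  dimnames(rates) <- list(unit_ids, as.character(seq_len(dim(rates)[2])), NULL)
  structure(list(rates = rates,
                 bin_starts = t0 + (seq_len(n_bins) - 1) * step_s,
                 bin_width_s = bin_width_s, step_s = step_s,
                 window = c(t0, t0 + (n_bins - 1) * step_s + bin_width_s),
                 unit_ids = unit_ids,
                 trial_ids = seq_len(dim(rates)[2]),
                 normalized = FALSE, baseline_window = NULL,
                 baseline_stats = NULL),
            class = "binned_rates")
}

# Small synthetic DNMS recording used by the selectivity / decoding tests.
gen_recording <- function(n_trials = 80, n_units = 8, sel_hz = 6,
                          delay_s = 4, sel_tau = 20, baseline = 5,
                          error_atten = 0.3, seed = 1, lapse = 0,
                          amplitude_A = 0.45) {
  spec <- behavior_gen_spec(n_subjects = 1, n_trials_per_subject = n_trials,
                            lapse_rate = lapse, amplitude_A = amplitude_A)
  trials <- simulate_behavior_cohort(
    spec, list(task = "DNMS", delays_s = delay_s, laser_scheme = "none"),
    seed = seed)
  neurons <- lapply(seq_len(n_units), function(i)
    neuron_spec(baseline_rate_hz = baseline, delay_selectivity_hz = sel_hz,
                selectivity_decay_tau_s = sel_tau,
                error_trial_attenuation = error_atten,
                preferred_sample = if (i %% 2 == 0) "S1" else "S2",
                unit_id = sprintf("u%03d", i)))
  spikes <- simulate_session(neurons, trials, seed = seed + 1000)
  list(trials = trials, spikes = spikes, neurons = neurons)
}

# Stack a copy of every unit on top of the original array (redundancy tests).
abind_units <- function(r) {
  out <- array(NA_real_, dim = c(2 * dim(r)[1], dim(r)[2], dim(r)[3]))
  out[seq_len(dim(r)[1]), , ] <- r
  out[dim(r)[1] + seq_len(dim(r)[1]), , ] <- r
  out
}

small_decoder_config <- function(n_repeats = 40, seed = 11, n_shuffles = 0,
                                 ...) {
  decoder_config(c_grid = 2^c(-1, 1, 3), gamma_grid = 2^c(-6, -3, 0),
                 n_repeats = n_repeats, n_shuffles = n_shuffles,
                 shuffle_repeats = 15, seed = seed, ...)
}
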
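test_that("trial TSV round-trips losslessly and canonically", {
  trials <- fixture_trials(3, lick = list(numeric(0), c(7.1, 7.2), 8.25))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_trials(trials, f1)
  loaded <- read_trials(f1)
  expect_equal(loaded$lick_times_s, trials$lick_times_s)
  expect_equal(loaded$delay_s, trials$delay_s)
  expect_identical(loaded$outcome, trials$outcome)
  # canonical form is a fixed point of write . read
  write_trials(read_trials(f1), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("write/read round-trip is lossless on random synthetic sessions", {
  for (s in 1:20) {
    spec <- behavior_gen_spec(n_subjects = 2, n_trials_per_subject = 16)
    trials <- simulate_behavior_cohort(
      spec, list(task = "DNMS", delays_s = c(5, 10),
                 laser_scheme = "interleaved"), seed = s)
    f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
    write_trials(trials, f1)
    write_trials(read_trials(f1), f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    unlink(c(f1, f2))
  }
})

test_that("validation rejects malformed tables with row-level messages", {
  trials <- fixture_trials(3)
  bad <- as.data.frame(trials)
  bad$sample_odor[2] <- "S9"
  expect_error(trial_table(bad), "sample_odor.*row 2")
  bad <- as.data.frame(trials)
  bad$sample_odor[3] <- "S3"  # valid for MSDPA only
  expect_error(trial_table(bad), "row 3.*S1/S2")
  bad <- as.data.frame(trials)
  bad$relation[1] <- "nonmatch"  # S1-T1 is a match in DNMS
  expect_error(trial_table(bad), "inconsistent")
  bad <- as.data.frame(trials)
  bad$laser_on[1] <- TRUE  # laser fields must accompany laser_on
  expect_error(trial_table(bad), "laser")
  expect_error(trial_table(trials[, -3]), "missing required column")
})

test_that("spike tables are cross-checked against trials", {
  trials <- fixture_trials(2)
  good <- data.frame(unit_id = "u1", trial_id = 1L,
                     spike_times_s = I(list(c(0.1, 0.2))))
  expect_s3_class(spike_table(good, trials), "spike_table")
  orphan <- data.frame(unit_id = "u1", trial_id = 99L,
                       spike_times_s = I(list(0.1)))
  expect_error(spike_table(orphan, trials), "unknown trial_id")
  unsorted <- data.frame(unit_id = "u1", trial_id = 1L,
                         spike_times_s = I(list(c(0.2, 0.1))))
  expect_error(spike_table(unsorted, trials), "sorted")
})

test_that("load_session validates and links both files", {
  trials <- fixture_trials(3)
  spikes <- spike_table(data.frame(
    unit_id = c("u1", "u1", "u2"), trial_id = c(1L, 2L, 1L),
    spike_times_s = I(list(c(-0.5, 0.1), c(1.5), numeric(0)))), trials)
  ft <- tempfile(fileext = ".tsv"); fs <- tempfile(fileext = ".tsv")
  write_session(list(trials = trials, spikes = spikes), ft, fs)
  sess <- load_session(ft, fs)
  expect_equal(nrow(sess$trials), 3)
  expect_equal(sess$spikes$spike_times_s, spikes$spike_times_s)
  unlink(c(ft, fs))
})

test_that("bin_spikes computes half-open bin rates", {
  trials <- fixture_trials(1)
  spikes <- spike_table(data.frame(
    unit_id = "u1", trial_id = 1L,
    spike_times_s = I(list(c(0.1, 0.25, 0.9)))), trials)
  b <- bin_spikes(spikes, trials, 0.5, 0.5, c(0, 1))
  expect_equal(as.numeric(b$rates[1, 1, ]), c(4, 2))
  # no spikes -> all-zero matrix
  empty <- spike_table(data.frame(unit_id = "u1", trial_id = 1L,
                                  spike_times_s = I(list(numeric(0)))), trials)
  b0 <- bin_spikes(empty, trials, 0.5, 0.5, c(0, 1))
  expect_true(all(b0$rates == 0))
  # window longer than the recorded span errors with the offending trial
  expect_error(bin_spikes(spikes, trials, 0.5, 0.5, c(0, 100)),
               "exceeds the recorded span.*1")
})

test_that("non-overlapping bins conserve spike counts", {
  rec <- gen_recording(n_trials = 8, n_units = 3, seed = 5)
  b <- bin_spikes(rec$spikes, rec$trials, 0.5, 0.5, c(-1, 7))
  counts <- b$rates * b$bin_width_s
  for (r in seq_len(nrow(rec$spikes))) {
    st <- rec$spikes$spike_times_s[[r]]
    u <- match(rec$spikes$unit_id[r], b$unit_ids)
    k <- match(rec$spikes$trial_id[r], b$trial_ids)
    expect_equal(sum(counts[u, k, ]), sum(st >= -1 & st < 7))
  }
})

test_that("homogeneous Poisson binning recovers the generating rate", {
  trials <- fixture_trials(200)
  neuron <- neuron_spec(baseline_rate_hz = 10, odor_gain = 1,
                        delay_selectivity_hz = 0, refractory_s = 0)
  spikes <- simulate_session(list(neuron), trials, seed = 99)
  b <- bin_spikes(spikes, trials, 0.2, 0.2, c(-1, 7))
  grand <- mean(b$rates)
  # SE of the grand mean rate: total expected count / total time
  se <- sqrt(10 / (200 * 8))
  expect_lt(abs(grand - 10), 3 * se)
})

test_that("z-scoring against baseline normalizes and inverts exactly", {
  # unit with baseline mean 5 Hz, SD 2 Hz: a 9 Hz bin maps to z = 2
  rates <- array(0, dim = c(1, 4, 3))
  rates[1, , 1] <- c(3, 5, 5, 7)   # baseline bin: mean 5, sd ~1.63
  rates[1, , 2] <- 9
  b <- make_binned(rates, bin_width_s = 1, step_s = 1, t0 = -1)
  z <- zscore_to_baseline(b, c(-1, 0))
  sd_bl <- sd(c(3, 5, 5, 7))
  expect_equal(z$rates[1, 1, 2], (9 - 5) / sd_bl)
  # invertibility
  back <- unzscore(z)
  expect_lt(max(abs(back$rates - b$rates)), 1e-9)
  # constant-rate unit falls under the degenerate rule: all z = 0
  flat <- make_binned(array(4, dim = c(1, 4, 3)), 1, 1, -1)
  expect_warning(zf <- zscore_to_baseline(flat, c(-1, 0)), "SD of 1")
  expect_true(all(zf$rates == 0))
})

test_that("baseline z-values have mean 0 and SD 1 per unit after normalization", {
  set.seed(42)
  for (rep in 1:5) {
    rates <- array(rexp(10 * 30 * 6, rate = 1 / 5), dim = c(10, 30, 6))
    b <- make_binned(rates, 0.5, 0.5, t0 = -1)
    z <- zscore_to_baseline(b, c(-1, 0))
    bl_bins <- which(z$bin_starts >= -1 - 1e-9 &
                       z$bin_starts + z$bin_width_s <= 1e-9)
    for (u in 1:10) {
      bl <- apply(z$rates[u, , bl_bins, drop = FALSE], 2, mean)
      expect_lt(abs(mean(bl)), 1e-9)
      expect_lt(abs(sd(bl) - 1), 1e-9)
    }
  }
})

test_that("unit QC applies the ISI and rate thresholds", {
  trials <- fixture_trials(1, delay_s = 16)  # 20.5 s recorded
  mk <- function(st) spike_table(data.frame(
    unit_id = "u1", trial_id = 1L, spike_times_s = I(list(st))), trials)
  # 1000 spikes with 2 ISI violations: 0.2% > 0.15% -> fail
  st <- seq(0.005, by = 0.005, length.out = 1000)
  st[2] <- st[1] + 0.001
  st[500] <- st[499] + 0.001
  st <- sort(st)
  qc <- qc_filter_units(mk(st), trials)
  expect_gt(qc$isi_violation_fraction, 0.0015)
  expect_false(qc$passes)
  # clean ISIs but 1.5 Hz -> fail on rate
  st2 <- seq(0, 19, length.out = round(1.5 * 20.5))
  qc2 <- qc_filter_units(mk(st2), trials)
  expect_lt(abs(qc2$mean_rate_hz - 1.5), 0.1)
  expect_false(qc2$passes)
  # ~5 Hz, no violations -> pass
  st3 <- seq(-1, 19.4, by = 1 / 5.2)
  qc3 <- qc_filter_units(mk(st3), trials)
  expect_true(qc3$passes)
  # < 2 spikes: ISI fraction defined as 0, still evaluated
  qc4 <- qc_filter_units(mk(0.5), trials)
  expect_equal(qc4$isi_violation_fraction, 0)
  expect_false(qc4$passes)
})
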
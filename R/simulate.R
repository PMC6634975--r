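#' Specifications for the synthetic-data generator
#'
#' `behavior_gen_spec()` parameterizes the behavioral generator: per-trial
#' correct probability follows an exponential memory-decay model
#' `p(delay) = chance + A * exp(-delay / tau)`, degraded by optogenetic
#' suppression (only when the genotype is ChR2 and the perturbation hits the
#' delay epoch) and by an inner distracting task in dual-task trials. The
#' laser-induced drop grows linearly with laser duration and with onset phase
#' within the delay (late > early) and can at worst push performance to
#' chance; a lapse rate mixes in chance-level guessing.
#'
#' `neuron_spec()` parameterizes one synthetic unit: Poisson spiking at a
#' baseline rate, multiplicative gain during odor delivery, additive
#' sample-odor selectivity during the delay that decays exponentially from
#' delay onset, attenuated selectivity in error trials, and a (possibly
#' cue-specific) response to the dual-task distractor odor.
#'
#' @param chance_level Chance correct probability (0.5 for two-alternative).
#' @param amplitude_A Probability mass above chance at zero delay.
#' @param decay_tau_s Memory decay time constant in seconds.
#' @param laser_effect List with `slope_per_s` (correct-rate drop per second of
#'   delay-period laser) and `phase_gain` (additional weight for late onsets).
#' @param distractor_effect Named drop in correct probability per distractor
#'   condition (dual task only).
#' @param lapse_rate Probability of a chance-level guess regardless of memory.
#' @param inner_correct_rate Correct probability of the inner Go/No-go task in
#'   dual-task trials.
#' @param n_subjects,n_trials_per_subject Cohort size.
#' @return A `behavior_gen_spec` / `neuron_spec` list.
#' @export
behavior_gen_spec <- function(chance_level = 0.5, amplitude_A = 0.45,
                              decay_tau_s = 20,
                              laser_effect = list(slope_per_s = 0.012,
                                                  phase_gain = 1),
                              distractor_effect = c(none = 0, nogo = 0.04,
                                                    go = 0.08),
                              lapse_rate = 0.02, inner_correct_rate = 0.9,
                              n_subjects = 10, n_trials_per_subject = 200) {
  stopifnot(chance_level > 0, chance_level < 1,
            amplitude_A >= 0, chance_level + amplitude_A <= 1,
            decay_tau_s > 0, lapse_rate >= 0, lapse_rate < 1,
            n_subjects >= 1, n_trials_per_subject >= 1)
  structure(list(chance_level = chance_level, amplitude_A = amplitude_A,
                 decay_tau_s = decay_tau_s, laser_effect = laser_effect,
                 distractor_effect = distractor_effect,
                 lapse_rate = lapse_rate,
                 inner_correct_rate = inner_correct_rate,
                 n_subjects = n_subjects,
                 n_trials_per_subject = n_trials_per_subject),
            class = "behavior_gen_spec")
}

#' @rdname behavior_gen_spec
#' @param baseline_rate_hz Baseline firing rate in Hz (> 0).
#' @param odor_gain Multiplicative rate gain during odor delivery; a scalar
#'   applied in the sample and test epochs, or a named vector per sample odor
#'   (e.g. `c(S1 = 3, S2 = 1.5)`) for odor-selective sensory responses (the
#'   test epoch then uses the mean gain).
#' @param preferred_sample Sample odor eliciting the positive half of the
#'   delay selectivity.
#' @param delay_selectivity_hz Additive preferred-minus-nonpreferred rate
#'   difference at delay onset, Hz; each class gets +/- half of it.
#' @param selectivity_decay_tau_s Decay time constant of delay selectivity, s.
#' @param error_trial_attenuation Factor in [0, 1] multiplying the delay
#'   selectivity in error (miss / false-alarm) trials.
#' @param distractor_gain Gain during the dual-task distractor odor; a scalar
#'   or a named vector `c(go = ..., nogo = ...)` for cue-specific responses.
#' @param refractory_s Absolute refractory period: spikes closer than this to
#'   the previous spike are discarded, as in a well-isolated single unit.
#' @param unit_id Optional unit identifier.
#' @export
neuron_spec <- function(baseline_rate_hz = 5, odor_gain = 2,
                        preferred_sample = "S1", delay_selectivity_hz = 4,
                        selectivity_decay_tau_s = 8,
                        error_trial_attenuation = 0.3, distractor_gain = 1,
                        refractory_s = 0.003, unit_id = NULL) {
  stopifnot(baseline_rate_hz > 0, odor_gain >= 0,
            delay_selectivity_hz >= 0, selectivity_decay_tau_s > 0,
            error_trial_attenuation >= 0, error_trial_attenuation <= 1,
            all(distractor_gain >= 0), refractory_s >= 0)
  if (!preferred_sample %in% wm_samples)
    stopf("preferred_sample must be one of %s", paste(wm_samples, collapse = ", "))
  structure(list(baseline_rate_hz = baseline_rate_hz, odor_gain = odor_gain,
                 preferred_sample = preferred_sample,
                 delay_selectivity_hz = delay_selectivity_hz,
                 selectivity_decay_tau_s = selectivity_decay_tau_s,
                 error_trial_attenuation = error_trial_attenuation,
                 distractor_gain = distractor_gain,
                 refractory_s = refractory_s, unit_id = unit_id),
            class = "neuron_spec")
}

# Trial-epoch timing, all relative to sample onset (t = 0): 1 s sample odor,
# delay, 1 s test odor, 1 s pre-response delay, 0.5 s response window. The
# dual-task inner cue starts 3 s into the delay (t = 4 s), lasts 0.5 s, and is
# followed by a 0.5 s pre-response delay and a 0.5 s inner response window.
trial_timing <- function(delay_s) {
  list(sample = c(0, 1), delay = c(1, 1 + delay_s),
       test = c(1 + delay_s, 2 + delay_s),
       resp_win = c(3 + delay_s, 3.5 + delay_s),
       inner_cue = c(4, 4.5), inner_resp = c(5, 5.5))
}

# One balanced block of four sample-test combinations for a two-sample task.
balanced_block <- function(task) {
  if (task == "GNG") {
    df <- data.frame(sample_odor = c("S1", "S1", "S2", "S2"),
                     test_odor = NA_character_, stringsAsFactors = FALSE)
  } else if (task == "MSDPA") {
    s <- c(sample(paste0("S", 1:3), 2), sample(paste0("S", 4:6), 2))
    df <- data.frame(sample_odor = s,
                     test_odor = c("T1", "T2", "T2", "T1"),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(sample_odor = c("S1", "S1", "S2", "S2"),
                     test_odor = c("T1", "T2", "T1", "T2"),
                     stringsAsFactors = FALSE)
  }
  df[sample.int(4), , drop = FALSE]
}

#' Simulate a behavioral cohort
#'
#' Generates a full [trial_table()] for a cohort of subjects: stimulus
#' combinations balanced and shuffled within every block of four consecutive
#' trials, laser trials interleaved one-on/one-off (starting laser-off) or in
#' alternating 24-trial blocks, outcomes drawn Bernoulli from the exponential
#' memory-decay performance model, and lick times consistent with outcomes
#' (a lick inside the response window iff hit or false alarm).
#'
#' @param spec A [behavior_gen_spec()].
#' @param design List of trial-schedule parameters: `task` (default "DNMS"),
#'   `delays_s` (vector, balanced across 4-trial blocks), `laser_scheme`
#'   ("interleaved", "blocks" or "none"), `perturb_epoch` ("delay", "baseline"
#'   or "none"), `laser_onset_s` / `laser_duration_s` (defaults: whole delay),
#'   `genotypes` (one per subject, recycled; default half ChR2, half control).
#' @param seed Integer seed; identical (spec, design, seed) give identical
#'   tables.
#' @return A [trial_table()] with outcomes filled.
#' @export
simulate_behavior_cohort <- function(spec, design = list(), seed) {
  stopifnot(inherits(spec, "behavior_gen_spec"))
  task <- design$task %||% "DNMS"
  if (!task %in% wm_tasks) stopf("unknown task '%s'", task)
  delays <- design$delays_s %||% if (task == "DPA" || task == "DUAL") 13
           else if (task == "MSDPA") 5 else if (task == "NMS_WOD") 0.1 else 8
  laser_scheme <- design$laser_scheme %||% "none"
  perturb_epoch <- design$perturb_epoch %||%
    (if (laser_scheme == "none") "none" else "delay")
  n_tr <- spec$n_trials_per_subject
  if (n_tr %% 4 != 0)
    stopf("infeasible design: n_trials_per_subject (%d) must be a multiple of 4",
          n_tr)
  if (laser_scheme == "blocks" && n_tr %% 48 != 0)
    stopf("infeasible design: block laser scheme needs a multiple of 48 trials")
  genotypes <- design$genotypes %||%
    rep(c("ChR2", "control"), length.out = spec$n_subjects)
  genotypes <- rep(genotypes, length.out = spec$n_subjects)

  with_seed(seed, {
    rows <- vector("list", spec$n_subjects)
    next_id <- 1L
    for (s in seq_len(spec$n_subjects)) {
      subject <- sprintf("M%02d", s)
      n_blocks <- n_tr / 4L
      combos <- do.call(rbind, lapply(seq_len(n_blocks),
                                      function(b) balanced_block(task)))
      delay <- rep(delays[((seq_len(n_blocks) - 1) %% length(delays)) + 1],
                   each = 4L)
      laser_on <- switch(laser_scheme,
        interleaved = rep(c(FALSE, TRUE), length.out = n_tr),
        blocks = rep(rep(c(FALSE, TRUE), each = 24L), length.out = n_tr),
        none = rep(FALSE, n_tr),
        stopf("unknown laser_scheme '%s'", laser_scheme))
      if (perturb_epoch == "none") laser_on[] <- FALSE
      onset <- rep(NA_real_, n_tr); dur <- rep(NA_real_, n_tr)
      if (perturb_epoch == "delay") {
        dur[laser_on] <- design$laser_duration_s %||% delay[laser_on]
        onset[laser_on] <- design$laser_onset_s %||% 1
      } else if (perturb_epoch == "baseline") {
        dur[laser_on] <- design$laser_duration_s %||% 3
        onset[laser_on] <- design$laser_onset_s %||% (-dur[laser_on])
      }
      distractor <- rep(NA_character_, n_tr)
      if (task == "DUAL") {
        n_cyc <- ceiling(n_tr / 3)
        d <- unlist(lapply(seq_len(n_cyc),
                           function(i) sample(c("none", "go", "nogo"))))
        distractor <- d[seq_len(n_tr)]
      }
      relation <- vapply(seq_len(n_tr), function(i)
        expected_relation(task, combos$sample_odor[i], combos$test_odor[i]),
        character(1))
      tm <- lapply(delay, trial_timing)
      rw0 <- vapply(tm, function(t) t$resp_win[1], numeric(1))
      rw1 <- vapply(tm, function(t) t$resp_win[2], numeric(1))

      # per-trial correct probability under the memory-decay model
      p <- spec$chance_level + spec$amplitude_A * exp(-delay / spec$decay_tau_s)
      suppressed <- laser_on & genotypes[s] == "ChR2" & perturb_epoch == "delay"
      if (any(suppressed)) {
        phase <- pmin(pmax((onset[suppressed] - 1) / delay[suppressed], 0), 1)
        drop <- spec$laser_effect$slope_per_s * dur[suppressed] *
          (1 + spec$laser_effect$phase_gain * phase)
        p[suppressed] <- pmax(p[suppressed] - drop, spec$chance_level)
      }
      if (task == "DUAL")
        p <- pmax(p - unname(spec$distractor_effect[distractor]),
                  spec$chance_level)
      p <- (1 - spec$lapse_rate) * p + spec$lapse_rate * spec$chance_level
      correct <- stats::runif(n_tr) < p
      rewarded <- relation %in% rewarded_relations
      outcome <- ifelse(rewarded,
                        ifelse(correct, "hit", "miss"),
                        ifelse(correct, "correct_rejection", "false_alarm"))
      licked <- outcome %in% c("hit", "false_alarm")
      licks <- lapply(seq_len(n_tr), function(i) {
        lk <- if (licked[i]) rw0[i] + 0.2 else numeric(0)
        if (task == "DUAL" && distractor[i] %in% c("go", "nogo")) {
          inner_ok <- stats::runif(1) < spec$inner_correct_rate
          inner_lick <- (distractor[i] == "go") == inner_ok
          if (inner_lick) lk <- sort(c(lk, tm[[i]]$inner_resp[1] + 0.2))
        }
        lk
      })
      rows[[s]] <- data.frame(
        trial_id = seq.int(next_id, length.out = n_tr),
        task = task, subject_id = subject, genotype = genotypes[s],
        sample_odor = combos$sample_odor, test_odor = combos$test_odor,
        relation = relation, delay_s = delay, distractor = distractor,
        laser_on = laser_on, laser_onset_s = onset, laser_duration_s = dur,
        perturb_epoch = ifelse(laser_on, perturb_epoch, "none"),
        resp_win_start_s = rw0, resp_win_end_s = rw1,
        stringsAsFactors = FALSE)
      rows[[s]]$lick_times_s <- licks
      rows[[s]]$outcome <- outcome
      next_id <- next_id + n_tr
    }
    trial_table(do.call(rbind, rows))
  })
}

# Keep only spikes at least `refractory_s` after the previously kept spike.
enforce_refractory <- function(st, refractory_s) {
  if (length(st) < 2 || refractory_s <= 0) return(st)
  keep <- logical(length(st))
  keep[1] <- TRUE
  last <- st[1]
  for (i in 2:length(st)) {
    if (st[i] - last >= refractory_s) {
      keep[i] <- TRUE
      last <- st[i]
    }
  }
  st[keep]
}

# Piecewise rate profile of one neuron in one trial, evaluated on a regular
# grid of segment left edges (piecewise-constant lambda at resolution dt).
neuron_rate_profile <- function(neuron, trial, t_left, dt) {
  tm <- trial_timing(trial$delay_s)
  t_mid <- t_left + dt / 2
  lam <- rep(neuron$baseline_rate_hz, length(t_left))
  in_sample <- t_mid >= tm$sample[1] & t_mid < tm$sample[2]
  in_test <- t_mid >= tm$test[1] & t_mid < tm$test[2]
  g <- neuron$odor_gain
  if (length(g) > 1) {
    gs <- g[trial$sample_odor]
    if (is.na(gs)) gs <- mean(g)
    lam[in_sample] <- neuron$baseline_rate_hz * unname(gs)
    lam[in_test] <- neuron$baseline_rate_hz * mean(g)
  } else {
    lam[in_sample | in_test] <- neuron$baseline_rate_hz * g
  }
  in_delay <- t_mid >= tm$delay[1] & t_mid < tm$delay[2]
  if (any(in_delay) && neuron$delay_selectivity_hz > 0) {
    sign_ <- if (trial$sample_odor == neuron$preferred_sample) 1 else -1
    atten <- if (!is.na(trial$outcome) &&
                 trial$outcome %in% c("miss", "false_alarm"))
      neuron$error_trial_attenuation else 1
    lam[in_delay] <- lam[in_delay] + sign_ * atten *
      (neuron$delay_selectivity_hz / 2) *
      exp(-(t_mid[in_delay] - tm$delay[1]) / neuron$selectivity_decay_tau_s)
  }
  if (trial$task == "DUAL" && !is.na(trial$distractor) &&
      trial$distractor %in% c("go", "nogo")) {
    g <- neuron$distractor_gain
    if (length(g) > 1) g <- unname(g[trial$distractor])
    if (!is.na(g) && g != 1) {
      # full gain during the cue, exponentially fading over ~0.5 s afterwards
      m <- numeric(length(t_mid))
      in_cue <- t_mid >= tm$inner_cue[1] & t_mid < tm$inner_cue[2]
      after <- t_mid >= tm$inner_cue[2] & t_mid < tm$inner_cue[2] + 2
      m[in_cue] <- 1
      m[after] <- exp(-(t_mid[after] - tm$inner_cue[2]) / 0.5)
      lam <- lam + neuron$baseline_rate_hz * (g - 1) * m
    }
  }
  pmax(lam, 0)
}

#' Simulate spike trains for a session
#'
#' Draws spikes from an inhomogeneous Poisson process with a piecewise rate:
#' baseline everywhere; odor epochs (sample and test) scaled by the odor gain;
#' the delay epoch adds +/- half the delay selectivity (sign set by the
#' preferred sample), decaying exponentially from delay onset; error trials
#' multiply the selectivity by the error-trial attenuation; dual-task
#' distractor epochs add a (possibly cue-specific) distractor response. Rates
#' are clipped at 0. Sampling is exact per piecewise-constant segment
#' (Poisson counts, then uniform spike times within the segment) at a 10 ms
#' resolution, which is fine enough for the exponential selectivity decay;
#' an absolute refractory period then thins the train as in a well-isolated
#' single unit.
#'
#' @param neurons List of [neuron_spec()]s.
#' @param trials A [trial_table()] (outcomes should be filled so that error
#'   trials can attenuate selectivity).
#' @param seed Integer seed; identical inputs and seed give identical output.
#' @param dt_s Piecewise-constant segment length in seconds (default 0.01).
#' @return A [spike_table()] with one row per (unit, trial), including rows
#'   with no spikes.
#' @export
simulate_session <- function(neurons, trials, seed, dt_s = 0.01) {
  if (inherits(neurons, "neuron_spec")) neurons <- list(neurons)
  stopifnot(all(vapply(neurons, inherits, logical(1), "neuron_spec")))
  unit_ids <- vapply(seq_along(neurons), function(i)
    neurons[[i]]$unit_id %||% sprintf("u%03d", i), character(1))
  if (anyDuplicated(unit_ids)) stopf("duplicated unit ids in neuron list")
  with_seed(seed, {
    out <- vector("list", length(neurons) * nrow(trials))
    k <- 1L
    for (n in seq_along(neurons)) {
      for (i in seq_len(nrow(trials))) {
        trial <- trials[i, ]
        t_end <- trial$resp_win_end_s
        n_seg <- floor((t_end - (-1)) / dt_s)
        if (n_seg < 1) {
          st <- numeric(0)
        } else {
          t_left <- -1 + (seq_len(n_seg) - 1) * dt_s
          lam <- neuron_rate_profile(neurons[[n]], trial, t_left, dt_s)
          counts <- stats::rpois(n_seg, lam * dt_s)
          tot <- sum(counts)
          st <- if (tot == 0) numeric(0) else
            sort(rep(t_left, counts) + stats::runif(tot) * dt_s)
          st <- enforce_refractory(st, neurons[[n]]$refractory_s)
        }
        out[[k]] <- list(unit_id = unit_ids[n], trial_id = trial$trial_id,
                         spike_times_s = st)
        k <- k + 1L
      }
    }
    spike_table(data.frame(
      unit_id = vapply(out, `[[`, character(1), "unit_id"),
      trial_id = vapply(out, `[[`, integer(1), "trial_id"),
      spike_times_s = I(lapply(out, `[[`, "spike_times_s")),
      stringsAsFactors = FALSE), trials)
  })
}
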
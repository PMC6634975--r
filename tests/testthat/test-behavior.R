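test_that("outcomes follow the lick-in-window rule with half-open boundaries", {
  tm <- trial_timing_fixture(4)  # window [7, 7.5)
  trials <- fixture_trials(4, lick = list(
    c(tm$resp0 + 0.2),     # nonmatch? row1 is S1-T1 match -> false alarm
    numeric(0),            # S1-T2 nonmatch, no lick -> miss
    c(tm$resp0 + 0.1),     # S2-T1 nonmatch, lick -> hit
    c(tm$resp0 - 0.001)))  # S2-T2 match, lick 1 ms before window -> no lick
  out <- classify_outcomes(trials)
  expect_equal(out$outcome,
               c("false_alarm", "miss", "hit", "correct_rejection"))
  # idempotent
  expect_identical(classify_outcomes(out)$outcome, out$outcome)
  # pure row-wise function: permuting rows permutes outcomes identically
  perm <- c(3, 1, 4, 2)
  out_perm <- classify_outcomes(trials[perm, ])
  expect_identical(out_perm$outcome, out$outcome[perm])
})

test_that("performance summaries satisfy the rate identities and d-prime oracle", {
  spec <- behavior_gen_spec(n_subjects = 3, n_trials_per_subject = 100)
  tr <- simulate_behavior_cohort(spec, list(task = "DNMS", delays_s = 8),
                                 seed = 2)
  s <- summarize_performance(tr, "subject_id")
  expect_equal(s$n_hit + s$n_miss + s$n_false_alarm + s$n_correct_rejection,
               s$n_trials)
  expect_equal(s$hit_rate + s$miss_rate, rep(1, nrow(s)))
  expect_equal(s$false_alarm_rate + s$correct_rejection_rate, rep(1, nrow(s)))
  expect_equal(s$correct_rate, (s$n_hit + s$n_correct_rejection) / s$n_trials)
  # d' oracle: hit 0.84, FA 0.16 (84/100 vs 16/100)
  expect_lt(abs(d_prime(84, 100, 16, 100) -
                  (qnorm(0.84) - qnorm(0.16))), 1e-12)
  expect_lt(abs(d_prime(84, 100, 16, 100) - 1.9890), 1e-3)
  # symmetry and antisymmetry
  expect_equal(d_prime(30, 100, 30, 100), 0)
  expect_equal(d_prime(84, 100, 16, 100), -d_prime(16, 100, 84, 100))
  # clamping keeps extreme rates finite
  expect_true(is.finite(d_prime(100, 100, 0, 100)))
  expect_true(is.na(d_prime(0, 0, 5, 10)))
})

test_that("lick efficiency counts rewarded over all response-window licks", {
  # 30 rewarded window licks (3 hits x 10) + 10 unrewarded (1 FA x 10) -> 0.75
  tm <- trial_timing_fixture(4)
  win_licks <- function(k) tm$resp0 + seq(0.01, 0.4, length.out = k)
  trials <- fixture_trials(4, lick = list(
    win_licks(10),   # S1-T1 match + licks -> false alarm (10 unrewarded)
    numeric(0), numeric(0), numeric(0)))
  trials$lick_times_s <- list(win_licks(10), win_licks(10), win_licks(10),
                              numeric(0))
  # rows: match(FA), nonmatch(hit), nonmatch(hit), match(CR)
  out <- classify_outcomes(trials)
  s <- summarize_performance(out)
  expect_equal(s$lick_efficiency, 20 / 30)
  # all-hit case
  trials2 <- fixture_trials(4, lick = list(
    numeric(0), win_licks(15), win_licks(15), numeric(0)))
  s2 <- summarize_performance(classify_outcomes(trials2))
  expect_equal(s2$lick_efficiency, 1)
})

test_that("well-trained windows use inclusive thresholds on unperturbed trials", {
  mk <- function(correct, laser = rep(FALSE, length(correct))) {
    tr <- fixture_trials(length(correct))
    tr$laser_on <- laser
    tr$laser_onset_s <- ifelse(laser, 1, NA_real_)
    tr$laser_duration_s <- ifelse(laser, 4, NA_real_)
    tr$perturb_epoch <- ifelse(laser, "delay", "none")
    rewarded <- tr$relation %in% c("nonmatch")
    tr$outcome <- ifelse(rewarded,
                         ifelse(correct, "hit", "miss"),
                         ifelse(correct, "correct_rejection", "false_alarm"))
    tr
  }
  # 40 consecutive correct -> all flagged
  expect_true(all(find_well_trained_windows(mk(rep(TRUE, 40)), "w40")))
  # 31 of 40 (77.5%) -> none flagged
  expect_false(any(find_well_trained_windows(
    mk(c(rep(TRUE, 31), rep(FALSE, 9))), "w40")))
  # exactly 32 of 40 (80%): inclusive threshold -> flagged
  expect_true(all(find_well_trained_windows(
    mk(rep(c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE), 4)),
    "w40")))
  # interleaved laser-on trials inside a qualifying laser-off span are flagged
  correct <- rep(TRUE, 80)
  laser <- rep(c(FALSE, TRUE), 40)
  mask <- find_well_trained_windows(mk(correct, laser), "w40")
  expect_true(all(mask[laser][1:39]))
  # too few unperturbed trials -> all-false with a warning
  expect_warning(m <- find_well_trained_windows(mk(rep(TRUE, 10)), "w40"),
                 "fewer than 40")
  expect_false(any(m))
  # block criterion: 6-of-8 unperturbed correct flags the 32-trial block
  correct_b <- rep(FALSE, 64)
  laser_b <- rep(rep(c(FALSE, TRUE), c(1, 3)), 16)   # 8 unperturbed per block
  correct_b[which(!laser_b)[1:8][1:6]] <- TRUE       # 6 correct in block 1
  mask_b <- find_well_trained_windows(mk(correct_b, laser_b), "b32")
  expect_true(all(mask_b[1:32]))
  expect_false(any(mask_b[33:64]))
})

test_that("memory-decay fit recovers noiseless parameters and flags degeneracy", {
  d <- c(2, 5, 8, 12, 20, 40)
  y <- 0.5 + 0.45 * exp(-d / 20)
  fit <- fit_memory_decay(d, y)
  expect_lt(abs(fit$asymptote - 0.5), 1e-6)
  expect_lt(abs(fit$amplitude_A - 0.45), 1e-6)
  expect_lt(abs(fit$tau_s - 20), 1e-4)
  expect_lt(fit$residual_sse, 1e-12)
  expect_false(fit$unidentifiable)
  # free-asymptote mode recovers the same noiseless parameters
  fit_f <- fit_memory_decay(d, y, asymptote = "free")
  expect_lt(abs(fit_f$asymptote - 0.5), 1e-6)
  expect_lt(abs(fit_f$tau_s - 20), 1e-3)
  # constant correct rate: amplitude ~ 0, tau flagged unidentifiable
  flat <- fit_memory_decay(d, rep(0.5, 6))
  expect_true(flat$unidentifiable)
  expect_lt(flat$amplitude_A, 0.01)
  expect_equal(flat$asymptote, 0.5)
  flat_f <- fit_memory_decay(d, rep(0.52, 6), asymptote = "free")
  expect_true(flat_f$unidentifiable)
  expect_equal(flat_f$asymptote, 0.52)
  expect_error(fit_memory_decay(c(5, 5, 10), c(0.9, 0.9, 0.8)),
               "3 distinct delays")
})

test_that("dual-task interference splits by distractor and tests across subjects", {
  spec <- behavior_gen_spec(n_subjects = 8, n_trials_per_subject = 120,
                            distractor_effect = c(none = 0, nogo = 0.05,
                                                  go = 0.15))
  tr <- simulate_behavior_cohort(spec, list(task = "DUAL"), seed = 9)
  res <- dual_task_interference(tr)
  expect_setequal(unique(res$summary$distractor), c("none", "nogo", "go"))
  expect_equal(nrow(res$summary), 24)
  # generated ordering: go worst, none best
  expect_lt(res$condition_means["go"], res$condition_means["none"])
  expect_false(is.null(res$anova))
  expect_true(res$anova$p_value > 0 && res$anova$p_value <= 1)
  # single subject: summaries only, no omnibus statistic
  one <- tr[tr$subject_id == "M01", ]
  res1 <- dual_task_interference(one)
  expect_null(res1$anova)
  expect_error(dual_task_interference(fixture_trials(4)), "task DUAL")
})

test_that("an injected go-distractor deficit is detected with adequate power", {
  hits <- 0
  n_sim <- 15
  for (s in seq_len(n_sim)) {
    spec <- behavior_gen_spec(n_subjects = 10, n_trials_per_subject = 96,
                              distractor_effect = c(none = 0, nogo = 0,
                                                    go = 0.15))
    tr <- simulate_behavior_cohort(spec, list(task = "DUAL"), seed = 4000 + s)
    res <- dual_task_interference(tr)
    if (res$anova$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits / n_sim, 0.8)
})
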
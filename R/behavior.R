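#' Classify trial outcomes from licking
#'
#' A lick inside the half-open response window `[start, end)` on a
#' rewarded-type trial (nonmatch / paired / go) is a hit; on an
#' unrewarded-type trial (match / unpaired / nogo) it is a false alarm. The
#' no-lick counterparts are miss and correct rejection. The function is a pure
#' function of (lick times, response window, relation) and is idempotent.
#'
#' @param trials A [trial_table()].
#' @return The same table with the `outcome` column filled.
#' @export
classify_outcomes <- function(trials) {
  if (any(is.na(trials$relation))) stopf("relation must be present for every trial")
  licked <- vapply(seq_len(nrow(trials)), function(i) {
    lk <- trials$lick_times_s[[i]]
    any(lk >= trials$resp_win_start_s[i] & lk < trials$resp_win_end_s[i])
  }, logical(1))
  rewarded <- trials$relation %in% rewarded_relations
  trials$outcome <- ifelse(rewarded,
                           ifelse(licked, "hit", "miss"),
                           ifelse(licked, "false_alarm", "correct_rejection"))
  trials
}

outcome_correct <- function(outcome) outcome %in% c("hit", "correct_rejection")

# Rates of 0 or 1 are replaced by 1/(2n) and 1 - 1/(2n) before the inverse
# normal transform, keeping d' finite.
clamp_rate <- function(k, n) {
  r <- k / n
  if (r == 0) 1 / (2 * n) else if (r == 1) 1 - 1 / (2 * n) else r
}

#' Sensitivity index d-prime
#'
#' `d' = qnorm(hit rate) - qnorm(false-alarm rate)`, with extreme rates
#' clamped to `1/(2n)` / `1 - 1/(2n)` of the relevant trial count.
#'
#' @param n_hit,n_go Hit count and number of rewarded-type (go-type) trials.
#' @param n_fa,n_nogo False-alarm count and number of unrewarded-type trials.
#' @return d' (dimensionless), or `NA` if either trial count is zero.
#' @export
d_prime <- function(n_hit, n_go, n_fa, n_nogo) {
  if (n_go == 0 || n_nogo == 0) return(NA_real_)
  stats::qnorm(clamp_rate(n_hit, n_go)) - stats::qnorm(clamp_rate(n_fa, n_nogo))
}

#' Summarize behavioral performance
#'
#' Per group: trial and outcome counts, correct rate (hits + correct
#' rejections over all trials), hit / miss rates over go-type trials,
#' false-alarm / correct-rejection rates over nogo-type trials, d' with
#' clamped rates, and lick efficiency (rewarded window licks over all window
#' licks; hits produce rewarded licks, false alarms unrewarded ones).
#'
#' @param trials A [trial_table()] with outcomes filled.
#' @param group_by Character vector of grouping columns (e.g.
#'   `c("subject_id", "genotype", "laser_on", "delay_s")`).
#' @return A data.frame with one row per group.
#' @export
summarize_performance <- function(trials, group_by = character(0)) {
  if (any(is.na(trials$outcome))) stopf("outcomes must be filled; run classify_outcomes()")
  if (!all(group_by %in% names(trials)))
    stopf("unknown grouping column(s): %s",
          paste(setdiff(group_by, names(trials)), collapse = ", "))
  key <- if (length(group_by) == 0) rep("all", nrow(trials))
         else do.call(paste, c(lapply(group_by, function(g) trials[[g]]), sep = "\r"))
  idx <- split(seq_len(nrow(trials)), key)
  res <- lapply(idx, function(ii) {
    tt <- trials[ii, , drop = FALSE]
    n <- nrow(tt)
    n_hit <- sum(tt$outcome == "hit")
    n_miss <- sum(tt$outcome == "miss")
    n_fa <- sum(tt$outcome == "false_alarm")
    n_cr <- sum(tt$outcome == "correct_rejection")
    n_go <- n_hit + n_miss
    n_nogo <- n_fa + n_cr
    window_licks <- vapply(seq_len(n), function(i)
      sum(tt$lick_times_s[[i]] >= tt$resp_win_start_s[i] &
            tt$lick_times_s[[i]] < tt$resp_win_end_s[i]), numeric(1))
    rewarded_licks <- sum(window_licks[tt$outcome == "hit"])
    unrewarded_licks <- sum(window_licks[tt$outcome == "false_alarm"])
    out <- data.frame(
      n_trials = n,
      n_hit = n_hit, n_miss = n_miss,
      n_false_alarm = n_fa, n_correct_rejection = n_cr,
      correct_rate = (n_hit + n_cr) / n,
      hit_rate = if (n_go > 0) n_hit / n_go else NA_real_,
      miss_rate = if (n_go > 0) n_miss / n_go else NA_real_,
      false_alarm_rate = if (n_nogo > 0) n_fa / n_nogo else NA_real_,
      correct_rejection_rate = if (n_nogo > 0) n_cr / n_nogo else NA_real_,
      d_prime = d_prime(n_hit, n_go, n_fa, n_nogo),
      lick_efficiency = if (rewarded_licks + unrewarded_licks > 0)
        rewarded_licks / (rewarded_licks + unrewarded_licks) else NA_real_,
      stringsAsFactors = FALSE)
    for (g in rev(group_by)) out <- cbind(stats::setNames(
      data.frame(tt[[g]][1], stringsAsFactors = FALSE), g), out)
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag trials inside well-trained performance windows
#'
#' Criteria are evaluated over unperturbed (laser-off) trials only:
#' * `"w40"`: at least 80% correct within 40 consecutive unperturbed trials;
#' * `"w20"`: the same with 20 consecutive unperturbed trials;
#' * `"b32"`: at least 6 correct among the unperturbed trials of each 32-trial
#'   block (designed for schedules with 8 unperturbed trials per block).
#'
#' Thresholds are inclusive ("no less than"). Membership is mapped back to
#' every trial - including interleaved laser-on trials - whose index lies in
#' the span of a qualifying window or block.
#'
#' @param trials A [trial_table()] with outcomes filled, in session order.
#' @param criterion One of `"w40"`, `"w20"`, `"b32"`.
#' @return Logical mask over the rows of `trials`.
#' @export
find_well_trained_windows <- function(trials, criterion = c("w40", "w20", "b32")) {
  criterion <- match.arg(criterion)
  if (any(is.na(trials$outcome))) stopf("outcomes must be filled")
  mask <- rep(FALSE, nrow(trials))
  for (sid in unique(trials$subject_id)) {
    ii <- which(trials$subject_id == sid)
    correct <- outcome_correct(trials$outcome[ii])
    unpert <- !trials$laser_on[ii]
    if (criterion %in% c("w40", "w20")) {
      n_win <- if (criterion == "w40") 40L else 20L
      up_idx <- which(unpert)
      if (length(up_idx) < n_win) {
        warnf("subject %s has fewer than %d unperturbed trials; none flagged",
              sid, n_win)
        next
      }
      cs <- cumsum(c(0, correct[up_idx]))
      for (s in seq_len(length(up_idx) - n_win + 1)) {
        if ((cs[s + n_win] - cs[s]) / n_win >= 0.8) {
          lo <- up_idx[s]; hi <- up_idx[s + n_win - 1]
          mask[ii[lo:hi]] <- TRUE
        }
      }
    } else {
      n_blocks <- ceiling(length(ii) / 32L)
      for (b in seq_len(n_blocks)) {
        lo <- (b - 1L) * 32L + 1L
        hi <- min(b * 32L, length(ii))
        blk <- lo:hi
        if (sum(correct[blk][unpert[blk]]) >= 6) mask[ii[blk]] <- TRUE
      }
    }
  }
  mask
}

#' Fit an exponential memory-decay curve to correct rates
#'
#' Least-squares fit of `C(d) = asymptote + A * exp(-d / tau)` to per-delay
#' correct rates. By default the asymptote is anchored at the task's chance
#' level (0.5 for two alternatives): the tau-asymptote trade-off otherwise
#' inflates the variance of the decay constant roughly threefold (the
#' Cramer-Rao bound for a free asymptote at five delay points puts the
#' relative error of tau near 80% of its value at 100 trials/delay), while a
#' two-alternative task must decay to chance by construction.
#' `asymptote = "free"` fits it as a free parameter bounded to [0.45, 0.6]
#' and initialized at 0.5; the convention used is recorded in the result.
#'
#' @param delays_s Delay durations (>= 3 distinct values).
#' @param correct_rates Correct rates, same length.
#' @param weights Optional least-squares weights (e.g. trial counts).
#' @param asymptote `"chance"` (default) or `"free"`.
#' @param chance_level Anchor for the chance convention (default 0.5).
#' @return A `memory_decay_fit` list: `amplitude_A`, `tau_s`, `asymptote`,
#'   `residual_sse`, `fitted`, `unidentifiable` (TRUE when A is essentially 0,
#'   in which case tau is meaningless), and `asymptote_convention` metadata.
#' @export
fit_memory_decay <- function(delays_s, correct_rates, weights = NULL,
                             asymptote = c("chance", "free"),
                             chance_level = 0.5) {
  asymptote <- match.arg(asymptote)
  stopifnot(length(delays_s) == length(correct_rates))
  if (length(unique(delays_s)) < 3)
    stopf("need at least 3 distinct delays to fit the decay model")
  df <- data.frame(d = delays_s, y = correct_rates)
  w <- weights %||% rep(1, nrow(df))
  a0 <- max(min(max(correct_rates) - chance_level, 0.55), 0.01)
  convention <- if (asymptote == "chance")
    sprintf("anchored at chance (%.2f)", chance_level)
  else "free, bounded to [0.45, 0.6]"
  fit <- tryCatch({
    if (asymptote == "chance") {
      df$chance <- chance_level
      minpack.lm::nlsLM(y ~ chance + A * exp(-d / tau), data = df,
                        start = list(A = a0, tau = stats::median(delays_s)),
                        weights = w, lower = c(A = 0, tau = 1e-3),
                        upper = c(A = 1 - chance_level, tau = 1e4),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(y ~ asym + A * exp(-d / tau), data = df,
                        start = list(asym = 0.5, A = a0,
                                     tau = stats::median(delays_s)),
                        weights = w,
                        lower = c(asym = 0.45, A = 0, tau = 1e-3),
                        upper = c(asym = 0.6, A = 0.55, tau = 1e4),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) e)
  if (inherits(fit, "error")) {
    # a flat curve leaves tau unidentifiable: report the amplitude-free fit
    if (stats::sd(correct_rates) < 1e-2) {
      asym <- if (asymptote == "chance") chance_level
              else min(max(sum(w * correct_rates) / sum(w), 0.45), 0.6)
      return(structure(list(
        amplitude_A = 0, tau_s = NA_real_, asymptote = asym,
        residual_sse = sum(w * (correct_rates - asym)^2),
        fitted = rep(asym, length(correct_rates)), unidentifiable = TRUE,
        asymptote_convention = convention),
        class = "memory_decay_fit"))
    }
    stopf("memory-decay fit failed to converge: %s", conditionMessage(fit))
  }
  cf <- stats::coef(fit)
  asym_hat <- if (asymptote == "chance") chance_level else unname(cf["asym"])
  structure(list(amplitude_A = unname(cf["A"]), tau_s = unname(cf["tau"]),
                 asymptote = asym_hat,
                 residual_sse = sum(w * stats::residuals(fit)^2),
                 fitted = stats::fitted(fit),
                 unidentifiable = unname(cf["A"]) < 0.01,
                 asymptote_convention = convention),
            class = "memory_decay_fit")
}

#' @export
print.memory_decay_fit <- function(x, ...) {
  cat(sprintf("<memory_decay_fit> asymptote %.3f + %.3f * exp(-delay / %.2f s); SSE %.3g%s\n",
              x$asymptote, x$amplitude_A, x$tau_s, x$residual_sse,
              if (x$unidentifiable) " [amplitude ~ 0: tau unidentifiable]" else ""))
  invisible(x)
}

#' Dual-task interference on the outer task
#'
#' Splits the outer-task (DPA) correct rate of dual-task trials by distractor
#' condition (none / nogo / go) per subject and runs a one-way
#' repeated-measures ANOVA across conditions with subject as the repeated
#' factor.
#'
#' @param trials A dual-task [trial_table()] with outcomes filled.
#' @return List with `summary` (subject x condition correct rates),
#'   `condition_means`, and `anova` (`statistic`, `df`, `p_value`; `NULL` when
#'   fewer than 2 subjects or conditions are available).
#' @export
dual_task_interference <- function(trials) {
  if (!all(trials$task == "DUAL")) stopf("dual_task_interference expects task DUAL")
  if (any(is.na(trials$distractor))) stopf("distractor field must be present")
  if (any(is.na(trials$outcome))) stopf("outcomes must be filled")
  correct <- outcome_correct(trials$outcome)
  tab <- stats::aggregate(correct,
                          by = list(subject_id = trials$subject_id,
                                    distractor = trials$distractor),
                          FUN = mean)
  names(tab)[3] <- "correct_rate"
  cond_means <- tapply(tab$correct_rate, tab$distractor, mean)
  n_subj <- length(unique(tab$subject_id))
  n_cond <- length(unique(tab$distractor))
  anova_res <- NULL
  if (n_subj >= 2 && n_cond >= 2) {
    tab$subject_id <- factor(tab$subject_id)
    tab$distractor <- factor(tab$distractor)
    fit <- stats::aov(correct_rate ~ distractor + Error(subject_id),
                      data = tab)
    sm <- summary(fit)
    within <- sm[["Error: Within"]][[1]]
    row <- grep("^distractor", trimws(rownames(within)))
    anova_res <- list(statistic = within[row, "F value"],
                      df = c(within[row, "Df"],
                             within[nrow(within), "Df"]),
                      p_value = within[row, "Pr(>F)"],
                      method = "one-way repeated-measures ANOVA")
  }
  list(summary = tab, condition_means = cond_means, anova = anova_res)
}
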
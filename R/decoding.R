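#' Decoder configuration
#'
#' Defaults follow the canonical analysis: RBF-kernel SVM, cost grid
#' `2^(-5..5)`, gamma grid `2^(-10..0)`, 500 repeats of resampled
#' leave-one-trial-out cross-validation with 30 bootstrap pseudotrials per
#' class, strict inclusion of units with more than 30 trials per class, and a
#' 1000-permutation shuffle null run at a reduced 200 repeats per permutation
#' (recorded in the result). Reduced grids/repeats may be configured for
#' exploratory runs.
#'
#' @param c_grid,gamma_grid RBF hyperparameter grids.
#' @param n_repeats Cross-validation repeats.
#' @param n_train_boot Bootstrap pseudotrials per class per repeat.
#' @param min_trials_per_class Inclusion threshold (strictly more than this
#'   many trials per class required).
#' @param n_shuffles Label permutations for the null (0 disables).
#' @param shuffle_repeats Repeats per permutation (reduced relative to
#'   `n_repeats` for tractability).
#' @param mask_alpha Significance threshold against the shuffle null.
#' @param seed Master seed; per-bin and per-repeat streams are derived
#'   deterministically so cross-temporal diagonals reproduce the time course.
#' @export
decoder_config <- function(c_grid = 2^(-5:5), gamma_grid = 2^(-10:0),
                           n_repeats = 500, n_train_boot = 30,
                           min_trials_per_class = 30, n_shuffles = 1000,
                           shuffle_repeats = 200, mask_alpha = 0.001,
                           seed = 1L) {
  stopifnot(length(c_grid) > 0, length(gamma_grid) > 0, n_repeats >= 1,
            n_train_boot >= 1, min_trials_per_class >= 0)
  structure(list(c_grid = sort(c_grid), gamma_grid = sort(gamma_grid),
                 n_repeats = n_repeats, n_train_boot = n_train_boot,
                 min_trials_per_class = min_trials_per_class,
                 n_shuffles = n_shuffles, shuffle_repeats = shuffle_repeats,
                 mask_alpha = mask_alpha, seed = seed),
            class = "decoder_config")
}

#' Select units for population decoding
#'
#' Includes units with strictly more than `min_trials_per_class` available
#' trials for every class, counting only trials in `trial_mask` (canonically
#' the correct, well-trained trials).
#'
#' @param spikes A [spike_table()].
#' @param trials The companion [trial_table()].
#' @param labels Class label per row of `trials`.
#' @param config A [decoder_config()].
#' @param trial_mask Optional logical mask over trials (default all).
#' @return Character vector of included unit ids; errors if empty.
#' @export
select_units <- function(spikes, trials, labels, config = decoder_config(),
                         trial_mask = NULL) {
  trial_mask <- trial_mask %||% rep(TRUE, nrow(trials))
  lev <- sort(unique(labels[trial_mask]))
  unit_ids <- sort(unique(spikes$unit_id))
  kept <- vapply(unit_ids, function(uid) {
    covered <- trials$trial_id %in% spikes$trial_id[spikes$unit_id == uid]
    counts <- table(factor(labels[trial_mask & covered], lev))
    all(counts > config$min_trials_per_class)
  }, logical(1))
  if (!any(kept))
    stopf("no unit has more than %d trials for every class",
          config$min_trials_per_class)
  unit_ids[kept]
}

#' Min-max normalize rates to [0, 1]
#'
#' Per unit, rates are scaled by the min and max over all trials and bins;
#' constant units map to 0 (with a warning).
#'
#' @param binned A `binned_rates`.
#' @export
normalize_rates <- function(binned) {
  stopifnot(inherits(binned, "binned_rates"))
  lo <- apply(binned$rates, 1, min)
  hi <- apply(binned$rates, 1, max)
  rng <- hi - lo
  flat <- rng == 0
  if (any(flat)) {
    warnf("constant rate for unit(s) %s; mapped to 0",
          paste(binned$unit_ids[flat], collapse = ", "))
    rng[flat] <- 1
  }
  out <- binned
  out$rates <- sweep(sweep(binned$rates, 1, lo, "-"), 1, rng, "/")
  out$normalized <- TRUE
  out$norm_method <- "minmax01"
  out
}

# Inner 5-fold grid search over a pseudotrial training set; ties broken by
# smallest cost, then smallest gamma.
grid_search_rbf <- function(train_x, train_y, c_grid, gamma_grid) {
  n <- nrow(train_x)
  folds <- rep_len(seq_len(5), n)
  best <- c(acc = -1, cost = NA, gamma = NA)
  for (cost in c_grid) for (gam in gamma_grid) {
    correct <- 0
    for (f in seq_len(5)) {
      tr <- folds != f
      fit <- e1071::svm(train_x[tr, , drop = FALSE], train_y[tr],
                        kernel = "radial", cost = cost, gamma = gam,
                        scale = FALSE)
      correct <- correct + sum(stats::predict(fit, train_x[!tr, , drop = FALSE]) ==
                                 train_y[!tr])
    }
    acc <- correct / n
    if (acc > best["acc"] + 1e-12) best <- c(acc = acc, cost = cost, gamma = gam)
  }
  best
}

# Core engine for one training bin. Draws, per repeat, one held-out test
# trial per class and per-neuron bootstrap pseudotrial indices from the
# remaining trials; those index draws are independent of the bin, so training
# at `train_bin` and testing at any `test_bins` share the identical partition
# stream - the basis for CTD diagonal reproducibility. Grid search and the
# repeat loop consume independent derived seeds, so supplying `params`
# (skipping the search) leaves the partitions unchanged.
decode_train_bin <- function(rates, class_trials, train_bin, test_bins,
                             config, seed, params = NULL,
                             n_repeats = config$n_repeats) {
  n_units <- dim(rates)[1]
  k <- length(class_trials)
  y_train <- factor(rep(seq_len(k), each = config$n_train_boot))
  y_test <- factor(seq_len(k), levels = levels(y_train))
  if (is.null(params)) {
    params <- with_seed(derive_seed(seed, 1), {
      train_idx <- lapply(class_trials, function(pool)
        matrix(sample(pool, config$n_train_boot * n_units, replace = TRUE),
               nrow = config$n_train_boot))
      tx <- do.call(rbind, lapply(train_idx, function(idx)
        t(vapply(seq_len(nrow(idx)), function(r)
          rates[cbind(seq_len(n_units), idx[r, ], train_bin)], numeric(n_units)))))
      g <- grid_search_rbf(tx, y_train, config$c_grid, config$gamma_grid)
      c(cost = unname(g["cost"]), gamma = unname(g["gamma"]))
    })
  }
  acc <- matrix(NA_real_, n_repeats, length(test_bins))
  with_seed(derive_seed(seed, 2), {
    for (r in seq_len(n_repeats)) {
      test_trial <- vapply(class_trials, function(pool)
        pool[sample.int(length(pool), 1)], numeric(1))
      train_x <- matrix(NA_real_, k * config$n_train_boot, n_units)
      row0 <- 0
      boot_idx <- vector("list", k)
      for (cl in seq_len(k)) {
        pool <- setdiff(class_trials[[cl]], test_trial[cl])
        idx <- matrix(sample(pool, config$n_train_boot * n_units,
                             replace = TRUE), nrow = config$n_train_boot)
        boot_idx[[cl]] <- idx
        for (rr in seq_len(config$n_train_boot))
          train_x[row0 + rr, ] <- rates[cbind(seq_len(n_units), idx[rr, ],
                                              train_bin)]
        row0 <- row0 + config$n_train_boot
      }
      # leakage guard: held-out trials never contribute training samples
      stopifnot(!any(test_trial %in% unlist(boot_idx)))
      fit <- e1071::svm(train_x, y_train, kernel = "radial",
                        cost = params["cost"], gamma = params["gamma"],
                        scale = FALSE)
      for (j in seq_along(test_bins)) {
        test_x <- t(vapply(seq_len(k), function(cl)
          rates[, test_trial[cl], test_bins[j]], numeric(n_units)))
        acc[r, j] <- mean(stats::predict(fit, test_x) == y_test)
      }
    }
  })
  list(acc = acc, params = params)
}

decode_inputs <- function(binned, labels) {
  labels <- as.character(labels)
  stopifnot(length(labels) == length(binned$trial_ids))
  lev <- sort(unique(labels))
  class_trials <- lapply(lev, function(l) which(labels == l))
  if (any(lengths(class_trials) < 2))
    stopf("each class needs more trials than the test-set size")
  list(lev = lev, class_trials = class_trials)
}

#' Time-resolved population decoding accuracy
#'
#' Per time bin: resampled leave-one-trial-out cross-validation with an RBF
#' SVM trained on bootstrap pseudotrial vectors (per neuron, one same-class
#' trial sampled with replacement), hyperparameters selected once per bin by
#' an inner 5-fold grid search, accuracy averaged over repeats, a bootstrap
#' 95% band over repeats, and (optionally) a label-shuffle null run at the
#' observed hyperparameters with reduced repeats, giving per-bin significance
#' at `mask_alpha`.
#'
#' @param binned A normalized `binned_rates` (see [normalize_rates()]).
#' @param labels Class label per trial.
#' @param config A [decoder_config()].
#' @return A `decoding_result`: `accuracy` per bin, `band` (2 x bins),
#'   `acc_repeats` (repeats x bins), `params` (per-bin cost/gamma),
#'   `null_acc` (shuffles x bins or NULL), `p_values`, `mask`, `chance`,
#'   `bin_starts`, `config`.
#' @export
decode_timecourse <- function(binned, labels, config = decoder_config()) {
  inp <- decode_inputs(binned, labels)
  n_bins <- dim(binned$rates)[3]
  acc_repeats <- matrix(NA_real_, config$n_repeats, n_bins)
  params <- matrix(NA_real_, n_bins, 2, dimnames = list(NULL, c("cost", "gamma")))
  for (b in seq_len(n_bins)) {
    res <- decode_train_bin(binned$rates, inp$class_trials, b, b, config,
                            seed = derive_seed(config$seed, b))
    acc_repeats[, b] <- res$acc[, 1]
    params[b, ] <- res$params
  }
  accuracy <- colMeans(acc_repeats)
  band <- vapply(seq_len(n_bins), function(b)
    bootstrap_ci_mean(acc_repeats[, b], n_rep = 1000,
                      seed = derive_seed(config$seed, b, 3)),
    numeric(2))
  null_acc <- NULL; p_values <- NULL; mask <- NULL
  if (config$n_shuffles > 0) {
    null_acc <- matrix(NA_real_, config$n_shuffles, n_bins)
    n_trials <- length(binned$trial_ids)
    for (sh in seq_len(config$n_shuffles)) {
      perm <- with_seed(derive_seed(config$seed, 1000000, sh),
                        sample.int(n_trials))
      sh_classes <- lapply(inp$class_trials, function(g) perm[g])
      for (b in seq_len(n_bins)) {
        res <- decode_train_bin(binned$rates, sh_classes, b, b, config,
                                seed = derive_seed(config$seed, b, 200000 + sh),
                                params = params[b, ],
                                n_repeats = config$shuffle_repeats)
        null_acc[sh, b] <- mean(res$acc[, 1])
      }
    }
    p_values <- vapply(seq_len(n_bins), function(b)
      (sum(null_acc[, b] >= accuracy[b] - 1e-12) + 1) / (config$n_shuffles + 1),
      numeric(1))
    mask <- p_values < config$mask_alpha
  }
  structure(list(accuracy = accuracy, band = band, acc_repeats = acc_repeats,
                 params = as.data.frame(params), null_acc = null_acc,
                 p_values = p_values, mask = mask,
                 chance = 1 / length(inp$lev), classes = inp$lev,
                 bin_starts = binned$bin_starts, config = config),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %d bins, %d classes (chance %.2f); accuracy %.3f-%.3f\n",
              length(x$accuracy), length(x$classes), x$chance,
              min(x$accuracy), max(x$accuracy)))
  invisible(x)
}

#' Cross-temporal decoding matrix
#'
#' Trains the decoder on activity from each time bin and tests it on every
#' time bin, keeping the hyperparameters obtained for the training bin and
#' excluding the held-out test trials from training at every (train, test)
#' pair. With the same configuration seed, the diagonal reproduces
#' [decode_timecourse()] exactly.
#'
#' @param binned A normalized `binned_rates`.
#' @param labels Class label per trial.
#' @param config A [decoder_config()].
#' @param result Optional `decoding_result` supplying per-bin hyperparameters
#'   (otherwise re-derived identically from the seed).
#' @return A `ctd_result`: `ctd` (train-bin x test-bin accuracy), `params`,
#'   `bin_starts`, `config`.
#' @export
cross_temporal_decoding <- function(binned, labels, config = decoder_config(),
                                    result = NULL) {
  inp <- decode_inputs(binned, labels)
  n_bins <- dim(binned$rates)[3]
  ctd <- matrix(NA_real_, n_bins, n_bins)
  params <- matrix(NA_real_, n_bins, 2, dimnames = list(NULL, c("cost", "gamma")))
  for (i in seq_len(n_bins)) {
    p <- if (!is.null(result)) unlist(result$params[i, ]) else NULL
    res <- decode_train_bin(binned$rates, inp$class_trials, i, seq_len(n_bins),
                            config, seed = derive_seed(config$seed, i),
                            params = p)
    ctd[i, ] <- colMeans(res$acc)
    params[i, ] <- res$params
  }
  structure(list(ctd = ctd, params = as.data.frame(params),
                 chance = 1 / length(inp$lev),
                 bin_starts = binned$bin_starts, config = config),
            class = "ctd_result")
}

#' Correlation between decoding accuracy and behavioral performance
#'
#' Across conditions (e.g. distractor none / No-go / Go), correlates mean
#' decoding accuracy with mean correct rate; per bootstrap resample both sides
#' are resampled (repeat-level accuracies, subject-level correct rates) and
#' the Pearson statistic recomputed.
#'
#' @param accuracy_samples Named list, one numeric vector of per-repeat
#'   decoding accuracies per condition.
#' @param performance_samples Named list, one numeric vector of per-subject
#'   correct rates per condition (same condition order).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Optional integer seed.
#' @param level CI coverage (default 0.95).
#' @return List: `r`, `r_squared`, `ci`, `boot_r`, `condition_means`.
#' @export
decode_behavior_correlation <- function(accuracy_samples, performance_samples,
                                        n_boot = 1000, seed = NULL,
                                        level = 0.95) {
  k <- length(accuracy_samples)
  if (k < 2 || length(performance_samples) != k)
    stopf("need >= 2 conditions with matching accuracy and performance samples")
  acc_mean <- vapply(accuracy_samples, mean, numeric(1))
  perf_mean <- vapply(performance_samples, mean, numeric(1))
  r <- stats::cor(acc_mean, perf_mean)
  boot_r <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    a <- vapply(accuracy_samples, function(v)
      mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
    p <- vapply(performance_samples, function(v)
      mean(v[sample.int(length(v), replace = TRUE)]), numeric(1))
    suppressWarnings(stats::cor(a, p))
  }, numeric(1)))
  alpha <- (1 - level) / 2
  ci <- stats::quantile(boot_r, c(alpha, 1 - alpha), names = FALSE, na.rm = TRUE)
  list(r = r, r_squared = r^2, ci = ci, boot_r = boot_r,
       condition_means = data.frame(condition = names(accuracy_samples) %||%
                                      seq_len(k),
                                    accuracy = acc_mean,
                                    correct_rate = perf_mean))
}
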
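#' Candidate model specifications for performance GLMs
#'
#' A model is a set of trial covariates (optionally with interactions) used to
#' explain the per-combination mean correct rate. The covariate universe:
#' `sample_odor`, `test_odor`, `relation` (match/non-match or paired/unpaired),
#' `genotype`, `laser_on`, `perturb_epoch`, `decay` (the delay duration
#' transformed to `exp(-delay_s / tau)` with tau from [fit_memory_decay()]),
#' and the derived indicator `perturb_delay` (laser on during the delay epoch
#' in a ChR2 subject, i.e. suppression actually happened).
#'
#' @param model_id Integer or character label.
#' @param terms Character vector of covariate names (may be empty for an
#'   intercept-only model).
#' @param interactions List of character vectors; each becomes a product term.
#' @return A `model_spec` list.
#' @export
model_spec <- function(model_id, terms = character(0), interactions = list()) {
  universe <- glm_covariate_universe()
  bad <- setdiff(unique(c(terms, unlist(interactions))), universe)
  if (length(bad) > 0)
    stopf("unknown model term(s): %s (universe: %s)",
          paste(bad, collapse = ", "), paste(universe, collapse = ", "))
  structure(list(model_id = model_id, terms = terms,
                 interactions = interactions),
            class = "model_spec")
}

#' @rdname model_spec
#' @export
glm_covariate_universe <- function() {
  c("sample_odor", "test_odor", "relation", "genotype", "laser_on",
    "perturb_epoch", "decay", "perturb_delay")
}

spec_formula <- function(spec) {
  parts <- c(spec$terms,
             vapply(spec$interactions, paste, character(1), collapse = ":"))
  if (length(parts) == 0) parts <- "1"
  stats::as.formula(paste("~", paste(parts, collapse = " + ")))
}

spec_variables <- function(spec) {
  unique(c(spec$terms, unlist(spec$interactions)))
}

#' Default seven-candidate model set
#'
#' Shipping defaults for the candidate family, from the null model with no
#' task parameter (#1), through sensory cues (#2), memory decay (#3),
#' perturbation main effects (#4) and their interactions (#5), to the compact
#' model (#6) combining the delay-period-suppression indicator, the trial
#' relation and the memory-decay value with their interactions, and a
#' kitchen-sink superset (#7). All are editable via [model_spec()].
#'
#' @return A named list of 7 [model_spec()]s.
#' @export
default_model_specs <- function() {
  pe <- c("genotype", "laser_on", "perturb_epoch")
  list(
    m1 = model_spec(1L),
    m2 = model_spec(2L, c("sample_odor", "test_odor")),
    m3 = model_spec(3L, c("sample_odor", "test_odor", "decay")),
    m4 = model_spec(4L, c("sample_odor", "test_odor", "decay", pe)),
    m5 = model_spec(5L, c("sample_odor", "test_odor", "decay", pe),
                    interactions = list(c("genotype", "laser_on"),
                                        c("genotype", "perturb_epoch"),
                                        c("laser_on", "perturb_epoch"),
                                        pe)),
    m6 = model_spec(6L, c("perturb_delay", "relation", "decay"),
                    interactions = list(c("perturb_delay", "relation"),
                                        c("perturb_delay", "decay"),
                                        c("relation", "decay"),
                                        c("perturb_delay", "relation", "decay"))),
    m7 = model_spec(7L, glm_covariate_universe()[1:7],
                    interactions = list(c("relation", "decay"),
                                        c("genotype", "laser_on"),
                                        c("genotype", "laser_on", "perturb_epoch"),
                                        c("laser_on", "perturb_epoch", "decay")))
  )
}

#' Per-trial covariate frame for the GLM universe
#'
#' Builds the per-trial covariates used by the candidate models: the factors
#' `sample_odor`, `test_odor`, `relation` (collapsed to rewarded/unrewarded),
#' `genotype`, `perturb_epoch`; numeric `laser_on`, `decay`
#' (`exp(-delay_s / tau_s)`) and the `perturb_delay` suppression indicator.
#'
#' @param trials A [trial_table()].
#' @param tau_s Memory-decay time constant in seconds.
#' @export
glm_covariates <- function(trials, tau_s) {
  rel <- ifelse(trials$relation %in% c("match", "nonmatch"),
                ifelse(trials$relation == "nonmatch", "rewarded", "unrewarded"),
                ifelse(trials$relation %in% rewarded_relations,
                       "rewarded", "unrewarded"))
  data.frame(
    sample_odor = factor(trials$sample_odor),
    test_odor = factor(ifelse(is.na(trials$test_odor), "none",
                              trials$test_odor)),
    relation = factor(rel, levels = c("unrewarded", "rewarded")),
    genotype = factor(trials$genotype, levels = wm_genotypes),
    laser_on = as.numeric(trials$laser_on),
    perturb_epoch = factor(trials$perturb_epoch, levels = wm_epochs),
    decay = exp(-trials$delay_s / tau_s),
    perturb_delay = as.numeric(trials$laser_on &
                                 trials$perturb_epoch == "delay" &
                                 trials$genotype == "ChR2"))
}

#' Build the grouped design for a candidate model
#'
#' Trials sharing the same combination of the model's covariates are grouped;
#' the group's mean correct rate is the response. Categorical covariates are
#' dummy-coded and interaction columns are products; aliased columns are
#' dropped with a warning.
#'
#' @param trials A [trial_table()] with outcomes filled.
#' @param spec A [model_spec()].
#' @param tau_s Memory-decay time constant used for the `decay` covariate.
#' @return List: `X` (design matrix), `mu` (group mean correct rates), `w`
#'   (group sizes), `groups` (covariate frame, one row per group),
#'   `group_trials` (trial-index list), `terms`, `xlevels`.
#' @export
build_design <- function(trials, spec, tau_s) {
  if (any(is.na(trials$outcome))) stopf("outcomes must be filled")
  covs <- glm_covariates(trials, tau_s)
  vars <- spec_variables(spec)
  correct <- as.numeric(outcome_correct(trials$outcome))
  key <- if (length(vars) == 0) rep("all", nrow(trials))
         else do.call(paste, c(covs[vars], sep = "\r"))
  group_trials <- split(seq_len(nrow(trials)), key)
  groups <- covs[vapply(group_trials, `[`, integer(1), 1), , drop = FALSE]
  rownames(groups) <- NULL
  mu <- vapply(group_trials, function(ii) mean(correct[ii]), numeric(1))
  w <- lengths(group_trials)
  fml <- spec_formula(spec)
  mf <- stats::model.frame(fml, data = groups)
  X <- stats::model.matrix(fml, data = mf)
  qrX <- qr(X * sqrt(w))
  if (qrX$rank < ncol(X)) {
    drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    warnf("dropping %d aliased design column(s): %s", length(drop),
          paste(colnames(X)[drop], collapse = ", "))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  list(X = X, mu = unname(mu), w = unname(w), groups = groups,
       group_trials = unname(lapply(group_trials, function(ii) correct[ii])),
       terms = stats::terms(mf), xlevels = stats::.getXlevels(stats::terms(mf), mf),
       model_id = spec$model_id)
}

#' Weighted Gaussian-identity fit of a grouped design
#'
#' Weighted least squares of the group mean correct rates on the design
#' matrix, weights = group sizes. Returns the coefficients, weighted r-squared,
#' Gaussian log-likelihood and `AIC = 2k - 2 logL` with `k` = number of
#' coefficients + 1 (the residual variance).
#'
#' @param design Output of [build_design()] (or a matrix).
#' @param mu,w Response and weights; defaulted from `design`.
#' @export
fit_glm <- function(design, mu = design$mu, w = design$w) {
  X <- if (is.list(design)) design$X else design
  n <- length(mu)
  if (n < ncol(X)) stopf("fewer groups (%d) than coefficients (%d)", n, ncol(X))
  sw <- sqrt(w)
  fit <- stats::lm.fit(X * sw, mu * sw)
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  mbar <- sum(w * mu) / sum(w)
  tss <- sum(w * (mu - mbar)^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  rss_f <- max(rss, 1e-300)
  ll <- -n / 2 * (log(2 * pi) + log(rss_f / n) + 1) + sum(log(w)) / 2
  k <- fit$rank + 1
  list(coefficients = b, r_squared = r2, log_lik = ll,
       aic = 2 * k - 2 * ll, k = k, rss = rss, fitted = X %*% b)
}

#' Compare candidate GLMs by bootstrap AIC
#'
#' All candidates are fit to the shared task-parameter-combination table:
#' trials are grouped by the union of the candidates' covariates, giving every
#' model the same response vector (group mean correct rates, weighted by group
#' size) and hence comparable likelihoods - under per-model grouping an
#' intercept-only candidate would be saturated (one group, zero residual) and
#' its AIC meaningless. For each bootstrap replicate, trial outcomes are
#' resampled with replacement within the shared groups (sizes preserved, so
#' no group can empty), the group means recomputed, and every candidate refit
#' on the same replicate; per-replicate AIC and r-squared are recorded. The
#' selected model is the one with the lowest mean bootstrap AIC; its AIC
#' distribution is compared pairwise to every other candidate by a
#' permutation test over replicates.
#'
#' @param trials A [trial_table()] with outcomes filled.
#' @param specs List of [model_spec()]s (>= 1).
#' @param tau_s Memory-decay time constant (held fixed across replicates; see
#'   the fit metadata).
#' @param n_boot Bootstrap replicates (default 500).
#' @param seed Optional integer seed.
#' @param n_perm_pairwise Repeats for the pairwise AIC permutation tests; 0
#'   skips them.
#' @return A `model_comparison` list: `summary` data.frame (one row per
#'   model: point AIC/r2, bootstrap means and SDs), `aic_boot` / `r2_boot`
#'   matrices (replicate x model), `selected_model_id`, `pairwise_p`,
#'   `designs`, `boot_coefs` for the selected model, `tau_s`,
#'   `tau_policy = "fixed point estimate"`.
#' @export
compare_models <- function(trials, specs, tau_s, n_boot = 500, seed = NULL,
                           n_perm_pairwise = 1000) {
  if (length(specs) < 1) stopf("need at least one model spec")
  ids <- vapply(specs, function(s) as.character(s$model_id), character(1))
  union_vars <- unique(unlist(lapply(specs, spec_variables)))
  base <- build_design(trials, model_spec("shared", union_vars), tau_s)
  designs <- lapply(specs, function(s) {
    fml <- spec_formula(s)
    mf <- stats::model.frame(fml, data = base$groups)
    X <- stats::model.matrix(fml, data = mf)
    qrX <- qr(X * sqrt(base$w))
    if (qrX$rank < ncol(X)) {
      drop <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
      warnf("model %s: dropping %d aliased design column(s): %s", s$model_id,
            length(drop), paste(colnames(X)[drop], collapse = ", "))
      X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
    }
    list(X = X, mu = base$mu, w = base$w, groups = base$groups,
         group_trials = base$group_trials, terms = stats::terms(mf),
         xlevels = stats::.getXlevels(stats::terms(mf), mf),
         model_id = s$model_id)
  })
  point <- lapply(designs, fit_glm)
  aic_boot <- matrix(NA_real_, n_boot, length(specs),
                     dimnames = list(NULL, ids))
  r2_boot <- aic_boot
  sel_coefs <- NULL
  with_seed(seed, {
    coef_store <- lapply(designs, function(d)
      matrix(NA_real_, n_boot, ncol(d$X), dimnames = list(NULL, colnames(d$X))))
    for (b in seq_len(n_boot)) {
      mu_b <- vapply(base$group_trials, function(cc)
        mean(cc[sample.int(length(cc), replace = TRUE)]), numeric(1))
      for (m in seq_along(specs)) {
        d <- designs[[m]]
        f <- fit_glm(d, mu = mu_b, w = d$w)
        aic_boot[b, m] <- f$aic
        r2_boot[b, m] <- f$r_squared
        coef_store[[m]][b, ] <- f$coefficients
      }
    }
    sel <- which.min(colMeans(aic_boot))
    sel_coefs <- coef_store[[sel]]
  })
  aic_mean <- colMeans(aic_boot)
  sel <- which.min(aic_mean)
  pairwise <- rep(NA_real_, length(specs)); names(pairwise) <- ids
  if (n_perm_pairwise > 0 && length(specs) > 1) {
    for (m in seq_along(specs)) {
      if (m == sel) next
      pairwise[m] <- permutation_test(aic_boot[, sel], aic_boot[, m],
                                      n_rep = n_perm_pairwise,
                                      seed = NULL)$p_value
    }
  }
  summary_df <- data.frame(
    model_id = ids,
    k = vapply(point, `[[`, numeric(1), "k"),
    aic_point = vapply(point, `[[`, numeric(1), "aic"),
    r2_point = vapply(point, `[[`, numeric(1), "r_squared"),
    aic_boot_mean = aic_mean,
    aic_boot_sd = apply(aic_boot, 2, stats::sd),
    r2_boot_mean = colMeans(r2_boot),
    selected = seq_along(specs) == sel,
    stringsAsFactors = FALSE)
  rownames(summary_df) <- NULL
  structure(list(summary = summary_df, aic_boot = aic_boot, r2_boot = r2_boot,
                 selected_model_id = specs[[sel]]$model_id,
                 selected_index = sel, pairwise_p = pairwise,
                 designs = designs, point_fits = point,
                 boot_coefs = sel_coefs, specs = specs, tau_s = tau_s,
                 tau_policy = "fixed point estimate"),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("<model_comparison> %d candidates, selected model %s (lowest mean bootstrap AIC)\n",
              nrow(x$summary), x$selected_model_id))
  print(x$summary[c("model_id", "k", "aic_point", "r2_point",
                    "aic_boot_mean", "selected")], digits = 4)
  invisible(x)
}

#' Predicted correct-rate surface from the selected model
#'
#' Evaluates `X b` for the selected model on a covariate grid, with bootstrap
#' confidence bands from the replicate coefficient distributions.
#'
#' @param result A `model_comparison` from [compare_models()].
#' @param grid Data.frame over the selected model's covariates (e.g. a delay
#'   sweep crossed with the suppression indicator).
#' @param level Band coverage (default 0.95).
#' @return `grid` augmented with `predicted`, `lower`, `upper`.
#' @export
project_effects <- function(result, grid, level = 0.95) {
  d <- result$designs[[result$selected_index]]
  vars <- all.vars(stats::delete.response(d$terms))
  missing_vars <- setdiff(vars, names(grid))
  if (length(missing_vars) > 0)
    stopf("grid is missing model covariate(s): %s",
          paste(missing_vars, collapse = ", "))
  X <- stats::model.matrix(stats::delete.response(d$terms), data = grid,
                           xlev = d$xlevels)
  X <- X[, colnames(d$X), drop = FALSE]
  b <- result$point_fits[[result$selected_index]]$coefficients
  pred <- drop(X %*% b)
  boot_pred <- X %*% t(result$boot_coefs)
  a <- (1 - level) / 2
  qs <- apply(boot_pred, 1, stats::quantile, probs = c(a, 1 - a))
  out <- grid
  out$predicted <- pred
  out$lower <- qs[1, ]
  out$upper <- qs[2, ]
  out
}
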
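# Cohort with crossed suppression structure used throughout this file.
glm_fixture_trials <- function(seed = 1, n_trials = 160, n_subjects = 4) {
  spec <- behavior_gen_spec(n_subjects = n_subjects,
                            n_trials_per_subject = n_trials)
  simulate_behavior_cohort(
    spec, list(task = "DNMS", delays_s = c(5, 12, 20),
               laser_scheme = "interleaved"),
    seed = seed)
}

test_that("build_design groups trials by the model's covariate combinations", {
  tr <- glm_fixture_trials()
  # two binary covariates fully crossed -> 4 design rows
  d2 <- build_design(tr, model_spec("x", c("laser_on", "relation")), tau_s = 20)
  expect_equal(nrow(d2$X), 4)
  expect_equal(sum(d2$w), nrow(tr))
  # intercept-only model: one group whose response is the overall correct rate
  d1 <- build_design(tr, model_spec(1L), tau_s = 20)
  expect_equal(nrow(d1$X), 1)
  expect_equal(d1$mu, mean(tr$outcome %in% c("hit", "correct_rejection")))
  expect_equal(d1$w, nrow(tr))
  # unknown term is rejected by name
  expect_error(model_spec("bad", "flavor"), "flavor")
})

test_that("weighted least squares recovers exact coefficients and the AIC formula", {
  tr <- glm_fixture_trials()
  spec <- model_spec("m", c("relation", "decay"),
                     interactions = list(c("relation", "decay")))
  d <- build_design(tr, spec, tau_s = 20)
  # noiseless response generated from known coefficients is interpolated
  b_true <- c(0.6, 0.1, 0.25, -0.15)
  mu_gen <- drop(d$X %*% b_true)
  f <- fit_glm(d, mu = mu_gen)
  expect_lt(max(abs(f$coefficients - b_true)), 1e-9)
  expect_lt(f$rss, 1e-18)
  # intercept-only fit equals the weighted mean
  d1 <- build_design(tr, model_spec(1L), tau_s = 20)
  f1 <- fit_glm(d1)
  expect_equal(unname(f1$coefficients[1]), sum(d1$w * d1$mu) / sum(d1$w))
  # AIC against an independent weighted-Gaussian likelihood oracle
  f2 <- fit_glm(d)
  n <- length(d$mu)
  res <- d$mu - drop(d$X %*% f2$coefficients)
  rss_w <- sum(d$w * res^2)
  ll <- -n / 2 * (log(2 * pi) + log(rss_w / n) + 1) + sum(log(d$w)) / 2
  expect_lt(abs(f2$log_lik - ll), 1e-9)
  expect_lt(abs(f2$aic - (2 * (ncol(d$X) + 1) - 2 * ll)), 1e-9)
  # lm cross-check of the coefficients
  lmfit <- lm(d$mu ~ 0 + d$X, weights = d$w)
  expect_lt(max(abs(unname(coef(lmfit)) - unname(f2$coefficients))), 1e-9)
})

test_that("adding terms never increases the point-fit weighted SSE", {
  tr <- glm_fixture_trials(seed = 3)
  nested <- list(model_spec(1L),
                 model_spec(2L, "decay"),
                 model_spec(3L, c("decay", "relation")),
                 model_spec(4L, c("decay", "relation", "perturb_delay")),
                 model_spec(5L, c("decay", "relation", "perturb_delay"),
                            interactions = list(c("perturb_delay", "decay"))))
  # evaluate all models on the finest grouping so SSEs are comparable
  full_vars <- c("decay", "relation", "perturb_delay")
  base <- build_design(tr, model_spec(0L, full_vars), tau_s = 20)
  sse <- vapply(nested, function(sp) {
    X <- model.matrix(wmpop:::spec_formula(sp), data = base$groups)
    f <- fit_glm(X, mu = base$mu, w = base$w)
    sum(base$w * (base$mu - drop(X %*% f$coefficients))^2)
  }, numeric(1))
  expect_true(all(diff(sse) < 1e-9))
})

test_that("compare_models selects by mean bootstrap AIC and degenerates gracefully", {
  tr <- glm_fixture_trials(seed = 5)
  # single candidate is selected trivially
  one <- compare_models(tr, list(model_spec("only", "decay")), tau_s = 20,
                        n_boot = 25, seed = 2, n_perm_pairwise = 0)
  expect_equal(one$selected_model_id, "only")
  specs <- list(model_spec("null"), model_spec("decay", "decay"))
  cmp <- compare_models(tr, specs, tau_s = 20, n_boot = 50, seed = 2,
                        n_perm_pairwise = 200)
  expect_equal(cmp$summary$model_id[cmp$summary$selected],
               as.character(cmp$selected_model_id))
  expect_equal(which.min(cmp$summary$aic_boot_mean),
               which(cmp$summary$selected))
  expect_true(all(is.na(cmp$pairwise_p[cmp$selected_index])))
})

test_that("doubling the bootstrap concentrates AIC around the point fit", {
  tr <- glm_fixture_trials(seed = 7)
  spec <- list(model_spec("m", c("decay", "relation")))
  c1 <- compare_models(tr, spec, tau_s = 20, n_boot = 100, seed = 3,
                       n_perm_pairwise = 0)
  c2 <- compare_models(tr, spec, tau_s = 20, n_boot = 200, seed = 3,
                       n_perm_pairwise = 0)
  point <- c1$summary$aic_point
  expect_lt(abs(c2$summary$aic_boot_mean - c1$summary$aic_boot_mean),
            3 * c1$summary$aic_boot_sd)
  expect_lt(abs(c2$summary$aic_boot_mean - point), 3 * c2$summary$aic_boot_sd +
              10)
})

test_that("project_effects reproduces fitted design points and zeroed interactions", {
  tr <- glm_fixture_trials(seed = 9)
  spec <- model_spec(6L, c("perturb_delay", "relation", "decay"),
                     interactions = list(c("perturb_delay", "decay")))
  cmp <- compare_models(tr, list(spec), tau_s = 20, n_boot = 60, seed = 4,
                        n_perm_pairwise = 0)
  d <- cmp$designs[[1]]
  pred <- project_effects(cmp, d$groups)
  fitted <- drop(d$X %*% cmp$point_fits[[1]]$coefficients)
  expect_lt(max(abs(pred$predicted - fitted)), 1e-9)
  expect_true(all(pred$lower <= pred$predicted + 1e-9))
  expect_true(all(pred$upper >= pred$predicted - 1e-9))
  # unperturbed grid rows depend only on the decay / relation terms
  grid <- data.frame(perturb_delay = 0,
                     relation = factor("rewarded",
                                       levels = c("unrewarded", "rewarded")),
                     decay = exp(-c(5, 12, 20, 30) / 20))
  p0 <- project_effects(cmp, grid)
  b <- cmp$point_fits[[1]]$coefficients
  manual <- b["(Intercept)"] + b["relationrewarded"] + b["decay"] * grid$decay
  expect_lt(max(abs(p0$predicted - unname(manual))), 1e-9)
  expect_error(project_effects(cmp, data.frame(decay = 0.5)),
               "missing model covariate")
})
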
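test_that("logit transform and delta-method variance match hand computation", {
  expect_equal(logit_with_variance(50, 100), data.frame(y = 0, v = 0.04))
  obs <- logit_with_variance(41, 100)
  expect_equal(obs$y, log(41 / 59))
  expect_equal(obs$v, 1 / 41 + 1 / 59)
  # boundary counts get the +0.5 / +1 continuity correction
  zero <- logit_with_variance(0, 100)
  expect_equal(zero$y, log(0.5 / 100.5))
  expect_equal(zero$v, 1 / 0.5 + 1 / 100.5)
  full <- logit_with_variance(100, 100)
  expect_equal(full$y, log(100.5 / 0.5))
  expect_error(logit_with_variance(1, 0), "positive")
  expect_error(logit_with_variance(5, 4), "cases")
})

test_that("tau2 = 0 fit reproduces the closed-form inverse-variance WLS mean", {
  set.seed(31)
  for (rep in 1:20) {
    k <- sample(3:12, 1)
    y <- rnorm(k)
    v <- runif(k, 0.01, 0.5)
    fit <- fit_prevalence_model(data.frame(y = y, v = v), tau2_fixed = 0)
    expect_equal(fit$beta[["intercept"]], sum(y / v) / sum(1 / v), tolerance = 1e-14)
    expect_equal(fit$beta_cov[1, 1], 1 / sum(1 / v), tolerance = 1e-14)
  }
})

test_that("homogeneous observations give the common value and zero heterogeneity", {
  obs <- data.frame(y = rep(0.7, 3), v = c(0.1, 0.2, 0.05))
  for (m in c("REML", "moment")) {
    fit <- fit_prevalence_model(obs, method = m)
    expect_equal(fit$beta[["intercept"]], 0.7, tolerance = 1e-10)
    expect_equal(fit$tau2, 0, tolerance = 1e-8)
  }
})

test_that("moment estimator equals the independent DerSimonian-Laird oracle", {
  set.seed(41)
  for (rep in 1:30) {
    k <- sample(3:10, 1)
    n <- sample(50:500, k, replace = TRUE)
    cases <- rbinom(k, n, runif(k, 0.1, 0.6))
    obs <- logit_with_variance(cases, n)
    fit <- fit_prevalence_model(obs, method = "moment")
    oracle <- dl_pool_oracle(obs$y, obs$v)
    expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-12)
    expect_equal(fit$beta[["intercept"]], oracle$mu, tolerance = 1e-12)
    expect_equal(sqrt(fit$beta_cov[1, 1]), oracle$se, tolerance = 1e-12)
  }
})

test_that("moment and REML fits agree with metafor on meta-regression designs", {
  skip_if_not_installed("metafor")
  set.seed(51)
  for (rep in 1:5) {
    tab <- generate_study_table(sim_config(
      60, beta = c(intercept = -1, high_trauma = 0.8), tau2 = 0.25, seed = 500 + rep))
    obs <- observations_from_table(tab)
    mm <- fit_prevalence_model(obs, "high_trauma", method = "moment")
    rm_dl <- metafor::rma(yi = obs$y, vi = obs$v, mods = ~ obs$high_trauma,
                          method = "DL")
    expect_equal(mm$tau2, rm_dl$tau2, tolerance = 1e-8)
    expect_equal(unname(mm$beta), as.numeric(rm_dl$beta), tolerance = 1e-8)
    mr <- fit_prevalence_model(obs, "high_trauma", method = "REML")
    rm_reml <- metafor::rma(yi = obs$y, vi = obs$v, mods = ~ obs$high_trauma,
                            method = "REML", control = list(tau2.min = 0))
    expect_equal(mr$tau2, rm_reml$tau2, tolerance = 1e-4)
    expect_equal(unname(mr$beta), as.numeric(rm_reml$beta), tolerance = 1e-4)
  }
})

test_that("estimated heterogeneity is never negative", {
  set.seed(61)
  for (rep in 1:20) {
    k <- sample(4:15, 1)
    obs <- data.frame(y = rnorm(k, 0, 0.05), v = runif(k, 0.1, 0.5))
    expect_gte(fit_prevalence_model(obs, method = "moment")$tau2, 0)
    expect_gte(fit_prevalence_model(obs, method = "REML")$tau2, 0)
  }
})

test_that("rank-deficient designs fail with the collinear column named", {
  obs <- data.frame(y = rnorm(10), v = rep(0.1, 10),
                    a = rep(1, 10), b = 1:10)
  expect_error(fit_prevalence_model(obs, c("a", "b")), "collinear.*a")
  expect_error(fit_prevalence_model(obs, c("missing_col")), "not found")
  expect_error(fit_prevalence_model(data.frame(y = 1, v = 0.1)), "at least")
})

test_that("stratum prediction back-transforms with a Wald interval on the logit", {
  # hand-built model with zero covariance: degenerate interval at expit(eta)
  m0 <- structure(list(beta = c(intercept = 0), beta_cov = matrix(0, 1, 1),
                       tau2 = 0, method = "REML", n_studies = 10,
                       covariates = character(), tau2_fixed = NULL),
                  class = "prev_meta")
  p <- predict_stratum(m0)
  expect_equal(unlist(p[, 1:3]), c(prevalence = 0.5, ci_low = 0.5, ci_high = 0.5))
  # expit(logit(p)) identity through a shifted intercept
  for (prob in c(0.1, 0.413, 0.9)) {
    m <- m0
    m$beta <- c(intercept = qlogis(prob))
    expect_equal(predict_stratum(m)$prevalence, prob)
  }
  expect_error(predict_stratum(m0, list(oops = 1)), "unknown covariate")
})

test_that("predicted prevalence is monotone in a positive coefficient's covariate", {
  tab <- generate_study_table(sim_config(
    150, beta = c(intercept = -1, pte_ratio = 2), tau2 = 0.1, seed = 77))
  obs <- cbind(logit_with_variance(tab$cases, tab$n),
               pte_ratio = pte_adversity_ratio(tab$pte_endorsed, tab$pte_assessed))
  fit <- fit_prevalence_model(obs, "pte_ratio")
  expect_gt(fit$beta[["pte_ratio"]], 0)
  grid <- seq(0.05, 0.6, by = 0.05)
  preds <- vapply(grid, function(r)
    predict_stratum(fit, list(pte_ratio = r))$prevalence, numeric(1))
  expect_true(all(diff(preds) > 0))
})

test_that("odds ratios exponentiate linear-predictor contrasts", {
  m <- structure(list(beta = c(intercept = -1, x = log(2)),
                      beta_cov = diag(c(0.01, 0.04)), tau2 = 0.1,
                      method = "REML", n_studies = 50, covariates = "x",
                      tau2_fixed = NULL),
                 class = "prev_meta")
  o <- odds_ratio(m, list(x = 1), list(x = 0))
  expect_equal(o$or, 2)
  expect_equal(o$ci_low, exp(log(2) - 1.96 * 0.2))
  same <- odds_ratio(m, list(x = 1), list(x = 1))
  expect_equal(unlist(same), c(or = 1, ci_low = 1, ci_high = 1))
})

test_that("heterogeneity decomposition follows the tau2 arithmetic", {
  mk <- function(tau2) structure(list(beta = c(intercept = 0),
                                      beta_cov = matrix(0.1, 1, 1), tau2 = tau2,
                                      method = "REML", n_studies = 100,
                                      covariates = character(), tau2_fixed = NULL),
                                 class = "prev_meta")
  ve <- variance_explained(mk(0.647), mk(0.83), mk(1.0))
  expect_equal(ve$base_share, 0.17)
  expect_equal(ve$additive_share, 0.183)
  same <- variance_explained(mk(0.83), mk(0.83), mk(1.0))
  expect_equal(same$additive_share, 0)
  expect_warning(ve0 <- variance_explained(mk(0), mk(0), mk(0)), "undefined")
  expect_equal(ve0$base_share, 0)
})

test_that("a covariate unrelated to the outcome explains no heterogeneity in expectation", {
  set.seed(91)
  shares <- replicate(20, {
    tab <- generate_study_table(sim_config(
      80, beta = c(intercept = -1), tau2 = 0.3, seed = sample.int(1e6, 1)))
    obs <- cbind(logit_with_variance(tab$cases, tab$n), noise = rnorm(80))
    null <- fit_prevalence_model(obs)
    full <- fit_prevalence_model(obs, "noise")
    variance_explained(full, null, null)$additive_share
  })
  expect_lt(mean(shares), 0.05)
})

test_that("fitted models round-trip through JSON", {
  tab <- generate_study_table(sim_config(
    40, beta = c(intercept = -1, high_trauma = 0.5), tau2 = 0.2, seed = 13))
  fit <- fit_prevalence_model(observations_from_table(tab), "high_trauma")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(fit, path)
  back <- read_model_json(path)
  expect_equal(back$beta, fit$beta)
  expect_equal(back$beta_cov, fit$beta_cov)
  expect_equal(back$tau2, fit$tau2)
  expect_equal(predict_stratum(back, list(high_trauma = 1)),
               predict_stratum(fit, list(high_trauma = 1)))
})
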
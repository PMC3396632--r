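test_that("SDS categories partition [0, 10] at the 4 and 7 cut-offs", {
  expect_equal(categorize_sds(3), "mild")
  expect_equal(categorize_sds(7), "severe")
  expect_equal(categorize_sds(0), "mild")
  grid <- seq(0, 10, by = 0.25)
  cats <- categorize_sds(grid)
  expect_true(all(cats %in% c("mild", "moderate", "severe")))
  expect_equal(cats[grid < 4], rep("mild", sum(grid < 4)))
  expect_equal(cats[grid >= 4 & grid < 7], rep("moderate", sum(grid >= 4 & grid < 7)))
  expect_equal(cats[grid >= 7], rep("severe", sum(grid >= 7)))
  # category boundaries are adjacent: no score is unclassified or doubly classified
  expect_equal(length(cats), length(grid))
  expect_error(categorize_sds(11), "0, 10")
  expect_error(categorize_sds(-1), "0, 10")
})

test_that("random-effects pooling of proportions matches the DL-on-logits oracle", {
  pooled <- pool_proportions(c(30, 25, 35), c(100, 100, 100))
  obs <- logit_with_variance(c(30, 25, 35), c(100, 100, 100))
  oracle <- dl_pool_oracle(obs$y, obs$v)
  expect_equal(pooled$prop, plogis(oracle$mu), tolerance = 1e-12)
  expect_equal(pooled$ci_low, plogis(oracle$mu - 1.96 * oracle$se), tolerance = 1e-4)
  expect_equal(pooled$tau2, oracle$tau2, tolerance = 1e-12)
  set.seed(17)
  for (rep in 1:25) {
    k <- sample(3:10, 1)
    tot <- sample(40:400, k, replace = TRUE)
    ev <- rbinom(k, tot, runif(1, 0.2, 0.7))
    pl <- pool_proportions(ev, tot)
    obs <- logit_with_variance(ev, tot)
    orc <- dl_pool_oracle(obs$y, obs$v)
    expect_equal(pl$prop, plogis(orc$mu), tolerance = 1e-12)
    expect_equal(pl$tau2, orc$tau2, tolerance = 1e-12)
    # pooled estimate lies within the span of study proportions
    expect_gte(pl$prop, min(ev / tot))
    expect_lte(pl$prop, max(ev / tot))
  }
  expect_error(pool_proportions(integer(), integer()), "no studies")
})

test_that("homogeneous severity studies pool to the common proportion", {
  pl <- pool_proportions(rep(30, 4), rep(100, 4))
  expect_equal(pl$prop, 0.30, tolerance = 1e-10)
  expect_equal(pl$tau2, 0)
})

test_that("double-arcsine pooling is a sane alternative transform", {
  pl <- pool_proportions(c(30, 25, 35), c(100, 100, 100), transform = "arcsine")
  expect_gt(pl$prop, 0.2)
  expect_lt(pl$prop, 0.4)
  expect_lte(pl$ci_low, pl$prop)
  expect_gte(pl$ci_high, pl$prop)
})

test_that("severe prevalence scales the total estimate and CI by the point severity", {
  ptsd <- severe_prevalence(
    data.frame(prevalence = 41.3, ci_low = 28.3, ci_high = 55.6), 0.30, percent = TRUE)
  expect_equal(unlist(ptsd), c(prevalence = 12.4, ci_low = 8.5, ci_high = 16.7))
  dep <- severe_prevalence(
    data.frame(prevalence = 37.3, ci_low = 26.5, ci_high = 49.6), 0.53, percent = TRUE)
  expect_equal(unlist(dep), c(prevalence = 19.8, ci_low = 14.0, ci_high = 26.3))
  zero <- severe_prevalence(
    data.frame(prevalence = 41.3, ci_low = 28.3, ci_high = 55.6), 0, percent = TRUE)
  expect_equal(unlist(zero), c(prevalence = 0, ci_low = 0, ci_high = 0))
  # CI ordering is preserved for arbitrary valid inputs
  set.seed(23)
  for (rep in 1:20) {
    ci <- sort(runif(3))
    s <- runif(1)
    out <- severe_prevalence(
      data.frame(prevalence = ci[2], ci_low = ci[1], ci_high = ci[3]), s)
    expect_true(out$ci_low <= out$prevalence && out$prevalence <= out$ci_high)
  }
})

test_that("Monte-Carlo severity propagation widens the interval around the same point", {
  total <- data.frame(prevalence = 0.413, ci_low = 0.283, ci_high = 0.556)
  sev <- list(prop = 0.30, ci_low = 0.27, ci_high = 0.33)
  plain <- severe_prevalence(total, sev$prop)
  mc <- severe_prevalence_mc(total, sev, seed = 4)
  expect_equal(mc$prevalence, plain$prevalence)
  expect_lt(mc$ci_low, plain$prevalence)
  expect_gt(mc$ci_high, plain$prevalence)
  expect_gt(mc$ci_high - mc$ci_low, 0)
  # reproducible under the seed
  expect_equal(mc, severe_prevalence_mc(total, sev, seed = 4))
})

test_that("comorbidity split derives the three planning groups", {
  # published reproduction: override injects the printed depression-only count
  sp <- comorbidity_split(123200, 228100, 0.5, depression_only_override = 43300)
  expect_equal(sp, list(ptsd_only = 61600, depression_only = 43300, comorbid = 61600))
  # stated rule without override: depression-only by subtraction
  sp2 <- comorbidity_split(123200, 228100, 0.5)
  expect_equal(sp2, list(ptsd_only = 61600, depression_only = 166500, comorbid = 61600))
  # no comorbidity
  expect_equal(comorbidity_split(1000, 2000, 0),
               list(ptsd_only = 1000, depression_only = 2000, comorbid = 0))
  # comorbid counts are rounded half up
  expect_equal(comorbidity_split(101, 1000, 0.5)$comorbid, 51)
  expect_error(comorbidity_split(1000, 100, 0.9), "exceed")
})

test_that("shipped severity constants load with the expected structure", {
  sev <- severity_defaults()
  expect_equal(sev$ptsd$prop, 0.30)
  expect_equal(sev$depression$prop, 0.53)
  expect_equal(sev$phi, 0.5)
  expect_true(sev$ptsd$ci_low <= sev$ptsd$prop && sev$ptsd$prop <= sev$ptsd$ci_high)
})
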
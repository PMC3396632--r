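#' Sheehan Disability Scale severity category
#'
#' Maps an SDS impairment score (0-10, highest-domain score of a 30-day case)
#' to the severity category used for service planning: 0-3 mild, 4-6
#' moderate, 7-10 severe.
#'
#' @param score numeric score(s) in \[0, 10\].
#' @return Character vector: `"mild"`, `"moderate"` or `"severe"`.
#' @export
categorize_sds <- function(score) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 10))
    stopf("SDS score must lie in [0, 10]")
  ifelse(score < 4, "mild", ifelse(score < 7, "moderate", "severe"))
}

#' Pool severity proportions across studies (random effects)
#'
#' DerSimonian-Laird random-effects pooling of per-study proportions on the
#' logit scale (delta-method variances, boundary continuity correction as in
#' [logit_with_variance()]), back-transformed to a pooled proportion with a
#' 95% Wald interval.  A Freeman-Tukey style double-arcsine transform is
#' available as an alternative.
#'
#' @param events per-study counts in the category (e.g. severe cases).
#' @param totals per-study totals (e.g. all cases); all positive.
#' @param transform `"logit"` (default) or `"arcsine"` (double arcsine with
#'   harmonic-mean back-transformation).
#' @param level confidence level.
#' @return A list with `prop`, `ci_low`, `ci_high`, `tau2` and `k`.
#' @export
pool_proportions <- function(events, totals, transform = c("logit", "arcsine"),
                             level = 0.95) {
  transform <- match.arg(transform)
  if (length(events) == 0L) stopf("no studies to pool")
  if (length(events) != length(totals)) stopf("events and totals must have equal length")
  if (any(totals <= 0)) stopf("each total must be positive")
  if (any(events < 0) || any(events > totals)) stopf("events must lie in [0, total]")
  z <- z_crit(level)
  if (transform == "logit") {
    obs <- logit_with_variance(events, totals)
    fit <- fit_prevalence_model(obs, method = "moment")
    mu <- fit$beta[["intercept"]]
    se <- sqrt(fit$beta_cov[1, 1])
    list(prop = expit(mu), ci_low = expit(mu - z * se), ci_high = expit(mu + z * se),
         tau2 = fit$tau2, k = length(events))
  } else {
    y <- asin(sqrt(events / (totals + 1))) + asin(sqrt((events + 1) / (totals + 1)))
    v <- 1 / (totals + 0.5)
    fit <- fit_prevalence_model(data.frame(y = y, v = v), method = "moment")
    mu <- fit$beta[["intercept"]]
    se <- sqrt(fit$beta_cov[1, 1])
    # asymptotic inverse: t ~ 2*asin(sqrt(p)), so p = sin(t/2)^2
    back <- function(t) sin(pmin(pmax(t, 0), pi) / 2)^2
    list(prop = back(mu), ci_low = back(mu - z * se), ci_high = back(mu + z * se),
         tau2 = fit$tau2, k = length(events))
  }
}

#' Severe-case prevalence from total prevalence and a severity proportion
#'
#' Multiplies a stratum's total case prevalence and both confidence bounds by
#' the point estimate of the severe-case proportion.  The severity estimate's
#' own uncertainty is deliberately not propagated (the severe interval is the
#' total interval scaled by the point proportion); [severe_prevalence_mc()]
#' offers Monte-Carlo propagation for sensitivity analysis.
#'
#' @param total one-row `data.frame` with `prevalence`, `ci_low`, `ci_high`
#'   (proportions, as returned by [predict_stratum()], or percent values if
#'   `percent = TRUE`).
#' @param severe_prop point proportion of cases that are severe.
#' @param percent if `TRUE`, inputs are percentages and the result is rounded
#'   half-up to one decimal, the convention used when reporting stratum
#'   prevalences.
#' @return A one-row `data.frame` with `prevalence`, `ci_low`, `ci_high`.
#' @examples
#' # 41.3% (28.3-55.6) total, 30% severe -> 12.4% (8.5-16.7)
#' severe_prevalence(data.frame(prevalence = 41.3, ci_low = 28.3, ci_high = 55.6),
#'                   0.30, percent = TRUE)
#' @export
severe_prevalence <- function(total, severe_prop, percent = FALSE) {
  stopifnot(all(c("prevalence", "ci_low", "ci_high") %in% names(total)),
            severe_prop >= 0, severe_prop <= 1)
  out <- data.frame(prevalence = total$prevalence * severe_prop,
                    ci_low = total$ci_low * severe_prop,
                    ci_high = total$ci_high * severe_prop)
  if (percent) out[] <- lapply(out, round_half_up, unit = 0.1)
  out
}

#' @rdname severe_prevalence
#' @description `severe_prevalence_mc()` propagates severity uncertainty by
#'   simulation: total prevalence draws on the logit scale crossed with
#'   severity draws (logit-normal matched to the severity CI), summarised by
#'   quantiles.
#' @param severity list with `prop`, `ci_low`, `ci_high` for the severity
#'   proportion (as from [pool_proportions()]).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed optional seed.
#' @export
severe_prevalence_mc <- function(total, severity, n_draws = 10000, seed = NULL) {
  with_seed(seed, {
    eta <- logit(total$prevalence)
    se_eta <- (logit(total$ci_high) - logit(total$ci_low)) / (2 * 1.96)
    s_eta <- logit(severity$prop)
    s_se <- (logit(severity$ci_high) - logit(severity$ci_low)) / (2 * 1.96)
    draws <- expit(stats::rnorm(n_draws, eta, se_eta)) *
      expit(stats::rnorm(n_draws, s_eta, s_se))
    q <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    data.frame(prevalence = total$prevalence * severity$prop,
               ci_low = q[1], ci_high = q[2])
  })
}

#' Split severe cases into comorbidity planning groups
#'
#' Applies a comorbidity proportion `phi` (the fraction of PTSD cases also
#' meeting depression criteria) to derive the three service-planning groups:
#' comorbid, PTSD-only and depression-only.
#'
#' @param severe_ptsd total severe PTSD cases.
#' @param severe_depression total severe depression cases.
#' @param phi comorbidity proportion in \[0, 1\].
#' @param depression_only_override optional externally supplied
#'   depression-only count used instead of
#'   `severe_depression - comorbid` (reproduction of published planning
#'   figures requires injecting the published 43,300).
#' @return A list with integer counts `ptsd_only`, `depression_only`,
#'   `comorbid`.
#' @export
comorbidity_split <- function(severe_ptsd, severe_depression, phi = 0.5,
                              depression_only_override = NULL) {
  stopifnot(phi >= 0, phi <= 1, severe_ptsd >= 0, severe_depression >= 0)
  comorbid <- round_half_up(phi * severe_ptsd)
  if (is.null(depression_only_override)) {
    if (comorbid > severe_depression)
      stopf("comorbid cases (%d) exceed severe depression cases (%d); supply an override",
            comorbid, severe_depression)
    depression_only <- severe_depression - comorbid
  } else {
    depression_only <- depression_only_override
  }
  list(ptsd_only = severe_ptsd - comorbid,
       depression_only = depression_only,
       comorbid = comorbid)
}

#' Shipped severity and comorbidity constants
#'
#' Severe-case proportions pooled from the World Mental Health Surveys
#' (anxiety disorders as the PTSD proxy, affective disorders for depression)
#' and the comorbidity proportion, read from the package's configuration
#' file: PTSD 0.30 (0.27-0.33), depression 0.53 (0.46-0.60), phi 0.5.
#'
#' @param path optional path to an alternative JSON file with the same shape.
#' @return Nested list: `ptsd` and `depression` (each `prop`, `ci_low`,
#'   `ci_high`), and `phi`.
#' @export
severity_defaults <- function(path = NULL) {
  path <- path %||% system.file("extdata", "severity_config.json",
                                package = "conflictmh", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}
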
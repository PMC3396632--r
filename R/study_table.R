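#' @title Study-level survey tables
#' @description Data model, validation, CSV input/output and synthetic
#'   generation of study-level prevalence surveys from conflict-affected
#'   populations.  A study table is a plain `data.frame` with one row per
#'   survey and the columns listed in [study_table_columns()].
#' @name study_table
NULL

#' Column schema of a study table
#'
#' @return Character vector of the required column names, in canonical order:
#'   `study_id`, `outcome` (`"PTSD"` or `"depression"`), `cases`, `n`,
#'   `measure_type` (`"self_report"` or `"diagnostic_interview"`), `sampling`
#'   (`"random"` or `"nonrandom"`), `pts` (Political Terror Scale, 1-5),
#'   `pte_endorsed` (mean potentially traumatic events endorsed),
#'   `pte_assessed` (number of PTEs assessed), `years_since_conflict`,
#'   `displaced` (logical).
#' @export
study_table_columns <- function() {
  c("study_id", "outcome", "cases", "n", "measure_type", "sampling",
    "pts", "pte_endorsed", "pte_assessed", "years_since_conflict", "displaced")
}

.outcomes <- c("PTSD", "depression")
.measures <- c("self_report", "diagnostic_interview")
.samplings <- c("random", "nonrandom")

#' PTE adversity ratio
#'
#' The mean number of potentially traumatic events (PTEs) endorsed by a study
#' sample divided by the number of PTEs assessed by its instrument.  The ratio
#' standardises trauma exposure across surveys that use checklists of
#' different lengths; values of 0.3 and above define the "high trauma"
#' stratum.
#'
#' @param pte_endorsed mean PTEs endorsed (non-negative, at most
#'   `pte_assessed`).
#' @param pte_assessed number of PTEs assessed (positive integer).
#' @return The ratio, a value in \[0, 1\]. Vectorised.
#' @examples
#' pte_adversity_ratio(6, 20)   # 0.30, the high-trauma boundary
#' @export
pte_adversity_ratio <- function(pte_endorsed, pte_assessed) {
  if (any(!is.finite(pte_assessed)) || any(pte_assessed <= 0))
    stopf("pte_assessed must be a positive number of events")
  if (any(pte_endorsed < 0) || any(pte_endorsed > pte_assessed))
    stopf("pte_endorsed must lie in [0, pte_assessed]")
  pte_endorsed / pte_assessed
}

#' Exposure stratification
#'
#' Classifies a survey (or a population profile) into political-terror and
#' trauma strata.  Defaults follow the thresholds associated with elevated
#' risk of mental disorder: Political Terror Scale ratings of 4 or 5 are
#' "high" terror, and a PTE adversity ratio of at least 0.3 is "high" trauma.
#'
#' @param pts Political Terror Scale rating, integer 1-5.
#' @param pte_ratio PTE adversity ratio in \[0, 1\].
#' @param pts_cutoff terror threshold; ratings `>= pts_cutoff` are high.
#' @param ratio_cutoff trauma threshold; ratios `>= ratio_cutoff` are high.
#' @return A `data.frame` with character columns `terror` and `trauma`, each
#'   `"moderate"` or `"high"`. Vectorised over `pts` and `pte_ratio`.
#' @examples
#' stratify_exposure(4, 0.3)    # high terror, high trauma
#' stratify_exposure(3, 0.29)   # moderate, moderate
#' @export
stratify_exposure <- function(pts, pte_ratio, pts_cutoff = 4, ratio_cutoff = 0.3) {
  if (any(is.na(pts)) || any(is.na(pte_ratio)))
    stopf("stratification requires both pts and the PTE adversity ratio; got missing values")
  if (any(pts < 1 | pts > 5)) stopf("pts must be a rating between 1 and 5")
  if (any(pte_ratio < 0 | pte_ratio > 1)) stopf("pte_ratio must lie in [0, 1]")
  data.frame(
    terror = ifelse(pts >= pts_cutoff, "high", "moderate"),
    trauma = ifelse(pte_ratio >= ratio_cutoff, "high", "moderate"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for synthetic study tables
#'
#' Describes the data-generating process assumed by the meta-regression:
#' study `i` has true prevalence `logit(p_i) = x_i' beta + u_i` with
#' `u_i ~ N(0, tau2)`, and observed `cases_i ~ Binomial(n_i, p_i)`.
#'
#' @param n_studies number of surveys to generate (0 gives an empty table).
#' @param beta named numeric vector of true coefficients on the logit scale.
#'   Must include `"intercept"`; further names select covariates from
#'   `pts`, `pte_ratio`, `years_since_conflict`, `displaced`, `self_report`,
#'   `nonrandom`, `high_terror`, `high_trauma` (the last two are the stratum
#'   indicator variables).
#' @param tau2 between-study variance on the logit scale (non-negative).
#' @param sample_size_range integer range `c(min, max)` from which survey
#'   sample sizes are drawn uniformly.
#' @param outcome outcome label written into the table.
#' @param seed integer seed; the generator is reproducible given the seed and
#'   leaves the caller's RNG stream untouched.
#' @return A `SimConfig` list.
#' @export
sim_config <- function(n_studies, beta = c(intercept = -1), tau2 = 0,
                       sample_size_range = c(50L, 1000L),
                       outcome = "PTSD", seed = NULL) {
  stopifnot(length(n_studies) == 1L, n_studies >= 0, n_studies == floor(n_studies))
  if (is.null(names(beta)) || names(beta)[1] != "intercept")
    stopf("beta must be a named vector whose first element is 'intercept'")
  known <- c("intercept", "pts", "pte_ratio", "years_since_conflict",
             "displaced", "self_report", "nonrandom", "high_terror", "high_trauma")
  bad <- setdiff(names(beta), known)
  if (length(bad)) stopf("unknown coefficient name(s): %s", paste(bad, collapse = ", "))
  if (tau2 < 0) stopf("tau2 must be non-negative")
  stopifnot(length(sample_size_range) == 2L, sample_size_range[1] >= 1,
            sample_size_range[2] >= sample_size_range[1])
  out <- list(n_studies = as.integer(n_studies), beta = beta, tau2 = tau2,
              sample_size_range = as.integer(sample_size_range),
              outcome = match.arg(outcome, .outcomes), seed = seed)
  class(out) <- "SimConfig"
  out
}

#' Generate a synthetic study table
#'
#' Draws surveys from the meta-regression's assumed model (see
#' [sim_config()]).  Covariates are sampled from distributions spanning the
#' stratification thresholds: sample sizes uniform over the configured range,
#' PTS uniform on \{2,...,5\}, PTE adversity ratio uniform on (0.05, 0.6),
#' years since conflict uniform on (0, 10), and binary design covariates
#' Bernoulli(0.5).  Boundary counts (`cases = 0` or `cases = n`) are retained
#' as drawn; continuity correction is the meta-regression's responsibility.
#'
#' @param config a [sim_config()] object.
#' @return A study table (see [study_table_columns()]) with two extra columns
#'   recording the simulation truth for oracle tests: `true_logit` (the
#'   linear predictor plus random effect) and `true_p`.
#' @export
generate_study_table <- function(config) {
  if (!inherits(config, "SimConfig")) stopf("config must be created by sim_config()")
  k <- config$n_studies
  empty <- data.frame(
    study_id = character(), outcome = character(), cases = integer(),
    n = integer(), measure_type = character(), sampling = character(),
    pts = integer(), pte_endorsed = numeric(), pte_assessed = integer(),
    years_since_conflict = numeric(), displaced = logical(),
    true_logit = numeric(), true_p = numeric(), stringsAsFactors = FALSE
  )
  if (k == 0L) return(empty)
  with_seed(config$seed, {
    rng <- config$sample_size_range
    # avoid sample()'s scalar expansion when the range collapses to one value
    n <- rng[1] + sample.int(rng[2] - rng[1] + 1L, k, replace = TRUE) - 1L
    pts <- sample(2:5, k, replace = TRUE)
    pte_assessed <- sample(10:30, k, replace = TRUE)
    ratio <- stats::runif(k, 0.05, 0.6)
    years <- stats::runif(k, 0, 10)
    displaced <- stats::runif(k) < 0.5
    self_report <- stats::runif(k) < 0.5
    nonrandom <- stats::runif(k) < 0.5
    x <- cbind(
      intercept = rep(1, k), pts = pts, pte_ratio = ratio,
      years_since_conflict = years, displaced = as.numeric(displaced),
      self_report = as.numeric(self_report), nonrandom = as.numeric(nonrandom),
      high_terror = as.numeric(pts >= 4), high_trauma = as.numeric(ratio >= 0.3)
    )
    eta <- drop(x[, names(config$beta), drop = FALSE] %*% config$beta)
    u <- if (config$tau2 > 0) stats::rnorm(k, 0, sqrt(config$tau2)) else numeric(k)
    true_logit <- eta + u
    p <- expit(true_logit)
    cases <- stats::rbinom(k, n, p)
    data.frame(
      study_id = sprintf("S%03d", seq_len(k)),
      outcome = config$outcome,
      cases = cases, n = n,
      measure_type = ifelse(self_report, "self_report", "diagnostic_interview"),
      sampling = ifelse(nonrandom, "nonrandom", "random"),
      pts = pts,
      pte_endorsed = ratio * pte_assessed,
      pte_assessed = pte_assessed,
      years_since_conflict = years,
      displaced = displaced,
      true_logit = true_logit, true_p = p,
      stringsAsFactors = FALSE
    )
  })
}

#' Validate a study table
#'
#' Checks schema and row-level invariants (`0 <= cases <= n`,
#' `pte_endorsed <= pte_assessed`, `pts` in 1..5, recognised factor levels).
#' Errors name the offending row and field.
#'
#' @param records a study-table `data.frame`.
#' @return `records`, invisibly, if valid.
#' @export
validate_study_table <- function(records) {
  missing_cols <- setdiff(study_table_columns(), names(records))
  if (length(missing_cols))
    stopf("study table is missing column(s): %s", paste(missing_cols, collapse = ", "))
  check <- function(bad, field, what) {
    idx <- which(bad)
    if (length(idx))
      stopf("row %d, field '%s': %s", idx[1], field, what)
  }
  if (nrow(records) == 0L) return(invisible(records))
  check(!records$outcome %in% .outcomes, "outcome",
        sprintf("must be one of %s", paste(.outcomes, collapse = "/")))
  check(!records$measure_type %in% .measures, "measure_type",
        sprintf("must be one of %s", paste(.measures, collapse = "/")))
  check(!records$sampling %in% .samplings, "sampling",
        sprintf("must be one of %s", paste(.samplings, collapse = "/")))
  check(is.na(records$n) | records$n <= 0, "n", "sample size must be positive")
  check(is.na(records$cases) | records$cases < 0 | records$cases > records$n,
        "cases", "must satisfy 0 <= cases <= n")
  check(is.na(records$pts) | records$pts < 1 | records$pts > 5, "pts",
        "must be a rating between 1 and 5")
  check(is.na(records$pte_assessed) | records$pte_assessed <= 0, "pte_assessed",
        "must be positive")
  check(is.na(records$pte_endorsed) | records$pte_endorsed < 0 |
          records$pte_endorsed > records$pte_assessed, "pte_endorsed",
        "must lie in [0, pte_assessed]")
  check(is.na(records$years_since_conflict) | records$years_since_conflict < 0,
        "years_since_conflict", "must be non-negative")
  invisible(records)
}

#' Read / write a study table as CSV
#'
#' UTF-8 CSV with the exact header given by [study_table_columns()]; missing
#' values are empty strings.  Reading validates every row; writing drops any
#' extra columns (such as the generator's `true_logit`).
#'
#' @param path file path.
#' @param records a valid study table.
#' @return `read_study_table()` returns the validated `data.frame`;
#'   `write_study_table()` returns `path` invisibly.
#' @export
read_study_table <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(study_id = "character"),
                             na.strings = "", fileEncoding = "UTF-8")
  missing_cols <- setdiff(study_table_columns(), names(records))
  if (length(missing_cols))
    stopf("'%s' is missing column(s): %s", path, paste(missing_cols, collapse = ", "))
  records <- records[, study_table_columns()]
  records$displaced <- as.logical(records$displaced)
  validate_study_table(records)
  records
}

#' @rdname read_study_table
#' @export
write_study_table <- function(records, path) {
  validate_study_table(records)
  utils::write.csv(records[, study_table_columns()], path,
                   row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
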
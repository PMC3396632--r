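#' Published stratified prevalence estimates
#'
#' The back-transformed total-case prevalence estimates (percent, with 95%
#' CI) of the published meta-regression, stratified by trauma exposure, for
#' the acute high-political-terror phase and the three-years-post-conflict
#' horizon.  These are the injectable inputs that let the projection stages
#' run without the original 117-survey dataset.
#'
#' @param horizon `"acute"` or `"three_year"`.
#' @param path optional alternative JSON file of the same shape.
#' @return `data.frame`: `disorder`, `trauma`, `prevalence`, `ci_low`,
#'   `ci_high` (percent scale).
#' @export
published_prevalence_estimates <- function(horizon = c("acute", "three_year"),
                                           path = NULL) {
  horizon <- match.arg(horizon)
  path <- path %||% system.file("extdata", "stratum_estimates.json",
                                package = "conflictmh", mustWork = TRUE)
  est <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  est[est$horizon == horizon,
      c("disorder", "trauma", "prevalence", "ci_low", "ci_high")]
}

# Severe prevalence table (percent, 1 dp) for one horizon from total
# prevalences and severity proportions.
.severe_table <- function(total, severity) {
  out <- total
  for (i in seq_len(nrow(out))) {
    s <- if (out$disorder[i] == "PTSD") severity$ptsd$prop else severity$depression$prop
    out[i, c("prevalence", "ci_low", "ci_high")] <-
      severe_prevalence(out[i, ], s, percent = TRUE)
  }
  out
}

# Per-group projections + totals for one disorder, matching each group's
# trauma stratum to the severe prevalence row.
.project_disorder <- function(groups, severe, disorder, rounding_unit) {
  rows <- severe[severe$disorder == disorder, ]
  idx <- match(groups$trauma_stratum, rows$trauma)
  if (anyNA(idx)) stopf("no severe prevalence for stratum of every group")
  proj <- project_cases(groups, rows[idx, c("prevalence", "ci_low", "ci_high")],
                        disorder = disorder, rounding_unit = rounding_unit,
                        percent = TRUE)
  cbind(proj,
        prevalence = rows$prevalence[idx],
        ci_low_pct = rows$ci_low[idx],
        ci_high_pct = rows$ci_high[idx],
        size = groups$size)
}

#' Run the projection pipeline end to end
#'
#' Chains the stages: stratified total prevalence -> severe-case prevalence
#' -> per-population case projections and totals -> comorbidity planning
#' groups -> service use -> FTE staffing and workforce gap.
#'
#' Two explicit modes:
#' \describe{
#'   \item{`paper_reproduction`}{Uses the shipped published stratum
#'     prevalences (see [published_prevalence_estimates()]), percent values
#'     rounded to one decimal, and the published depression-only planning
#'     count (43,300) as the comorbidity override.}
#'   \item{`model_driven`}{Fits the meta-regression to a supplied (or
#'     simulated) study table, predicts stratum prevalences at full
#'     precision, and derives the depression-only group by subtraction.}
#' }
#'
#' @param mode `"paper_reproduction"` or `"model_driven"`.
#' @param populations population registry `data.frame`
#'   ([libya_populations()] by default).
#' @param severity severity/comorbidity constants ([severity_defaults()]).
#' @param service service-model configuration ([service_config()]).
#' @param horizon prevalence horizon, `"acute"` or `"three_year"`.
#' @param study_tables named list (`PTSD`, `depression`) of study tables for
#'   `model_driven` mode; if `NULL`, tables are simulated from `sim_ptsd` /
#'   `sim_depression`.
#' @param sim_ptsd,sim_depression [sim_config()] objects used when simulating
#'   in `model_driven` mode.
#' @param depression_only_override depression-only planning count injected in
#'   `paper_reproduction` mode (default 43,300, the published figure).
#' @param rounding_unit case-count rounding unit (100, the planning-table
#'   convention).
#' @param seed integer seed governing all randomness in the run.
#' @param out_dir optional directory; when given, every table is written as
#'   CSV along with a JSON provenance block, deterministically for a given
#'   config.
#' @return A `RunReport` list: `prevalence` (total + severe, percent),
#'   `projections` (per group, both disorders), `totals`, `comorbidity`,
#'   `treatment_targets`, `service_use`, `staffing`, `workforce`,
#'   `provenance`, plus `models` in `model_driven` mode.
#' @export
run_pipeline <- function(mode = c("paper_reproduction", "model_driven"),
                         populations = libya_populations(),
                         severity = severity_defaults(),
                         service = service_config(),
                         horizon = "acute",
                         study_tables = NULL,
                         sim_ptsd = NULL, sim_depression = NULL,
                         depression_only_override = 43300,
                         rounding_unit = 100,
                         seed = NULL,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  stage <- "prevalence"
  report <- tryCatch({
    models <- NULL
    if (mode == "paper_reproduction") {
      total <- published_prevalence_estimates(horizon)
    } else {
      if (is.null(study_tables)) {
        sim_ptsd <- sim_ptsd %||% sim_config(
          200, beta = c(intercept = -1.0, high_trauma = 0.8), tau2 = 0.3,
          outcome = "PTSD", seed = if (!is.null(seed)) seed + 1L else NULL)
        sim_depression <- sim_depression %||% sim_config(
          200, beta = c(intercept = -0.8, high_trauma = 0.4), tau2 = 0.3,
          outcome = "depression", seed = if (!is.null(seed)) seed + 2L else NULL)
        study_tables <- list(PTSD = generate_study_table(sim_ptsd),
                             depression = generate_study_table(sim_depression))
      }
      fit_one <- function(tab) {
        obs <- cbind(logit_with_variance(tab$cases, tab$n),
                     high_trauma = as.numeric(
                       stratify_exposure(tab$pts,
                                         pte_adversity_ratio(tab$pte_endorsed,
                                                             tab$pte_assessed))$trauma == "high"))
        fit_prevalence_model(obs, covariates = "high_trauma", method = "REML")
      }
      models <- lapply(study_tables, fit_one)
      pred <- function(m, trauma)
        predict_stratum(m, list(high_trauma = as.numeric(trauma == "high")))
      total <- do.call(rbind, lapply(names(models), function(d) {
        do.call(rbind, lapply(c("moderate", "high"), function(tr) {
          p <- pred(models[[d]], tr)
          data.frame(disorder = d, trauma = tr,
                     prevalence = 100 * p$prevalence,
                     ci_low = 100 * p$ci_low, ci_high = 100 * p$ci_high)
        }))
      }))
    }

    stage <- "severity"
    severe <- .severe_table(total, severity)

    stage <- "projection"
    proj <- rbind(.project_disorder(populations, severe, "PTSD", rounding_unit),
                  .project_disorder(populations, severe, "depression", rounding_unit))
    totals <- rbind(
      aggregate_projections(proj[proj$disorder == "PTSD", ]),
      aggregate_projections(proj[proj$disorder == "depression", ]))

    stage <- "comorbidity"
    split <- comorbidity_split(
      totals$cases[totals$disorder == "PTSD"],
      totals$cases[totals$disorder == "depression"],
      phi = severity$phi,
      depression_only_override =
        if (mode == "paper_reproduction") depression_only_override else NULL)

    stage <- "services"
    use <- service_use_table(split, service$coverage_targets)
    treat <- vapply(c("depression_only", "ptsd_only", "comorbid"), function(g)
      round_half_up(split[[g]] * service$overall_coverage[[g]], 1000), numeric(1))

    stage <- "staffing"
    # per-population staffing: each population's severe cases split by phi
    per_pop <- lapply(seq_len(nrow(populations)), function(i) {
      ptsd_i <- proj$cases[proj$disorder == "PTSD"][i]
      dep_i <- proj$cases[proj$disorder == "depression"][i]
      sp <- comorbidity_split(ptsd_i, dep_i, phi = severity$phi)
      staffing_requirement(sp, service)
    })
    staff_tab <- data.frame(
      population = populations$name, size = populations$size,
      do.call(rbind, lapply(per_pop, function(s) as.data.frame(as.list(s$staff)))),
      total_fte = vapply(per_pop, function(s) round_half_up(s$total_fte), numeric(1)))
    combined <- staffing_requirement(split, service)

    stage <- "workforce"
    gap <- workforce_gap(combined$staff, unlist(service$workforce_rates),
                         sum(populations$size))

    list(mode = mode, horizon = horizon,
         prevalence = list(total = total, severe = severe),
         projections = proj, totals = totals,
         comorbidity = split, treatment_targets = as.list(treat),
         service_use = use,
         staffing = list(per_population = staff_tab, combined = combined),
         workforce = gap, models = models)
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })

  report$provenance <- .provenance(mode, horizon, seed, populations, severity,
                                   service, rounding_unit)
  class(report) <- "RunReport"
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

.provenance <- function(mode, horizon, seed, populations, severity, service,
                        rounding_unit) {
  cfg <- list(mode = mode, horizon = horizon, seed = seed,
              populations = populations, severity = severity,
              service = list(coverage_targets = service$coverage_targets,
                             overall_coverage = service$overall_coverage,
                             service_parameters = service$service_parameters,
                             workforce_rates = service$workforce_rates),
              rounding_unit = rounding_unit)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  list(package = "conflictmh",
       version = as.character(utils::packageVersion("conflictmh")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       mode = mode, horizon = horizon, seed = seed,
       config_hash = unname(tools::md5sum(tmp)))
}

#' Write a run report to disk
#'
#' Emits one CSV per table plus `provenance.json`; outputs are byte-identical
#' across runs with the same configuration.
#'
#' @param report a `RunReport` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  stopifnot(inherits(report, "RunReport"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(report$prevalence$total, "prevalence_total.csv")
  w(report$prevalence$severe, "prevalence_severe.csv")
  w(report$projections, "case_projections.csv")
  w(report$totals, "case_totals.csv")
  w(as.data.frame(report$comorbidity), "comorbidity_groups.csv")
  w(report$service_use, "service_use.csv")
  w(report$staffing$per_population, "staffing_by_population.csv")
  w(report$workforce, "workforce_gap.csv")
  jsonlite::write_json(report$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.RunReport <- function(x, ...) {
  cat(sprintf("Post-conflict mental health projection run (%s mode, %s horizon)\n",
              x$mode, x$horizon))
  cat("\nSevere-case prevalence (%, 95% CI):\n")
  print(x$prevalence$severe, row.names = FALSE)
  cat("\nProjected severe cases (totals):\n")
  print(x$totals, row.names = FALSE)
  cat(sprintf("\nPlanning groups: %s comorbid, %s PTSD-only, %s depression-only\n",
              format(x$comorbidity$comorbid, big.mark = ","),
              format(x$comorbidity$ptsd_only, big.mark = ","),
              format(x$comorbidity$depression_only, big.mark = ",")))
  cat("\nWorkforce gap (FTE):\n")
  print(x$workforce, row.names = FALSE)
  invisible(x)
}
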
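#' Shipped service-model configuration
#'
#' Reads the JSON service configuration: per-group service-coverage targets,
#' service parameters (11 consultations per clinician-day, 225 working days a
#' year, visit rates, inpatient bed-day targets and staff:bed ratios), the
#' staff apportionment matrix, overall coverage targets and WHO per-100,000
#' workforce availability rates.
#'
#' Coverage targets ship as published for severe depression (adapted from the
#' mhGAP scale-up costing model) and its PTSD/comorbid extensions:
#' PTSD-only cases are managed entirely in primary care and psychosocial
#' services.  Visit rates, bed-day targets, staff:bed ratios and the
#' apportionment matrix are not published alongside the coverage targets;
#' they ship as documented placeholder values and should be replaced with
#' setting-specific planning figures where available.
#'
#' @param path optional alternative JSON config of the same shape.
#' @return Nested list with elements `coverage_targets`, `overall_coverage`,
#'   `service_parameters`, `apportionment`, `workforce_rates`.
#' @export
service_config <- function(path = NULL) {
  path <- path %||% system.file("extdata", "service_config.json",
                                package = "conflictmh", mustWork = TRUE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  apn <- cfg$apportionment
  if (!is.null(apn)) {
    m <- as.matrix(as.data.frame(apn[setdiff(names(apn), "service")]))
    rownames(m) <- apn$service
    if (any(abs(rowSums(m) - 1) > 1e-9))
      stopf("apportionment rows must each sum to 1")
    cfg$apportionment <- m
  }
  cfg
}

.services <- c("long_stay", "acute_inpatient", "day_care",
               "outpatient", "primary_care", "psychosocial")
.staff_categories <- c("medical", "nurse", "psychosocial")

#' Patients accessing a service over one year
#'
#' @param group_size number of severe cases in a planning group.
#' @param coverage service-coverage target: the fraction of the group
#'   expected to use the service over one year.
#' @return `round_half_up(group_size * coverage)`; vectorised.
#' @examples
#' patients_accessing(43300, 0.005)  # 217 long-stay depression patients
#' @export
patients_accessing <- function(group_size, coverage) {
  stopifnot(all(group_size >= 0), all(coverage >= 0), all(coverage <= 1))
  round_half_up(group_size * coverage)
}

#' Visits per average case
#'
#' The expected number of visits a service contributes per average case in a
#' group: the fraction of cases using the service times the average number of
#' visits of a service user (e.g. 1% day-care use x 50 visits = 0.5 day-care
#' visits per average depression case).
#'
#' @param pct_use fraction of cases using the service.
#' @param avg_use average annual visits per service user.
#' @return The product; vectorised.
#' @export
visits_per_case <- function(pct_use, avg_use) {
  stopifnot(all(pct_use >= 0), all(avg_use >= 0))
  pct_use * avg_use
}

#' Full-time-equivalent staff for ambulatory services
#'
#' Clinician FTE needed to deliver ambulatory care (primary healthcare,
#' outpatient, day-care, psychosocial visits):
#' `FTE = (population x prevalence x severity x coverage x visits per case) /
#' (consultations_per_day x working_days)`.
#'
#' `fte_from_visits()` is the algebraically equivalent entry point starting
#' from an annual visit total (patient count x average visits).
#'
#' @param population population size.
#' @param prevalence disorder prevalence (proportion of the population).
#' @param severity proportion of cases that are severe.
#' @param coverage proportion of severe cases reached by services.
#' @param visits visits per average (covered severe) case.
#' @param consultations_per_day consultations a clinician delivers per day.
#' @param working_days working days per year.
#' @return FTE (real, unrounded).
#' @examples
#' fte_ambulatory(100000, 0.10, 0.50, 0.33, 8)  # 5.333...
#' @export
fte_ambulatory <- function(population, prevalence, severity, coverage, visits,
                           consultations_per_day = 11, working_days = 225) {
  stopifnot(population >= 0, prevalence >= 0, severity >= 0, coverage >= 0,
            visits >= 0)
  denom <- consultations_per_day * working_days
  if (denom <= 0) stopf("consultations_per_day x working_days must be positive")
  population * prevalence * severity * coverage * visits / denom
}

#' @rdname fte_ambulatory
#' @param annual_visits total visits delivered over a year.
#' @export
fte_from_visits <- function(annual_visits, consultations_per_day = 11,
                            working_days = 225) {
  stopifnot(all(annual_visits >= 0))
  denom <- consultations_per_day * working_days
  if (denom <= 0) stopf("consultations_per_day x working_days must be positive")
  annual_visits / denom
}

#' Full-time-equivalent staff for inpatient services
#'
#' Inpatient staffing is driven by targeted beds: FTE = staff:bed ratio x
#' targeted beds.
#'
#' @param target_beds targeted number of inpatient beds.
#' @param staff_bed_ratio staff per bed (LMIC literature values supplied via
#'   configuration).
#' @return FTE; vectorised.
#' @export
fte_inpatient <- function(target_beds, staff_bed_ratio) {
  stopifnot(all(target_beds >= 0), all(staff_bed_ratio >= 0))
  target_beds * staff_bed_ratio
}

#' Apportion service FTE across staff categories
#'
#' Distributes each service's FTE across medical, nurse and psychosocial
#' staff via an apportionment matrix whose rows sum to one, then rounds the
#' per-category totals half-up to integers.
#'
#' @param fte_by_service named numeric vector of FTE per service.
#' @param apportionment matrix with one row per service (row names matching
#'   `names(fte_by_service)`) and one column per staff category.
#' @param round whether to round category totals to integers.
#' @return Named numeric vector of FTE per staff category.
#' @export
apportion_staff <- function(fte_by_service, apportionment, round = TRUE) {
  if (is.null(names(fte_by_service)) || is.null(rownames(apportionment)))
    stopf("fte_by_service and apportionment rows must be named")
  missing_rows <- setdiff(names(fte_by_service), rownames(apportionment))
  if (length(missing_rows))
    stopf("apportionment matrix lacks row(s): %s", paste(missing_rows, collapse = ", "))
  if (any(abs(rowSums(apportionment) - 1) > 1e-9))
    stopf("apportionment rows must each sum to 1")
  A <- apportionment[names(fte_by_service), , drop = FALSE]
  totals <- drop(fte_by_service %*% A)
  if (round) round_half_up(totals) else totals
}

#' Workforce availability and shortfall
#'
#' Converts WHO per-100,000 staffing rates into the number of staff available
#' for a population and compares them with required FTE.
#'
#' @param required named numeric vector of required FTE per staff category.
#' @param rates named numeric vector of available staff per 100,000
#'   population (defaults: 0.18 medical, 0.5 psychiatric nurses, 6.5
#'   psychosocial providers).
#' @param population population served.
#' @return `data.frame` with `category`, `required`, `available`,
#'   `shortfall` (`max(0, required - available)`).
#' @export
workforce_gap <- function(required,
                          rates = c(medical = 0.18, nurse = 0.5, psychosocial = 6.5),
                          population) {
  stopifnot(all(rates >= 0), population >= 0)
  cats <- names(required)
  missing_rates <- setdiff(cats, names(rates))
  if (length(missing_rates))
    stopf("no availability rate for category(ies): %s", paste(missing_rates, collapse = ", "))
  available <- round_half_up(rates[cats] * population / 1e5)
  data.frame(category = cats,
             required = as.numeric(required),
             available = as.numeric(available),
             shortfall = pmax(0, as.numeric(required) - as.numeric(available)),
             stringsAsFactors = FALSE)
}

#' Patients-accessing-services table
#'
#' Crosses the three planning groups (depression-only, PTSD-only, comorbid)
#' with the six service types, giving coverage targets and the number of
#' patients accessing each service over one year.
#'
#' @param group_sizes list/vector with `depression_only`, `ptsd_only`,
#'   `comorbid` counts.
#' @param coverage_targets `data.frame` with columns `service`,
#'   `depression_only`, `ptsd_only`, `comorbid` holding coverage proportions
#'   (as in [service_config()]).
#' @return `data.frame` with one row per service: coverage and patient counts
#'   per group.
#' @export
service_use_table <- function(group_sizes, coverage_targets) {
  req <- c("service", "depression_only", "ptsd_only", "comorbid")
  stopifnot(all(req %in% names(coverage_targets)),
            all(c("depression_only", "ptsd_only", "comorbid") %in% names(group_sizes)))
  out <- coverage_targets[, req]
  for (g in c("depression_only", "ptsd_only", "comorbid")) {
    out[[paste0("patients_", g)]] <-
      patients_accessing(group_sizes[[g]], coverage_targets[[g]])
  }
  out
}

#' Staffing requirement for one population group
#'
#' Runs the full FTE algorithm for one population: patients per service from
#' severe-case counts and coverage targets, ambulatory FTE from annual visit
#' loads, inpatient FTE from targeted beds (patients x bed-days / 365 x
#' staff:bed ratio), apportioned across staff categories.
#'
#' @param severe_cases list/vector with severe `depression_only`,
#'   `ptsd_only`, `comorbid` counts for the population.
#' @param config a [service_config()] list.
#' @return A list: `fte_by_service` (unrounded), `staff` (rounded FTE per
#'   category), `total_fte` (unrounded grand total).
#' @export
staffing_requirement <- function(severe_cases, config = service_config()) {
  cov <- config$coverage_targets
  pars <- config$service_parameters
  groups <- c("depression_only", "ptsd_only", "comorbid")
  fte <- stats::setNames(numeric(length(cov$service)), cov$service)
  for (i in seq_along(cov$service)) {
    svc <- cov$service[i]
    patients <- sum(vapply(groups, function(g)
      patients_accessing(severe_cases[[g]], cov[[g]][i]), numeric(1)))
    if (svc %in% c("long_stay", "acute_inpatient")) {
      beds <- patients * pars$bed_days[[svc]] / 365
      fte[svc] <- fte_inpatient(beds, pars$staff_bed_ratio[[svc]])
    } else {
      fte[svc] <- fte_from_visits(patients * pars$avg_visits[[svc]],
                                  pars$consultations_per_day, pars$working_days)
    }
  }
  staff <- apportion_staff(fte, config$apportionment)
  list(fte_by_service = fte, staff = staff, total_fte = sum(fte))
}
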
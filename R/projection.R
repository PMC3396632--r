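#' Population registry
#'
#' Reads a JSON registry of population groups (name, size, trauma and terror
#' stratum).  [libya_populations()] returns the shipped registry of the six
#' conflict-affected Libyan groups (combined population 1,236,606): Misrata
#' and Benghazi in the moderate-trauma stratum, and the four
#' high-intensity-conflict groups (Tripoli/Zlitan displaced, Misrata
#' displaced, Zintan, Ras Jdir camps) in the high-trauma stratum.
#'
#' @param path JSON file with fields `name`, `size`, `trauma_stratum`,
#'   `terror_stratum` per group.
#' @return A `data.frame` with those columns.
#' @export
read_population_registry <- function(path) {
  reg <- jsonlite::read_json(path, simplifyVector = TRUE)
  req <- c("name", "size", "trauma_stratum", "terror_stratum")
  missing_cols <- setdiff(req, names(reg))
  if (length(missing_cols))
    stopf("population registry is missing field(s): %s", paste(missing_cols, collapse = ", "))
  if (any(reg$size <= 0)) stopf("population sizes must be positive")
  if (any(!reg$trauma_stratum %in% c("moderate", "high")) ||
      any(!reg$terror_stratum %in% c("moderate", "high")))
    stopf("strata must be 'moderate' or 'high'")
  as.data.frame(reg, stringsAsFactors = FALSE)
}

#' @rdname read_population_registry
#' @export
libya_populations <- function() {
  read_population_registry(system.file("extdata", "libya_populations.json",
                                       package = "conflictmh", mustWork = TRUE))
}

#' Project severe cases onto a population group
#'
#' Multiplies group size by the severe-case prevalence (point and both
#' confidence bounds) and rounds each value half-up to the nearest
#' `rounding_unit` (100 by default, the convention of the published planning
#' tables; `rounding_unit = 1` recovers exact products).
#'
#' @param groups `data.frame` with at least `name` and `size` (see
#'   [libya_populations()]); one row per group.
#' @param severe one-row `data.frame` per distinct prevalence, with
#'   `prevalence`, `ci_low`, `ci_high` as proportions — or percent values if
#'   `percent = TRUE`.  Either a single row applied to all groups, or
#'   `nrow(groups)` rows matched positionally.
#' @param disorder label attached to the projection.
#' @param rounding_unit counts are rounded half-up to this unit.
#' @param percent whether `severe` is on the percent scale.
#' @return A `data.frame`: `group`, `disorder`, `cases`, `ci_low`, `ci_high`.
#' @export
project_cases <- function(groups, severe, disorder = "PTSD",
                          rounding_unit = 100, percent = FALSE) {
  stopifnot(all(c("name", "size") %in% names(groups)),
            all(c("prevalence", "ci_low", "ci_high") %in% names(severe)))
  if (!nrow(severe) %in% c(1L, nrow(groups)))
    stopf("severe must have 1 row or one row per group")
  if (nrow(severe) == 1L) severe <- severe[rep(1L, nrow(groups)), , drop = FALSE]
  scale <- if (percent) 1 / 100 else 1
  data.frame(
    group = groups$name,
    disorder = disorder,
    cases = round_half_up(groups$size * severe$prevalence * scale, rounding_unit),
    ci_low = round_half_up(groups$size * severe$ci_low * scale, rounding_unit),
    ci_high = round_half_up(groups$size * severe$ci_high * scale, rounding_unit),
    stringsAsFactors = FALSE
  )
}

#' Total cases across groups
#'
#' Sums already-rounded per-group projections (point and each bound
#' separately) — the "sum of rounded" convention used by the planning tables.
#' All projections must refer to one disorder.
#'
#' @param projections output of [project_cases()].
#' @return One-row `data.frame`: `disorder`, `cases`, `ci_low`, `ci_high`.
#' @export
aggregate_projections <- function(projections) {
  if (nrow(projections) == 0L)
    return(data.frame(disorder = NA_character_, cases = 0, ci_low = 0, ci_high = 0,
                      stringsAsFactors = FALSE))
  disorders <- unique(projections$disorder)
  if (length(disorders) > 1L)
    stopf("cannot aggregate projections for mixed disorders: %s",
          paste(disorders, collapse = ", "))
  data.frame(disorder = disorders,
             cases = sum(projections$cases),
             ci_low = sum(projections$ci_low),
             ci_high = sum(projections$ci_high),
             stringsAsFactors = FALSE)
}
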
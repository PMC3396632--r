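#' Round half up
#'
#' Rounds to the nearest multiple of `unit`, with exact halves rounded away
#' from zero towards the larger value (so 216.5 becomes 217, and 4,950 rounds
#' to 5,000 at `unit = 100`).  This differs from [base::round()], which rounds
#' halves to even.  All count and percentage rounding in the package goes
#' through this function so that every table uses one convention.
#'
#' @param x numeric vector.
#' @param unit positive rounding unit (1 for integers, 100 for counts rounded
#'   to the nearest hundred, 0.1 for one-decimal percentages).
#' @return `x` rounded to the nearest multiple of `unit`.
#' @examples
#' round_half_up(216.5)        # 217
#' round_half_up(4950, 100)    # 5000
#' round_half_up(12.39, 0.1)   # 12.4
#' @export
round_half_up <- function(x, unit = 1) {
  stopifnot(is.numeric(x), is.numeric(unit), length(unit) == 1L, unit > 0)
  # divide first, then add 0.5: keeps the convention exact for half-multiples;
  # the sqrt(eps) guard stops binary representation error (4.05 stored as
  # 4.04999...) from flipping a true half downwards
  out <- floor(x / unit + 0.5 + sqrt(.Machine$double.eps)) * unit
  # guard against 0.1-style binary representation drift (e.g. 12.4 vs 12.400000000000001)
  if (unit < 1) out <- round(out, max(0L, ceiling(-log10(unit)) + 1L))
  out
}

#' @rdname round_half_up
#' @details `percent_1dp()` is a convenience wrapper converting a proportion to
#'   a percentage rounded half-up to one decimal, the form in which stratum
#'   prevalences are reported.
#' @export
percent_1dp <- function(x) round_half_up(100 * x, 0.1)

# logit / inverse-logit on the proportion scale
logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Critical value for a two-sided interval. The conventional z = 1.96 is used
# at the default 95% level (the level at which published intervals were
# back-calculated); other levels use the exact normal quantile.
z_crit <- function(level) {
  if (isTRUE(all.equal(level, 0.95))) 1.96
  else stats::qnorm(1 - (1 - level) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
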
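#' Logit prevalence and delta-method variance
#'
#' Transforms a survey's case count into a logit prevalence with the
#' delta-method within-study variance `1/cases + 1/non-cases`.  Boundary
#' counts (`cases = 0` or `cases = n`) receive a continuity correction of
#' +0.5 cases on a sample inflated by 1 before transformation, so every
#' survey yields a finite logit and variance.
#'
#' @param cases number of cases (0 to `n`); vectorised.
#' @param n sample size (positive); vectorised.
#' @return A `data.frame` with columns `y` (logit prevalence) and `v`
#'   (within-study variance).
#' @examples
#' logit_with_variance(50, 100)   # y = 0, v = 0.04
#' @export
logit_with_variance <- function(cases, n) {
  if (any(!is.finite(n)) || any(n <= 0)) stopf("n must be positive")
  if (any(cases < 0) || any(cases > n)) stopf("cases must satisfy 0 <= cases <= n")
  boundary <- cases == 0 | cases == n
  c_adj <- ifelse(boundary, cases + 0.5, cases)
  n_adj <- ifelse(boundary, n + 1, n)
  non <- n_adj - c_adj
  data.frame(y = log(c_adj / non), v = 1 / c_adj + 1 / non)
}

# -- internal helpers ---------------------------------------------------------

# Weighted least squares at a given tau2. Returns beta, covariance and the
# weighted residual sum of squares.
.wls <- function(y, X, v, tau2) {
  w <- 1 / (v + tau2)
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  xx_inv <- solve(XtWX)
  beta <- drop(xx_inv %*% (XtW %*% y))
  r <- y - drop(X %*% beta)
  list(beta = beta, cov = xx_inv, rss = sum(w * r^2), XtWX = XtWX, resid = r)
}

# Restricted log-likelihood of tau2 (additive constants dropped)
.reml_ll <- function(tau2, y, X, v) {
  w <- 1 / (v + tau2)
  fit <- .wls(y, X, v, tau2)
  -0.5 * (sum(log(v + tau2)) + determinant(fit$XtWX, logarithm = TRUE)$modulus[1] + fit$rss)
}

# Extended DerSimonian-Laird moment estimator of tau2 for a meta-regression
# design; reduces to classic DL for an intercept-only model.
.tau2_moment <- function(y, X, v) {
  k <- length(y); p <- ncol(X)
  w <- 1 / v
  fit0 <- .wls(y, X, v, 0)
  q_e <- fit0$rss
  # trace of P = W - W X (X'WX)^-1 X'W
  xx_inv <- solve(t(X * w) %*% X)
  tr_p <- sum(w) - sum(diag(xx_inv %*% (t(X * w^2) %*% X)))
  max(0, (q_e - (k - p)) / tr_p)
}

.design_matrix <- function(observations, covariates) {
  k <- nrow(observations)
  X <- matrix(1, nrow = k, ncol = 1, dimnames = list(NULL, "intercept"))
  if (length(covariates)) {
    missing_cov <- setdiff(covariates, names(observations))
    if (length(missing_cov))
      stopf("covariate(s) not found in observations: %s", paste(missing_cov, collapse = ", "))
    Xc <- as.matrix(as.data.frame(lapply(observations[covariates], as.numeric)))
    colnames(Xc) <- covariates
    X <- cbind(X, Xc)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stopf("design matrix is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  X
}

#' Fit a random-effects logit meta-regression
#'
#' Fits the mixed model `y_i ~ N(x_i' beta, v_i + tau2)` to logit-prevalence
#' observations, where `v_i` is the known delta-method within-study variance
#' and `tau2` is the between-study (random-effect) variance.  Two estimators
#' of `tau2` are provided: restricted maximum likelihood (the default,
#' profiled over `tau2` to the stated tolerance) and the extended
#' DerSimonian-Laird moment estimator followed by weighted least squares.
#'
#' @param observations a `data.frame` with columns `y` (logit prevalence) and
#'   `v` (within-study variance, positive), plus any covariate columns.
#'   Typically built by [logit_with_variance()] column-bound to the study
#'   table.
#' @param covariates character vector of covariate column names entering the
#'   fixed-effects design (an intercept is always included; binary and factor
#'   covariates must already be coded numerically).
#' @param method `"REML"` or `"moment"`.
#' @param tau2_fixed optional non-negative value at which `tau2` is held fixed
#'   (e.g. 0 to reproduce the fixed-effect weighted-least-squares fit).
#' @param tol convergence tolerance on the restricted log-likelihood.
#' @return An object of class `prev_meta`: a list with `beta` (named
#'   coefficients on the logit scale), `beta_cov` (their covariance matrix),
#'   `tau2`, `method`, `n_studies`, `covariates` and `tau2_fixed`.
#' @export
fit_prevalence_model <- function(observations, covariates = character(),
                                 method = c("REML", "moment"),
                                 tau2_fixed = NULL, tol = 1e-8) {
  method <- match.arg(method)
  if (!all(c("y", "v") %in% names(observations)))
    stopf("observations must contain columns 'y' and 'v'")
  y <- as.numeric(observations$y)
  v <- as.numeric(observations$v)
  if (any(!is.finite(y)) || any(!is.finite(v)) || any(v <= 0))
    stopf("each observation needs a finite y and a positive variance v")
  X <- .design_matrix(observations, covariates)
  k <- length(y); p <- ncol(X)
  if (k < p + 1L)
    stopf("need at least %d observations to fit %d coefficients", p + 1L, p)

  if (!is.null(tau2_fixed)) {
    if (tau2_fixed < 0) stopf("tau2_fixed must be non-negative")
    tau2 <- tau2_fixed
  } else if (method == "moment") {
    tau2 <- .tau2_moment(y, X, v)
  } else {
    upper <- max(10 * stats::var(y), 1e-3)
    opt <- stats::optimize(.reml_ll, interval = c(0, upper), y = y, X = X, v = v,
                           maximum = TRUE, tol = tol)
    tau2 <- opt$maximum
    # optimize never returns an exact endpoint; snap to zero when the
    # likelihood prefers the boundary
    if (.reml_ll(0, y, X, v) >= opt$objective) tau2 <- 0
    tau2 <- max(0, tau2)
  }
  fit <- .wls(y, X, v, tau2)
  structure(list(beta = fit$beta, beta_cov = fit$cov, tau2 = tau2,
                 method = method, n_studies = k, covariates = covariates,
                 tau2_fixed = tau2_fixed),
            class = "prev_meta")
}

#' @export
print.prev_meta <- function(x, ...) {
  cat(sprintf("Random-effects logit meta-regression (%s), k = %d studies\n",
              x$method, x$n_studies))
  cat(sprintf("tau^2 (between-study variance): %.4f\n", x$tau2))
  se <- sqrt(diag(x$beta_cov))
  tab <- data.frame(estimate = x$beta, se = se,
                    ci_low = x$beta - 1.96 * se, ci_high = x$beta + 1.96 * se)
  print(round(tab, 4))
  invisible(x)
}

# Build the prediction row for a covariate profile, matching model coding.
.profile_row <- function(model, profile) {
  wanted <- model$covariates
  unknown <- setdiff(names(profile), wanted)
  if (length(unknown))
    stopf("unknown covariate(s) in profile: %s", paste(unknown, collapse = ", "))
  missing_cov <- setdiff(wanted, names(profile))
  if (length(missing_cov))
    stopf("profile must supply covariate(s): %s", paste(missing_cov, collapse = ", "))
  c(intercept = 1, unlist(profile)[wanted])
}

#' Predicted prevalence for a covariate profile
#'
#' Back-transforms the model's linear predictor at a covariate profile into an
#' absolute prevalence with a 95% Wald confidence interval.  The interval
#' reflects uncertainty in the stratum mean only (coefficient covariance; the
#' between-study variance is not added), i.e. it is a confidence interval for
#' the expected prevalence of the stratum, not a prediction interval for a
#' new study.
#'
#' @param model a fitted [fit_prevalence_model()] object.
#' @param profile named list/vector supplying a value for every model
#'   covariate.
#' @param level confidence level (default 0.95, z = 1.96).
#' @return A one-row `data.frame`: `prevalence`, `ci_low`, `ci_high` (all
#'   proportions), plus the logit-scale `eta` and `se`.
#' @export
predict_stratum <- function(model, profile = list(), level = 0.95) {
  stopifnot(inherits(model, "prev_meta"))
  x <- .profile_row(model, profile)
  eta <- sum(x * model$beta)
  se <- sqrt(drop(t(x) %*% model$beta_cov %*% x))
  z <- z_crit(level)
  data.frame(prevalence = expit(eta),
             ci_low = expit(eta - z * se),
             ci_high = expit(eta + z * se),
             eta = eta, se = se)
}

#' Odds ratio between two covariate profiles
#'
#' Exponentiated contrast of the linear predictor between a profile and a
#' reference profile (for example high versus moderate trauma under high
#' political terror), with a Wald confidence interval on the contrast.
#'
#' @inheritParams predict_stratum
#' @param reference named list/vector for the reference profile.
#' @return A one-row `data.frame`: `or`, `ci_low`, `ci_high`.
#' @export
odds_ratio <- function(model, profile, reference, level = 0.95) {
  stopifnot(inherits(model, "prev_meta"))
  d <- .profile_row(model, profile) - .profile_row(model, reference)
  est <- sum(d * model$beta)
  se <- sqrt(drop(t(d) %*% model$beta_cov %*% d))
  z <- z_crit(level)
  data.frame(or = exp(est), ci_low = exp(est - z * se), ci_high = exp(est + z * se))
}

#' Between-study variance explained by covariate blocks
#'
#' Decomposes heterogeneity as in hierarchical meta-regression reporting: the
#' share of the intercept-only between-study variance removed by a baseline
#' (methodological) covariate block, and the additional share removed by the
#' full (substantive) model.
#'
#' @param model_full model with methodological and substantive covariates.
#' @param model_base model with methodological covariates only.
#' @param model_null intercept-only model on the same observations.
#' @return A list with `base_share` = (tau2_null - tau2_base)/tau2_null and
#'   `additive_share` = (tau2_base - tau2_full)/tau2_null, each floored at 0.
#'   If `tau2_null` is 0 the decomposition is undefined; both shares are
#'   returned as 0 with a warning.
#' @export
variance_explained <- function(model_full, model_base, model_null) {
  stopifnot(inherits(model_full, "prev_meta"), inherits(model_base, "prev_meta"),
            inherits(model_null, "prev_meta"))
  if (!(model_full$n_studies == model_base$n_studies &&
        model_base$n_studies == model_null$n_studies))
    stopf("all three models must be fitted to the same observations")
  t_null <- model_null$tau2
  if (t_null <= 0) {
    warning("intercept-only tau2 is zero; variance decomposition undefined, returning 0")
    return(list(base_share = 0, additive_share = 0))
  }
  list(base_share = max(0, (t_null - model_base$tau2) / t_null),
       additive_share = max(0, (model_base$tau2 - model_full$tau2) / t_null))
}

#' Serialise / restore a fitted model as JSON
#'
#' @param model a `prev_meta` object.
#' @param path file path.
#' @return `write_model_json()` returns `path` invisibly; `read_model_json()`
#'   returns the restored `prev_meta` object.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "prev_meta"))
  obj <- list(
    coefficients = as.list(model$beta),
    covariance = unname(apply(model$beta_cov, 1, as.list)),
    coefficient_names = names(model$beta),
    tau2 = model$tau2, method = model$method,
    n_studies = model$n_studies, covariates = as.list(model$covariates)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- unlist(obj$coefficients)
  cov <- matrix(unlist(obj$covariance), nrow = length(beta), byrow = TRUE,
                dimnames = list(obj$coefficient_names, obj$coefficient_names))
  structure(list(beta = beta, beta_cov = cov, tau2 = obj$tau2,
                 method = obj$method, n_studies = obj$n_studies,
                 covariates = as.character(unlist(obj$covariates)),
                 tau2_fixed = NULL),
            class = "prev_meta")
}
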
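# Sampling distributions for probabilistic sensitivity analysis.
#
# Each uncertain model input is summarised as mean (SE) and mapped onto the
# conventional second-order distribution for its measurement scale:
# beta for probabilities and utilities, gamma for costs, log-normal for
# hazard/risk ratios. A zero SE collapses to a degenerate (fixed) point.

#' Distribution specification
#'
#' Container for a parametric sampling distribution used in the PSA.
#' Constructed by [beta_from_moments()], [gamma_from_moments()] and
#' [lognormal_from_point()]; drawn from with [draw_dist()].
#'
#' @param family one of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param ... named shape parameters: `alpha`/`beta` (beta), `shape`/`rate`
#'   (gamma), `mu_log`/`sigma_log` (log-normal) or `point` (fixed).
#' @return an object of class `"dist_spec"`.
#' @export
dist_spec <- function(family = c("beta", "gamma", "lognormal", "fixed"), ...) {
  family <- match.arg(family)
  par <- list(...)
  # mu_log is a location on the log scale and may be any real; the fixed
  # point is range-checked by the parameter table, not here
  constrained <- setdiff(names(par), c("mu_log", "point"))
  if (any(unlist(par[constrained]) <= 0))
    stop("all shape parameters of a '", family, "' distribution must be positive")
  structure(list(family = family, par = par), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(x$family, "(",
      paste(names(x$par), signif(unlist(x$par), 6), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' Beta distribution from mean and standard error
#'
#' Method-of-moments beta fit for a probability or utility parameter:
#' `k = m(1-m)/se^2 - 1`, `alpha = m k`, `beta = (1-m) k`. The fitted
#' distribution reproduces the input mean and SE exactly.
#'
#' @param mean parameter mean, strictly inside (0, 1).
#' @param se standard error on the same scale; `0` yields a fixed point.
#' @param name optional parameter name used in error messages.
#' @return a [dist_spec()].
#' @export
beta_from_moments <- function(mean, se, name = NULL) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("beta mean must lie strictly in (0, 1)", for_param(name))
  if (se < 0) stop("se must be non-negative", for_param(name))
  if (se == 0) return(dist_spec("fixed", point = mean))
  if (se^2 >= mean * (1 - mean))
    stop("infeasible beta moments: se^2 >= mean*(1-mean)", for_param(name))
  k <- mean * (1 - mean) / se^2 - 1
  dist_spec("beta", alpha = mean * k, beta = (1 - mean) * k)
}

#' Gamma distribution from mean and standard error
#'
#' Method-of-moments gamma fit for a non-negative cost parameter:
#' `shape = m^2/se^2`, `rate = m/se^2`.
#'
#' @inheritParams beta_from_moments
#' @param mean parameter mean, strictly positive (PHP).
#' @return a [dist_spec()].
#' @export
gamma_from_moments <- function(mean, se, name = NULL) {
  if (!is.finite(mean) || mean <= 0)
    stop("gamma mean must be positive", for_param(name))
  if (se < 0) stop("se must be non-negative", for_param(name))
  if (se == 0) return(dist_spec("fixed", point = mean))
  dist_spec("gamma", shape = mean^2 / se^2, rate = mean / se^2)
}

#' Log-normal distribution for a hazard or risk ratio
#'
#' The published ratios are reported as point (SE) on the ratio scale.  The
#' default parameterisation sets `mu_log = log(ratio)` and transfers the SE
#' to the log scale by the delta method, `sigma_log = se/ratio`, so that the
#' sampling *median* equals the point estimate.  `method = "moments"` instead
#' matches the arithmetic mean and SD of the draws to the inputs
#' (`sigma_log^2 = log(1 + se^2/ratio^2)`, `mu_log = log(ratio) - sigma_log^2/2`).
#'
#' @param ratio point estimate, strictly positive.
#' @param se standard error on the ratio scale; `0` yields a fixed point.
#' @param method `"median"` (default, delta method) or `"moments"`.
#' @param name optional parameter name used in error messages.
#' @return a [dist_spec()].
#' @export
lognormal_from_point <- function(ratio, se, method = c("median", "moments"),
                                 name = NULL) {
  method <- match.arg(method)
  if (!is.finite(ratio) || ratio <= 0)
    stop("ratio must be positive", for_param(name))
  if (se < 0) stop("se must be non-negative", for_param(name))
  if (se == 0) return(dist_spec("fixed", point = ratio))
  if (method == "median") {
    dist_spec("lognormal", mu_log = log(ratio), sigma_log = se / ratio)
  } else {
    s2 <- log(1 + se^2 / ratio^2)
    dist_spec("lognormal", mu_log = log(ratio) - s2 / 2, sigma_log = sqrt(s2))
  }
}

#' Draw from a distribution specification
#'
#' @param spec a [dist_spec()].
#' @param n number of independent draws.
#' @return numeric vector of length `n`. Uses the current RNG state.
#' @export
draw_dist <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$family,
    fixed     = rep.int(spec$par$point, n),
    beta      = stats::rbeta(n, spec$par$alpha, spec$par$beta),
    gamma     = stats::rgamma(n, shape = spec$par$shape, rate = spec$par$rate),
    lognormal = stats::rlnorm(n, spec$par$mu_log, spec$par$sigma_log))
}

#' Analytic mean and SD of a distribution specification
#'
#' @param spec a [dist_spec()].
#' @return named numeric vector `c(mean, sd)`.
#' @export
dist_moments <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  with(spec$par, switch(spec$family,
    fixed = c(mean = point, sd = 0),
    beta  = c(mean = alpha / (alpha + beta),
              sd = sqrt(alpha * beta / ((alpha + beta)^2 * (alpha + beta + 1)))),
    gamma = c(mean = shape / rate, sd = sqrt(shape) / rate),
    lognormal = c(mean = exp(mu_log + sigma_log^2 / 2),
                  sd = exp(mu_log + sigma_log^2 / 2) *
                       sqrt(exp(sigma_log^2) - 1))))
}

# distribution appropriate to a parameter's model role
dist_for_role <- function(role) {
  switch(role,
    transition_prob = , utility = "beta",
    relative_effect = "lognormal",
    cost_dmc = , cost_dnmc = "gamma",
    epidemiology = , setting = "fixed",
    stop("unknown parameter role: ", role))
}

# build the dist_spec for one row of a parameter table
spec_for <- function(name, mean, se, dist, lognormal_method = "median") {
  switch(dist,
    fixed     = dist_spec("fixed", point = mean),
    beta      = beta_from_moments(mean, se, name),
    gamma     = gamma_from_moments(mean, se, name),
    lognormal = lognormal_from_point(mean, se, lognormal_method, name),
    stop("unknown distribution family '", dist, "'", for_param(name)))
}

for_param <- function(name) if (is.null(name)) "" else paste0(" for parameter '", name, "'")
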
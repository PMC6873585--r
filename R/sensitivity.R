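# Parameter-uncertainty analyses: probabilistic (second-order Monte Carlo)
# sensitivity analysis with cost-effectiveness plane and acceptability
# curves, one-way (tornado) and two-way deterministic analyses, and a sweep
# over the structural model options.

# incremental results for one parameter set, both perspectives
.run_deltas <- function(values, settings, options) {
  tr_t <- run_cohort(values, "trastuzumab", settings, options)
  tr_c <- run_cohort(values, "chemo", settings, options)
  out <- numeric(10)
  i <- 1
  for (persp in c("healthcare", "societal")) {
    ot <- accumulate_outcomes(tr_t, values, "trastuzumab", persp,
                              settings$discount_rate, options)
    oc <- accumulate_outcomes(tr_c, values, "chemo", persp,
                              settings$discount_rate, options)
    out[i:(i + 4)] <- c(ot$cost, oc$cost, ot$ly - oc$ly, ot$qaly, oc$qaly)
    i <- i + 5
  }
  names(out) <- c("cost_trast", "cost_chemo", "delta_ly", "qaly_trast", "qaly_chemo",
                  "cost_trast_soc", "cost_chemo_soc", "delta_ly_soc",
                  "qaly_trast_soc", "qaly_chemo_soc")
  out
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: draws `n` parameter sets from the sampling
#' distributions with [sample_parameters()] (infeasible sets rejected and
#' redrawn), runs both arms through the cohort model for each draw, and
#' stores per-iteration totals and increments under both perspectives.
#'
#' @param params a validated `"param_table"`.
#' @param n number of Monte Carlo replications (50,000 in the base case).
#' @param seed integer seed making the run reproducible.
#' @param options a [cua_options()] list.
#' @return object of class `"cua_psa"`: data frame `results` with one row
#'   per iteration (`delta_cost`, `delta_ly`, `delta_qaly` and per-arm
#'   cost/QALY totals, healthcare and `_soc` societal columns), plus `n`,
#'   `seed`, `resampled` count, settings and options.
#' @seealso [ceac()], [plot.cua_psa()]
#' @export
#' @examples
#' psa <- run_psa(default_parameters(), n = 200, seed = 2019)
#' summary(psa)
run_psa <- function(params, n = 50000, seed = 2019, options = cua_options()) {
  validate_parameters(params)
  settings <- param_settings(params)
  draws <- sample_parameters(params, n = n, seed = seed,
                             lognormal_method = options$lognormal_method)
  res <- matrix(0, n, 10)
  for (i in seq_len(n))
    res[i, ] <- .run_deltas(draws[i, ], settings, options)
  colnames(res) <- c("cost_trast", "cost_chemo", "delta_ly", "qaly_trast",
                     "qaly_chemo", "cost_trast_soc", "cost_chemo_soc",
                     "delta_ly_soc", "qaly_trast_soc", "qaly_chemo_soc")
  res <- as.data.frame(res)
  res$delta_cost <- res$cost_trast - res$cost_chemo
  res$delta_qaly <- res$qaly_trast - res$qaly_chemo
  res$delta_cost_soc <- res$cost_trast_soc - res$cost_chemo_soc
  res$delta_qaly_soc <- res$qaly_trast_soc - res$qaly_chemo_soc
  structure(list(results = res, n = n, seed = seed,
                 resampled = attr(draws, "resampled"),
                 settings = settings, options = options),
            class = "cua_psa")
}

#' @describeIn run_psa PSA as a `simulate()` method on a fitted
#'   [cua_model()] (requires the model to have been built from a parameter
#'   table).
#' @param object a `"cua_model"` built from a `"param_table"`.
#' @param nsim number of replications.
#' @param ... unused.
#' @export
simulate.cua_model <- function(object, nsim = 50000, seed = 2019, ...) {
  if (is.null(object$params))
    stop("simulate() needs a model built from a parameter table")
  run_psa(object$params, n = nsim, seed = seed, options = object$options)
}

#' Summary of a PSA
#'
#' Monte Carlo means of the increments and the ICERs formed from mean
#' incremental cost over mean incremental outcome, per perspective.
#'
#' @param object a `"cua_psa"`.
#' @param ... unused.
#' @return a data frame with one row per perspective.
#' @export
summary.cua_psa <- function(object, ...) {
  r <- object$results
  out <- data.frame(
    perspective = c("healthcare", "societal"),
    mean_cost_trast = c(mean(r$cost_trast), mean(r$cost_trast_soc)),
    mean_cost_chemo = c(mean(r$cost_chemo), mean(r$cost_chemo_soc)),
    mean_delta_cost = c(mean(r$delta_cost), mean(r$delta_cost_soc)),
    mean_delta_ly = c(mean(r$delta_ly), mean(r$delta_ly_soc)),
    mean_delta_qaly = c(mean(r$delta_qaly), mean(r$delta_qaly_soc)))
  out$icer_per_qaly <- out$mean_delta_cost / out$mean_delta_qaly
  out$icer_per_ly <- out$mean_delta_cost / out$mean_delta_ly
  out
}

#' @export
print.cua_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d replications (seed %s, %d redrawn)\n",
              x$n, format(x$seed), x$resampled))
  s <- summary(x)
  s[-1] <- lapply(s[-1], function(col) round(col, 3))
  print(s, row.names = FALSE)
  invisible(x)
}

#' @describeIn run_psa cost-effectiveness plane of the PSA draws with the
#'   willingness-to-pay threshold line.
#' @param x a `"cua_psa"`.
#' @param perspective which perspective to plot.
#' @param lambda threshold line slope (PHP/QALY); defaults to the run's
#'   setting.
#' @export
plot.cua_psa <- function(x, perspective = c("healthcare", "societal"),
                         lambda = NULL, ...) {
  perspective <- match.arg(perspective)
  r <- x$results
  dc <- if (perspective == "healthcare") r$delta_cost else r$delta_cost_soc
  dq <- if (perspective == "healthcare") r$delta_qaly else r$delta_qaly_soc
  if (is.null(lambda)) lambda <- x$settings$lambda
  graphics::plot(dq, dc, pch = ".", col = "grey40",
                 xlab = "incremental QALYs", ylab = "incremental cost (PHP)",
                 main = sprintf("Cost-effectiveness plane (%s)", perspective), ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  graphics::abline(0, lambda, col = "darkgreen", lwd = 2)
  graphics::abline(0, mean(dc) / mean(dq), col = "black", lwd = 2, lty = 2)
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the probability that trastuzumab
#' is cost-effective is the fraction of PSA iterations with positive net
#' monetary benefit (`lambda * dQALY - dCost > 0`); with two strategies the
#' chemotherapy probability is its complement.
#'
#' @param psa a `"cua_psa"`.
#' @param thresholds PHP/QALY grid (default 0 to 1,000,000 by 10,000).
#' @param perspective `"healthcare"` or `"societal"`.
#' @return object of class `"cua_ceac"`: data frame with `threshold`,
#'   `p_trastuzumab`, `p_chemo`.
#' @export
ceac <- function(psa, thresholds = seq(0, 1e6, by = 1e4),
                 perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  r <- psa$results
  dc <- if (perspective == "healthcare") r$delta_cost else r$delta_cost_soc
  dq <- if (perspective == "healthcare") r$delta_qaly else r$delta_qaly_soc
  p <- vapply(thresholds, function(l) mean(l * dq - dc > 0), numeric(1))
  structure(data.frame(threshold = thresholds, p_trastuzumab = p,
                       p_chemo = 1 - p),
            perspective = perspective,
            class = c("cua_ceac", "data.frame"))
}

#' @export
plot.cua_ceac <- function(x, ...) {
  graphics::plot(x$threshold, x$p_trastuzumab, type = "l", lwd = 2,
                 ylim = c(0, 1), xlab = "threshold (PHP per QALY)",
                 ylab = "probability cost-effective",
                 main = "Cost-effectiveness acceptability", ...)
  graphics::lines(x$threshold, x$p_chemo, lwd = 2, col = "grey50")
  graphics::legend("right", c("trastuzumab + CT", "CT alone"),
                   col = c("black", "grey50"), lwd = 2, bty = "n")
  invisible(x)
}

# clip a candidate parameter value to its validity range
.clip_value <- function(x, role) {
  switch(role,
    transition_prob = , utility = min(max(x, 0), 1),
    relative_effect = max(x, 1e-6),
    max(x, 0))
}

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the deterministic ICER per QALY with each parameter set to its
#' low and high value while all others stay at their means. Default ranges
#' are the normal-approximation 95% interval (mean +/- 1.96 SE) clipped to
#' validity; the discount rate is additionally varied over 0-6% and the
#' trastuzumab efficacy duration over 5-49 years.
#'
#' @param params a `"param_table"`.
#' @param perspective `"healthcare"` or `"societal"`.
#' @param options a [cua_options()] list.
#' @param z half-width multiplier for the default ranges (1.96 for 95%).
#' @param discount_range,efficacy_range low/high for the two setting sweeps.
#' @return object of class `"cua_tornado"`: data frame with `parameter`,
#'   `low`, `high`, `icer_low`, `icer_high` and the absolute ICER `span`,
#'   sorted by decreasing span.
#' @export
one_way_sa <- function(params, perspective = c("healthcare", "societal"),
                       options = cua_options(), z = 1.96,
                       discount_range = c(0, 0.06),
                       efficacy_range = c(5, 49)) {
  perspective <- match.arg(perspective)
  validate_parameters(params)
  settings <- param_settings(params)
  means <- param_means(params)
  icer_base <- function(values, settings)
    cua_model(values, options, settings)$ce[[perspective]]$icer_per_qaly
  vary <- params[params$se > 0 & params$role != "epidemiology", ]
  rows <- lapply(seq_len(nrow(vary)), function(i) {
    nm <- vary$name[i]
    lo <- .clip_value(vary$mean[i] - z * vary$se[i], vary$role[i])
    hi <- .clip_value(vary$mean[i] + z * vary$se[i], vary$role[i])
    v <- means
    v[nm] <- lo; il <- icer_base(v, settings)
    v[nm] <- hi; ih <- icer_base(v, settings)
    data.frame(parameter = nm, low = lo, high = hi,
               icer_low = il, icer_high = ih)
  })
  rows <- c(rows, list(
    data.frame(parameter = "discount_rate",
               low = discount_range[1], high = discount_range[2],
               icer_low = icer_base(means, utils::modifyList(settings,
                 list(discount_rate = discount_range[1]))),
               icer_high = icer_base(means, utils::modifyList(settings,
                 list(discount_rate = discount_range[2])))),
    data.frame(parameter = "efficacy_years",
               low = efficacy_range[1], high = efficacy_range[2],
               icer_low = icer_base(means, utils::modifyList(settings,
                 list(efficacy_years = efficacy_range[1]))),
               icer_high = icer_base(means, utils::modifyList(settings,
                 list(efficacy_years = efficacy_range[2]))))))
  out <- do.call(rbind, rows)
  out$span <- abs(out$icer_high - out$icer_low)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  structure(out, icer_base = icer_base(means, settings),
            perspective = perspective, class = c("cua_tornado", "data.frame"))
}

#' @export
plot.cua_tornado <- function(x, top = 12, ...) {
  d <- utils::head(x, top)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "icer_base")
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  ylim <- c(0, nrow(d) + 1)
  xlim <- range(c(d$icer_low, d$icer_high, base))
  graphics::plot(NA, xlim = xlim, ylim = ylim, yaxt = "n",
                 xlab = "ICER (PHP per QALY)", ylab = "",
                 main = "One-way sensitivity analysis", ...)
  for (i in seq_len(nrow(d))) {
    graphics::rect(min(d$icer_low[i], base), i - 0.3,
                   max(d$icer_low[i], base), i + 0.3, col = "gold")
    graphics::rect(min(d$icer_high[i], base), i - 0.3,
                   max(d$icer_high[i], base), i + 0.3,
                   col = grDevices::adjustcolor("darkgreen", 0.6))
  }
  graphics::abline(v = base, lwd = 2)
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  invisible(x)
}

#' Two-way sensitivity analysis over treatment effect and efficacy duration
#'
#' Evaluates, on a grid of DFS hazard-ratio values and efficacy durations,
#' which strategy has the higher net monetary benefit at the threshold
#' (deterministic model, all other parameters at their means).
#'
#' @param params a `"param_table"`.
#' @param hr_values grid of DFS hazard ratios (default the 95% CI of the
#'   pooled estimate).
#' @param durations grid of efficacy durations in years.
#' @param lambda threshold (PHP/QALY); defaults to the table's setting.
#' @param perspective `"healthcare"` or `"societal"`.
#' @param options a [cua_options()] list.
#' @return object of class `"cua_twoway"`: character matrix (rows =
#'   `hr_values`, columns = `durations`) of the cost-effective strategy.
#' @export
two_way_sa <- function(params, hr_values = NULL, durations = seq(5, 49, by = 4),
                       lambda = NULL, perspective = c("healthcare", "societal"),
                       options = cua_options()) {
  perspective <- match.arg(perspective)
  validate_parameters(params)
  settings <- param_settings(params)
  if (is.null(lambda)) lambda <- settings$lambda
  means <- param_means(params)
  if (is.null(hr_values)) {
    i <- match("hr_dfs", params$name)
    hr_values <- seq(max(params$mean[i] - 1.96 * params$se[i], 0.01),
                     params$mean[i] + 1.96 * params$se[i], length.out = 9)
  }
  out <- matrix("", length(hr_values), length(durations),
                dimnames = list(signif(hr_values, 4), durations))
  for (i in seq_along(hr_values)) for (j in seq_along(durations)) {
    v <- means
    v["hr_dfs"] <- hr_values[i]
    fit <- cua_model(v, options,
                     utils::modifyList(settings, list(efficacy_years = durations[j])))
    nmb <- net_monetary_benefit(fit$ce[[perspective]], lambda)
    out[i, j] <- if (nmb > 0) "trastuzumab" else "chemo"
  }
  structure(out, lambda = lambda, perspective = perspective,
            class = c("cua_twoway", "matrix", "array"))
}

#' @export
plot.cua_twoway <- function(x, ...) {
  z <- matrix(as.integer(unclass(x) == "trastuzumab"), nrow(x), ncol(x))
  graphics::image(as.numeric(rownames(x)), as.numeric(colnames(x)), z,
                  zlim = c(0, 1), col = c("grey80", "darkgreen"),
                  xlab = "hazard ratio for DFS", ylab = "efficacy duration (years)",
                  main = sprintf("Cost-effective strategy at PHP %s/QALY",
                                 format(attr(x, "lambda"), big.mark = ",")), ...)
  graphics::legend("topright", fill = c("grey80", "darkgreen"),
                   legend = c("chemo", "trastuzumab"), bg = "white")
  invisible(x)
}

#' Sweep over the structural model options
#'
#' Recomputes the deterministic ICER per QALY under every combination of the
#' binary structural choices (hazard-ratio method, CHF entry timing,
#' half-cycle correction, discount exponent), documenting how sensitive the
#' base-case result is to choices the published analysis leaves open.
#'
#' @param params a `"param_table"`.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return data frame with one row per configuration and its ICER per QALY.
#' @export
structural_sweep <- function(params, perspective = c("healthcare", "societal")) {
  perspective <- match.arg(perspective)
  grid <- expand.grid(hr_method = c("rate", "multiply"),
                      chf_entry = c("first_cycle", "every_cycle"),
                      half_cycle = c(FALSE, TRUE),
                      discount_exponent = c("t_minus_1", "t"),
                      stringsAsFactors = FALSE)
  grid$icer_per_qaly <- vapply(seq_len(nrow(grid)), function(i) {
    opt <- cua_options(hr_method = grid$hr_method[i],
                       chf_entry = grid$chf_entry[i],
                       half_cycle = grid$half_cycle[i],
                       discount_exponent = grid$discount_exponent[i])
    cua_model(params, opt)$ce[[perspective]]$icer_per_qaly
  }, numeric(1))
  grid
}
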
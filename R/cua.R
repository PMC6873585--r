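# Cost-utility accounting: discounted costs, life-years and QALYs per arm
# and perspective, incremental results, and the threshold (cost-effective)
# price of the trastuzumab treatment course.

#' Discount factor for a model cycle
#'
#' First-year flows are undiscounted under the default convention
#' (`1/(1+rate)^(cycle-1)`); `exponent = "t"` discounts from cycle 1.
#'
#' @param cycle 1-based cycle (vectorised).
#' @param rate annual discount rate (0.035 in the base case).
#' @param exponent `"t_minus_1"` (default) or `"t"`.
#' @return numeric discount factor(s).
#' @export
discount_factor <- function(cycle, rate, exponent = c("t_minus_1", "t")) {
  exponent <- match.arg(exponent)
  if (any(cycle < 1)) stop("cycle must be >= 1")
  if (rate < 0) stop("discount rate must be non-negative")
  1 / (1 + rate)^(cycle - (exponent == "t_minus_1"))
}

# per-state annual cost vector for a perspective, and the one-off
# treatment-course cost charged to the entering cohort at cycle 1
.state_costs <- function(values, perspective, options) {
  v <- values
  rl  <- if (options$rec_later_source == "primary") v[["dmc_rec_later"]]
         else v[["dmc_rec_later_alt"]]
  rln <- if (options$rec_later_source == "primary") v[["dnmc_rec_later"]]
         else v[["dnmc_rec_later_alt"]]
  dmc <- c(v[["dmc_dfs"]], v[["dmc_chf"]], v[["dmc_rec_y1"]], rl,
           v[["dmc_met_y1"]], v[["dmc_met_later"]], 0)
  if (perspective == "societal")
    dmc <- dmc + c(v[["dnmc_dfs"]], v[["dnmc_chf"]], v[["dnmc_rec_y1"]], rln,
                   v[["dnmc_met_y1"]], v[["dnmc_met_later"]], 0)
  dmc
}

.tx_cost <- function(values, arm, perspective) {
  tx <- if (arm == "trastuzumab") values[["dmc_tx_trast"]] else values[["dmc_tx_ct"]]
  if (perspective == "societal")
    tx <- tx + if (arm == "trastuzumab") values[["dnmc_tx_trast"]] else values[["dnmc_tx_ct"]]
  tx
}

#' Accumulate costs, life-years and QALYs over a cohort trace
#'
#' Per cycle, state costs are the occupancy-weighted annual costs (direct
#' medical only for the healthcare-system perspective; plus direct
#' non-medical for the societal perspective), with the first-year tunnel
#' states carrying the first-year recurrence/metastasis costs. The one-off
#' treatment-course cost is charged to the entering cohort at cycle 1.
#' Life-years count all alive states; QALYs weight occupancy by state
#' utility (death = 0, both recurrence sub-states share the recurrence
#' utility, both metastasis sub-states the metastasis utility). Totals are
#' discounted with [discount_factor()]; undiscounted totals are returned
#' alongside.
#'
#' @param trace a [run_cohort()] result.
#' @param values named parameter vector used for costs/utilities.
#' @param arm `"trastuzumab"` or `"chemo"` (defaults to the trace's arm).
#' @param perspective `"healthcare"` or `"societal"`.
#' @param discount_rate annual rate applied to both costs and outcomes.
#' @param options a [cua_options()] list.
#' @return object of class `"arm_outcome"`: list with `cost`, `ly`, `qaly`
#'   (discounted), their undiscounted counterparts, `arm` and `perspective`.
#' @export
accumulate_outcomes <- function(trace, values,
                                arm = attr(trace, "arm"),
                                perspective = c("healthcare", "societal"),
                                discount_rate = 0.035,
                                options = cua_options()) {
  perspective <- match.arg(perspective)
  cst <- .state_costs(values, perspective, options)
  u <- c(values[["u_dfs"]], values[["u_chf"]], values[["u_rec"]],
         values[["u_rec"]], values[["u_met"]], values[["u_met"]], 0)
  H <- nrow(trace)
  occ <- unclass(trace)
  if (options$half_cycle) {
    start <- rbind(c(1, numeric(6)), occ[-H, , drop = FALSE])
    occ <- (start + occ) / 2
  }
  df <- discount_factor(seq_len(H), discount_rate, options$discount_exponent)
  tx <- .tx_cost(values, arm, perspective)
  cost_flow <- as.numeric(occ %*% cst)
  cost_flow[1] <- cost_flow[1] + tx
  ly_flow <- 1 - occ[, "DEATH"]
  qaly_flow <- as.numeric(occ %*% u)
  structure(list(
    cost = sum(df * cost_flow), ly = sum(df * ly_flow), qaly = sum(df * qaly_flow),
    cost_undiscounted = sum(cost_flow), ly_undiscounted = sum(ly_flow),
    qaly_undiscounted = sum(qaly_flow),
    arm = arm, perspective = perspective), class = "arm_outcome")
}

#' @export
print.arm_outcome <- function(x, ...) {
  cat(sprintf("%s arm, %s perspective (discounted):\n", x$arm, x$perspective))
  cat(sprintf("  cost PHP %s, %.3f LY, %.3f QALY\n",
              format(round(x$cost), big.mark = ","), x$ly, x$qaly))
  invisible(x)
}

#' Incremental cost-effectiveness of one arm over another
#'
#' @param intervention,control `"arm_outcome"` objects from the same
#'   perspective.
#' @return object of class `"ce_result"`: incremental cost, life-years and
#'   QALYs, ICERs per LY and per QALY (NA when the outcome delta is zero),
#'   and a dominance flag (`"intervention_dominant"` when it saves money and
#'   gains health, `"intervention_dominated"` for the reverse, else
#'   `"none"`).
#' @export
compute_icer <- function(intervention, control) {
  if (intervention$perspective != control$perspective)
    stop("arm outcomes computed under different perspectives")
  dc <- intervention$cost - control$cost
  dly <- intervention$ly - control$ly
  dq <- intervention$qaly - control$qaly
  dominance <- if (dc < 0 && dq > 0) "intervention_dominant"
    else if (dc > 0 && dq < 0) "intervention_dominated"
    else "none"
  structure(list(
    delta_cost = dc, delta_ly = dly, delta_qaly = dq,
    icer_per_ly = if (dly != 0) dc / dly else NA_real_,
    icer_per_qaly = if (dq != 0) dc / dq else NA_real_,
    dominance = dominance, perspective = intervention$perspective),
    class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Incremental result (%s perspective):\n", x$perspective))
  cat(sprintf("  dCost PHP %s, dLY %.3f, dQALY %.3f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_ly, x$delta_qaly))
  cat(sprintf("  ICER: PHP %s per LY, PHP %s per QALY%s\n",
              format(round(x$icer_per_ly), big.mark = ","),
              format(round(x$icer_per_qaly), big.mark = ","),
              if (x$dominance == "none") "" else paste0(" [", x$dominance, "]")))
  invisible(x)
}

#' Net monetary benefit
#'
#' `lambda * delta_QALY - delta_cost` at willingness-to-pay `lambda`.
#'
#' @param ce a `"ce_result"` (or any list with `delta_cost`, `delta_qaly`).
#' @param lambda threshold in PHP per QALY, non-negative.
#' @return net monetary benefit in PHP.
#' @export
net_monetary_benefit <- function(ce, lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative")
  lambda * ce$delta_qaly - ce$delta_cost
}

#' Evaluate the cost-utility model
#'
#' Runs both treatment arms through the cohort engine at the given parameter
#' values and accumulates discounted costs, life-years and QALYs under both
#' perspectives, returning the incremental comparison of 1-year adjuvant
#' trastuzumab + chemotherapy against chemotherapy alone.
#'
#' @param params a `"param_table"` (defaults to the packaged table) or a
#'   named numeric vector of parameter values.
#' @param options a [cua_options()] list of structural choices.
#' @param settings overrides for the run settings; defaults to the table's.
#' @return object of class `"cua_model"` with elements `trace`
#'   (per arm), `outcomes` (per perspective and arm), `ce` (per
#'   perspective), plus the values, settings and options used.
#' @seealso [simulate.cua_model()] for the PSA, [threshold_price()],
#'   [one_way_sa()], [budget_impact()]
#' @export
#' @examples
#' fit <- cua_model()
#' fit
#' summary(fit)
cua_model <- function(params = default_parameters(), options = cua_options(),
                      settings = NULL) {
  if (inherits(params, "param_table")) {
    validate_parameters(params)
    values <- param_means(params)
    base_settings <- param_settings(params)
  } else {
    values <- params
    base_settings <- .default_settings()
  }
  settings <- utils::modifyList(base_settings, as.list(settings))
  trace <- list(
    trastuzumab = run_cohort(values, "trastuzumab", settings, options),
    chemo = run_cohort(values, "chemo", settings, options))
  outcomes <- list(); ce <- list()
  for (persp in c("healthcare", "societal")) {
    outcomes[[persp]] <- lapply(trace, function(tr)
      accumulate_outcomes(tr, values, attr(tr, "arm"), persp,
                          settings$discount_rate, options))
    ce[[persp]] <- compute_icer(outcomes[[persp]]$trastuzumab,
                                outcomes[[persp]]$chemo)
  }
  structure(list(trace = trace, outcomes = outcomes, ce = ce,
                 values = values, settings = settings, options = options,
                 params = if (inherits(params, "param_table")) params),
            class = "cua_model")
}

#' @export
print.cua_model <- function(x, ...) {
  cat("Markov cohort cost-utility model: adjuvant trastuzumab + CT vs CT alone\n")
  cat(sprintf("  %d one-year cycles, %.1f%% discount, efficacy %g years\n",
              x$settings$horizon_cycles, 100 * x$settings$discount_rate,
              x$settings$efficacy_years))
  for (persp in names(x$ce)) print(x$ce[[persp]])
  invisible(x)
}

#' @export
summary.cua_model <- function(object, ...) {
  rows <- do.call(rbind, lapply(names(object$outcomes), function(persp) {
    o <- object$outcomes[[persp]]
    data.frame(perspective = persp,
               arm = c("trastuzumab", "chemo"),
               cost = c(o$trastuzumab$cost, o$chemo$cost),
               ly = c(o$trastuzumab$ly, o$chemo$ly),
               qaly = c(o$trastuzumab$qaly, o$chemo$qaly))
  }))
  structure(list(arms = rows, ce = object$ce, settings = object$settings),
            class = "summary.cua_model")
}

#' @export
print.summary.cua_model <- function(x, ...) {
  cat("Discounted per-patient totals:\n")
  df <- x$arms
  df$cost <- round(df$cost); df$ly <- round(df$ly, 3); df$qaly <- round(df$qaly, 3)
  print(df, row.names = FALSE)
  cat("\n")
  for (persp in names(x$ce)) print(x$ce[[persp]])
  invisible(x)
}

#' @describeIn cua_model plot the two arms' state-occupancy traces.
#' @param x,y a `"cua_model"` object (plot method); `y` unused.
#' @param ... passed on to [graphics::matplot()].
#' @export
plot.cua_model <- function(x, y, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (arm in names(x$trace)) {
    tr <- x$trace[[arm]]
    graphics::matplot(seq_len(nrow(tr)), unclass(tr), type = "l", lty = 1,
                      col = seq_len(ncol(tr)), xlab = "cycle (year)",
                      ylab = "occupancy", main = arm, ...)
    graphics::legend("right", legend = colnames(tr), col = seq_len(ncol(tr)),
                     lty = 1, cex = 0.6, bty = "n")
  }
  invisible(x)
}

#' Cost-effective (threshold) price of the trastuzumab treatment course
#'
#' Finds, by bisection, the value of the trastuzumab-arm treatment-course
#' cost at which the deterministic ICER per QALY equals the willingness-to-pay
#' threshold. The whole therapy bundle (drugs, administration, cardiac
#' monitoring; plus the non-medical course cost under the societal
#' perspective) is the decision variable. The root is verified by the net
#' monetary benefit being zero at the returned price (within `tol` pesos,
#' since the ICER is strictly increasing in the treatment cost at fixed
#' outcomes).
#'
#' @param params a `"param_table"`.
#' @param lambda threshold in PHP per QALY (default the table's setting).
#' @param perspective `"healthcare"` or `"societal"`.
#' @param options a [cua_options()] list.
#' @param tol bisection tolerance in PHP (default 1).
#' @param upper upper search bracket for the course cost.
#' @return the threshold price in PHP.
#' @export
#' @examples
#' threshold_price(default_parameters())
threshold_price <- function(params, lambda = NULL,
                            perspective = c("healthcare", "societal"),
                            options = cua_options(), tol = 1, upper = NULL) {
  perspective <- match.arg(perspective)
  validate_parameters(params)
  settings <- param_settings(params)
  if (is.null(lambda)) lambda <- settings$lambda
  values <- param_means(params)
  if (is.null(upper)) upper <- 4 * .tx_cost(values, "trastuzumab", perspective)
  # outcomes do not depend on the course cost: run the traces once
  trace_t <- run_cohort(values, "trastuzumab", settings, options)
  trace_c <- run_cohort(values, "chemo", settings, options)
  out_c <- accumulate_outcomes(trace_c, values, "chemo", perspective,
                               settings$discount_rate, options)
  nmb_at <- function(price) {
    v <- values
    # 'price' is the full bundle cost; under the societal perspective the
    # non-medical course cost is part of the bundle
    v[["dmc_tx_trast"]] <- price -
      if (perspective == "societal") v[["dnmc_tx_trast"]] else 0
    out_t <- accumulate_outcomes(trace_t, v, "trastuzumab", perspective,
                                 settings$discount_rate, options)
    ce <- compute_icer(out_t, out_c)
    if (ce$delta_qaly <= 0)
      stop("threshold price undefined: no QALY gain at current parameters")
    net_monetary_benefit(ce, lambda)
  }
  lo <- 0; hi <- upper
  if (nmb_at(lo) < 0 || nmb_at(hi) > 0)
    stop("no sign change of net monetary benefit over [0, ", upper, "]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nmb_at(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
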
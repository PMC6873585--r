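# Cohort state-transition engine.
#
# Seven states: the five clinical states (disease-free survival, congestive
# heart failure, local recurrence, distant metastasis, death) with the
# recurrence and metastasis states split into first-year tunnel sub-states
# so that first-year and subsequent-year costs can differ.

.states <- c("DFS", "CHF", "REC_Y1", "REC_LATER", "MET_Y1", "MET_LATER", "DEATH")

#' Health-state labels of the cohort model
#'
#' `REC_Y1`/`MET_Y1` are one-cycle tunnel sub-states carrying first-year
#' treatment costs; `REC_LATER`/`MET_LATER` hold all later years. `DEATH`
#' is absorbing.
#' @return character vector of the seven state labels, in matrix order.
#' @export
health_states <- function() .states

#' Structural model options
#'
#' Collects the structural choices the published analysis leaves open, with
#' the package defaults first.
#'
#' @param hr_method how a hazard ratio modifies an annual probability:
#'   `"rate"` (default) converts through the constant-hazard relation
#'   `1 - (1-p)^HR`; `"multiply"` uses `p * HR` directly.
#' @param chf_entry whether cardiotoxic CHF entry from DFS occurs in the
#'   treatment year only (`"first_cycle"`, default) or in `"every_cycle"`;
#'   the CHF risk ratio for the trastuzumab arm applies in cycle 1 either way.
#' @param half_cycle logical; apply a half-cycle correction when accumulating
#'   costs and outcomes (default `FALSE`, matching an end-of-cycle count).
#' @param discount_exponent `"t_minus_1"` (default; first-year flows
#'   undiscounted) or `"t"`.
#' @param rec_later_source which published cost pair to use for the
#'   recurrence after-first-year state: `"primary"` (182,437 / 17,817,
#'   default) or `"alternate"` (516,904 / 5,939).
#' @param lognormal_method log-normal parameterisation for PSA ratio draws,
#'   see [lognormal_from_point()].
#' @return a named list of class `"cua_options"`.
#' @export
cua_options <- function(hr_method = c("rate", "multiply"),
                        chf_entry = c("first_cycle", "every_cycle"),
                        half_cycle = FALSE,
                        discount_exponent = c("t_minus_1", "t"),
                        rec_later_source = c("primary", "alternate"),
                        lognormal_method = c("median", "moments")) {
  structure(list(
    hr_method = match.arg(hr_method),
    chf_entry = match.arg(chf_entry),
    half_cycle = isTRUE(half_cycle),
    discount_exponent = match.arg(discount_exponent),
    rec_later_source = match.arg(rec_later_source),
    lognormal_method = match.arg(lognormal_method)), class = "cua_options")
}

#' Apply a hazard ratio to an annual transition probability
#'
#' Default conversion assumes a constant hazard within the cycle:
#' `p' = 1 - (1 - p)^HR`, the standard transformation for annual
#' probabilities under proportional hazards. With `method = "multiply"` the
#' probability is scaled directly.
#'
#' @param p annual probability in \[0, 1); `p = 1` is only valid with `hr = 1`.
#' @param hr hazard ratio, positive.
#' @param method `"rate"` or `"multiply"`.
#' @return the modified probability.
#' @export
#' @examples
#' apply_hazard_ratio(0.0294, 0.65)   # 1 - 0.9706^0.65
apply_hazard_ratio <- function(p, hr, method = c("rate", "multiply")) {
  method <- match.arg(method)
  if (any(hr <= 0)) stop("hazard ratio must be positive")
  if (any(p < 0 | p > 1)) stop("probability outside [0, 1]")
  if (any(p == 1 & hr != 1))
    stop("cannot apply a hazard ratio to a certain event (p = 1)")
  if (isTRUE(all(hr == 1))) return(p)    # exact identity at the null ratio
  if (method == "rate") 1 - (1 - p)^hr else pmin(p * hr, 1)
}

#' Build the one-cycle transition matrix
#'
#' Assembles the 7x7 row-stochastic transition matrix for one arm and cycle.
#' Disease-free exits go to CHF (cycle 1 only by default, inflated by the
#' CHF risk ratio in the trastuzumab arm), to the recurrence and metastasis
#' first-year tunnels, and to death; while trastuzumab efficacy lasts
#' (cycles 1 to `efficacy_years`) the DFS hazard ratio reduces the
#' recurrence and metastasis exits and the OS hazard ratio the death exit.
#' CHF is occupied for one cycle, exiting to recurrence, metastasis or death
#' with the residual returning to DFS (cardiotoxicity is modelled as a
#' once-only, largely reversible event). Recurrence states exit to
#' metastasis or death, metastasis states to death; death is absorbing.
#'
#' @param values named numeric vector of parameter values (a row of
#'   [sample_parameters()] output or [param_means()]).
#' @param arm `"trastuzumab"` or `"chemo"`.
#' @param cycle 1-based model year.
#' @param efficacy_years duration of the trastuzumab treatment effect.
#' @param options a [cua_options()] list.
#' @return 7x7 matrix over [health_states()], rows summing to 1.
#' @export
build_transition_matrix <- function(values, arm = c("trastuzumab", "chemo"),
                                    cycle = 1, efficacy_years = 11,
                                    options = cua_options()) {
  arm <- match.arg(arm)
  v <- values
  M <- matrix(0, 7, 7, dimnames = list(.states, .states))

  chf_open <- cycle == 1 || options$chf_entry == "every_cycle"
  p_chf <- if (chf_open) {
    if (arm == "trastuzumab" && cycle == 1) v[["tp_dfs_chf"]] * v[["rr_chf"]]
    else v[["tp_dfs_chf"]]
  } else 0
  if (arm == "trastuzumab" && cycle <= efficacy_years) {
    p_rec <- apply_hazard_ratio(v[["tp_dfs_rec"]], v[["hr_dfs"]], options$hr_method)
    p_met <- apply_hazard_ratio(v[["tp_dfs_met"]], v[["hr_dfs"]], options$hr_method)
    p_die <- apply_hazard_ratio(v[["tp_dfs_death"]], v[["hr_os"]], options$hr_method)
  } else {
    p_rec <- v[["tp_dfs_rec"]]; p_met <- v[["tp_dfs_met"]]; p_die <- v[["tp_dfs_death"]]
  }
  exits <- p_chf + p_rec + p_met + p_die
  if (exits > 1)
    stop("infeasible transition: DFS exit probabilities sum to ",
         signif(exits, 6), " > 1")
  M["DFS", c("DFS", "CHF", "REC_Y1", "MET_Y1", "DEATH")] <-
    c(1 - exits, p_chf, p_rec, p_met, p_die)

  chf_exits <- v[["tp_chf_rec"]] + v[["tp_chf_met"]] + v[["tp_chf_death"]]
  if (chf_exits > 1) stop("infeasible transition: CHF exit probabilities sum > 1")
  M["CHF", c("DFS", "REC_Y1", "MET_Y1", "DEATH")] <-
    c(1 - chf_exits, v[["tp_chf_rec"]], v[["tp_chf_met"]], v[["tp_chf_death"]])

  rec_exits <- v[["tp_rec_met"]] + v[["tp_rec_death"]]
  if (rec_exits > 1) stop("infeasible transition: recurrence exit probabilities sum > 1")
  for (s in c("REC_Y1", "REC_LATER"))
    M[s, c("REC_LATER", "MET_Y1", "DEATH")] <-
      c(1 - rec_exits, v[["tp_rec_met"]], v[["tp_rec_death"]])

  for (s in c("MET_Y1", "MET_LATER"))
    M[s, c("MET_LATER", "DEATH")] <- c(1 - v[["tp_met_death"]], v[["tp_met_death"]])

  M["DEATH", "DEATH"] <- 1
  M
}

#' Simulate the cohort trace
#'
#' Advances a unit cohort that enters the model in the disease-free state
#' through `horizon_cycles` one-year cycles; row `t` of the result is the
#' state occupancy at the end of cycle `t`. Transition matrices are constant
#' within the regimes (treatment year / efficacy window / post-efficacy) and
#' are built once per regime.
#'
#' @inheritParams build_transition_matrix
#' @param settings list with `horizon_cycles` and `efficacy_years`
#'   (see [param_settings()]).
#' @return a `horizon_cycles` x 7 occupancy matrix of class
#'   `"cohort_trace"` with the arm stored as an attribute; every row sums
#'   to 1.
#' @export
#' @examples
#' tr <- run_cohort(param_means(default_parameters()), "chemo")
#' head(round(tr, 4))
run_cohort <- function(values, arm = c("trastuzumab", "chemo"),
                       settings = .default_settings(),
                       options = cua_options()) {
  arm <- match.arg(arm)
  H <- as.integer(settings$horizon_cycles)
  eff <- settings$efficacy_years
  regime <- function(cycle) paste(
    cycle == 1 || options$chf_entry == "every_cycle",
    arm == "trastuzumab" && cycle <= eff,
    arm == "trastuzumab" && cycle == 1)
  cache <- new.env(parent = emptyenv())
  occ <- matrix(0, H, 7, dimnames = list(seq_len(H), .states))
  state <- c(1, numeric(6))
  for (t in seq_len(H)) {
    key <- regime(t)
    if (is.null(cache[[key]]))
      cache[[key]] <- build_transition_matrix(values, arm, t, eff, options)
    state <- as.numeric(state %*% cache[[key]])
    occ[t, ] <- state
  }
  structure(occ, arm = arm, class = c("cohort_trace", "matrix", "array"))
}

#' @export
print.cohort_trace <- function(x, digits = 4, ...) {
  cat("Cohort trace (", attr(x, "arm"), " arm, ", nrow(x), " cycles)\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

#' Export a cohort trace as a data frame
#' @param x a `"cohort_trace"`.
#' @param ... unused.
#' @return data frame with `cycle`, `arm` and one column per state.
#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  data.frame(cycle = seq_len(nrow(x)), arm = attr(x, "arm"),
             unclass(x), check.names = FALSE)
}
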
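# Random but structurally valid parameter tables for property testing:
# row-feasible probabilities with a safety margin, positive costs,
# utilities in [0, 1], feasible beta moments throughout.

#' Generate a random, structurally valid parameter table
#'
#' Draws every model parameter from wide but feasible ranges so that the
#' resulting table passes [validate_parameters()] and yields conserved
#' cohort traces in both arms: disease-free exit probabilities are rescaled
#' to keep their sum (including risk-ratio-inflated CHF entry) below
#' `1 - margin`, per-state exit sums are likewise bounded, SEs are drawn as
#' a fraction of the mean capped below the beta feasibility limit, and
#' epidemiology inputs stay fixed-point.
#'
#' @param seed integer seed; same seed, same table.
#' @param prob_scale upper bound for raw disease-progression probabilities.
#' @param cost_range range (PHP) for cost magnitudes.
#' @param utility_range range for state utilities.
#' @param se_frac range of the SE/mean ratio.
#' @param margin feasibility head-room left in each transition row.
#' @return a validated `"param_table"`.
#' @export
#' @examples
#' tab <- random_parameter_table(seed = 1)
#' validate_parameters(tab)
random_parameter_table <- function(seed, prob_scale = 0.4,
                                   cost_range = c(1e3, 2e6),
                                   utility_range = c(0.3, 0.95),
                                   se_frac = c(0.02, 0.25),
                                   margin = 0.05) {
  stopifnot(prob_scale > 0, prob_scale < 1, margin > 0, margin < 0.5)
  set.seed(seed)
  tab <- default_parameters()
  runif2 <- function(r) stats::runif(1, r[1], r[2])
  draw_se <- function(mean, dist) {
    s <- mean * runif2(se_frac)
    if (dist == "beta") min(s, 0.9 * sqrt(mean * (1 - mean)))
    else s
  }
  # relative effects first: the CHF risk ratio enters the DFS row budget
  rr <- stats::runif(1, 1, 5)
  hr <- stats::runif(2, 0.3, 1.2)
  # DFS exits: rescale so the worst-case row (risk-ratio inflated CHF entry,
  # hazard ratios above 1 applied through the rate conversion, which is
  # bounded by hr * p) sums below 1 - margin
  raw <- stats::runif(4, 0.001, prob_scale)   # chf, rec, met, death
  w <- c(max(rr, 1), max(hr[1], 1), max(hr[1], 1), max(hr[2], 1))
  budget <- sum(raw * w)
  if (budget > 1 - margin) raw <- raw * (1 - margin) / budget
  # CHF and recurrence rows with the same head-room
  chf <- stats::runif(3, 0.001, prob_scale)
  if (sum(chf) > 1 - margin) chf <- chf * (1 - margin) / sum(chf)
  rec <- stats::runif(2, 0.001, prob_scale)
  if (sum(rec) > 1 - margin) rec <- rec * (1 - margin) / sum(rec)
  met_death <- stats::runif(1, 0.001, 1 - margin)
  probs <- c(tp_dfs_chf = raw[1], tp_dfs_rec = raw[2], tp_dfs_met = raw[3],
             tp_dfs_death = raw[4], tp_chf_rec = chf[1], tp_chf_met = chf[2],
             tp_chf_death = chf[3], tp_rec_met = rec[1], tp_rec_death = rec[2],
             tp_met_death = met_death)
  ratios <- c(hr_dfs = hr[1], hr_os = hr[2], rr_chf = rr)
  for (i in seq_len(nrow(tab))) {
    nm <- tab$name[i]
    if (nm %in% names(probs)) tab$mean[i] <- probs[[nm]]
    else if (nm %in% names(ratios)) tab$mean[i] <- ratios[[nm]]
    else if (tab$role[i] == "utility") tab$mean[i] <- runif2(utility_range)
    else if (tab$role[i] == "epidemiology") next
    else if (tab$dist[i] != "fixed") tab$mean[i] <- runif2(cost_range)
    if (tab$dist[i] != "fixed")
      tab$se[i] <- draw_se(tab$mean[i], tab$dist[i])
  }
  validate_parameters(tab)
  tab
}

#' Multiplicatively perturb a parameter table
#'
#' Jitters every non-fixed mean by at most `fraction` (uniform multiplicative
#' noise), re-clips probabilities and utilities to \[0, 1\], and rescales any
#' transition row whose exits would exceed 1. Used for robustness checks.
#'
#' @param table a `"param_table"`.
#' @param fraction maximum relative perturbation, in \[0, 1).
#' @param seed integer seed.
#' @return a validated `"param_table"`.
#' @export
perturb_parameters <- function(table, fraction, seed = 1) {
  stopifnot(fraction >= 0, fraction < 1)
  validate_parameters(table)
  if (fraction == 0) return(table)
  set.seed(seed)
  jitter <- stats::runif(nrow(table), 1 - fraction, 1 + fraction)
  live <- table$dist != "fixed"
  table$mean[live] <- table$mean[live] * jitter[live]
  bounded <- table$role %in% c("transition_prob", "utility")
  table$mean[bounded] <- pmin(pmax(table$mean[bounded], 1e-6), 1 - 1e-6)
  # restore row feasibility where the jitter broke it
  v <- function(nm) table$mean[match(nm, table$name)]
  set_v <- function(nm, x) table$mean[match(nm, table$name)] <<- x
  rescale <- function(nms, weight = rep(1, length(nms)), cap = 0.999) {
    tot <- sum(vapply(nms, v, numeric(1)) * weight)
    if (tot > cap) for (nm in nms) set_v(nm, v(nm) * cap / tot)
  }
  rescale(c("tp_dfs_chf", "tp_dfs_rec", "tp_dfs_met", "tp_dfs_death"),
          weight = c(max(v("rr_chf"), 1), max(v("hr_dfs"), 1),
                     max(v("hr_dfs"), 1), max(v("hr_os"), 1)))
  rescale(c("tp_chf_rec", "tp_chf_met", "tp_chf_death"))
  rescale(c("tp_rec_met", "tp_rec_death"))
  # keep beta SEs feasible after the mean moved
  for (i in which(table$dist == "beta")) {
    lim <- sqrt(table$mean[i] * (1 - table$mean[i]))
    if (table$se[i] >= lim) table$se[i] <- 0.9 * lim
  }
  validate_parameters(table)
  table
}
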
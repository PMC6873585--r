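# shared fixtures built in code

# table with all sampling uncertainty switched off
zero_se_table <- function() {
  tab <- default_parameters()
  tab$se[] <- 0
  tab
}

# table in which trastuzumab has no effect (all ratios 1, equal course costs)
null_effect_table <- function() {
  tab <- default_parameters()
  for (nm in c("hr_dfs", "hr_os", "rr_chf")) tab$mean[tab$name == nm] <- 1
  tab$mean[tab$name == "dmc_tx_trast"] <- tab$mean[tab$name == "dmc_tx_ct"]
  tab$mean[tab$name == "dnmc_tx_trast"] <- tab$mean[tab$name == "dnmc_tx_ct"]
  tab
}

# hand-buildable cohort trace: constant occupancy row repeated
constant_trace <- function(row, cycles, arm = "chemo") {
  m <- matrix(rep(row, each = cycles), nrow = cycles,
              dimnames = list(NULL, health_states()))
  structure(m, arm = arm, class = c("cohort_trace", "matrix", "array"))
}

set_param <- function(tab, name, mean = NULL, se = NULL) {
  i <- match(name, tab$name)
  if (!is.null(mean)) tab$mean[i] <- mean
  if (!is.null(se)) tab$se[i] <- se
  tab
}
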
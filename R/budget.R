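# Five-year governmental budget impact of national coverage.
# All amounts are undiscounted 2017 PHP, per fiscal year, from the budget
# holder's (direct-medical-cost) viewpoint.

#' Eligible population for national coverage
#'
#' HER2-positive early-stage breast cancer cases derived from national
#' totals: `round(cases * her2_rate * early_rate)` for the prevalent pool
#' and the annual incident cohort.
#'
#' @param prevalent_bc national prevalent breast-cancer cases.
#' @param incident_bc national incident breast-cancer cases per year.
#' @param her2_rate HER2-positivity fraction.
#' @param early_rate early-stage fraction among HER2-positive cases.
#' @return list with integer `prevalent` and `incident` counts.
#' @export
#' @examples
#' eligible_population(64046, 21057, 0.2317, 0.80)  # 11,872 and 3,903
eligible_population <- function(prevalent_bc, incident_bc, her2_rate, early_rate) {
  stopifnot(prevalent_bc >= 0, incident_bc >= 0,
            her2_rate >= 0, her2_rate <= 1, early_rate >= 0, early_rate <= 1)
  list(prevalent = round(prevalent_bc * her2_rate * early_rate),
       incident = round(incident_bc * her2_rate * early_rate))
}

#' Drug acquisition cost
#'
#' Total acquisition cost of the trastuzumab drug alone for a covered
#' population: price per treatment course times number of patients.
#'
#' @param price_per_course PHP per patient course.
#' @param n_patients number of patients treated.
#' @return total PHP.
#' @export
drug_acquisition_cost <- function(price_per_course, n_patients) {
  stopifnot(price_per_course >= 0, n_patients >= 0)
  price_per_course * n_patients
}

# undiscounted per-person follow-up (state) cost in each year after
# treatment, from the cohort trace
.follow_up_costs <- function(values, arm, settings, options, years) {
  trace <- run_cohort(values, arm, settings, options)
  cst <- .state_costs(values, "healthcare", options)
  as.numeric(unclass(trace) %*% cst)[seq_len(years)]
}

#' Five-year budget impact of national coverage
#'
#' Projects undiscounted fiscal-year cost streams for treating every
#' eligible HER2-positive early-stage case under each strategy. Year 1
#' treats the full prevalent pool plus that year's incident cases at the
#' treatment-course cost; each later year treats a new incident cohort.
#' From the year after its treatment, every treated cohort accrues
#' follow-up costs taken from its arm's undiscounted cohort-trace state
#' costs, aged by years since treatment. The incremental stream is the
#' element-wise trastuzumab minus chemotherapy difference.
#'
#' @param params a `"param_table"` (epidemiology inputs and costs are taken
#'   from it).
#' @param years number of fiscal years (default 5).
#' @param options a [cua_options()] list.
#' @return object of class `"cua_bia"`: list with the eligible `population`,
#'   a `streams` data frame (per year and strategy: `treatment_cost`,
#'   `follow_up_cost`, `total_cost`) and the `incremental` yearly stream.
#' @export
#' @examples
#' bia <- budget_impact(default_parameters())
#' bia
budget_impact <- function(params, years = 5, options = cua_options()) {
  validate_parameters(params)
  values <- param_means(params)
  settings <- param_settings(params)
  pop <- eligible_population(values[["prevalent_bc"]], values[["incident_bc"]],
                             values[["her2_rate"]], values[["early_rate"]])
  cohort_sizes <- c(pop$prevalent + pop$incident,
                    rep(pop$incident, years - 1))
  streams <- list()
  for (arm in c("trastuzumab", "chemo")) {
    tx <- if (arm == "trastuzumab") values[["dmc_tx_trast"]] else values[["dmc_tx_ct"]]
    fu <- .follow_up_costs(values, arm, settings, options, years)
    treatment <- cohort_sizes * tx
    follow_up <- vapply(seq_len(years), function(y) {
      prior <- seq_len(y - 1)                  # cohorts treated before year y
      sum(cohort_sizes[prior] * fu[y - prior])
    }, numeric(1))
    streams[[arm]] <- data.frame(
      year = seq_len(years), strategy = arm,
      treatment_cost = treatment, follow_up_cost = follow_up,
      total_cost = treatment + follow_up)
  }
  streams <- rbind(streams$trastuzumab, streams$chemo)
  incr <- streams$total_cost[streams$strategy == "trastuzumab"] -
          streams$total_cost[streams$strategy == "chemo"]
  structure(list(population = pop, streams = streams,
                 incremental = data.frame(year = seq_len(years),
                                          incremental_cost = incr)),
            class = "cua_bia")
}

#' @export
print.cua_bia <- function(x, ...) {
  cat(sprintf("Budget impact: %s prevalent + %s incident/yr eligible patients\n",
              format(x$population$prevalent, big.mark = ","),
              format(x$population$incident, big.mark = ",")))
  wide <- data.frame(
    year = x$incremental$year,
    trastuzumab_M = round(x$streams$total_cost[x$streams$strategy == "trastuzumab"] / 1e6),
    chemo_M = round(x$streams$total_cost[x$streams$strategy == "chemo"] / 1e6),
    incremental_M = round(x$incremental$incremental_cost / 1e6))
  print(wide, row.names = FALSE)
  cat("(undiscounted PHP millions)\n")
  invisible(x)
}

#' @export
plot.cua_bia <- function(x, ...) {
  m <- rbind(trastuzumab = x$streams$total_cost[x$streams$strategy == "trastuzumab"],
             chemo = x$streams$total_cost[x$streams$strategy == "chemo"]) / 1e6
  graphics::barplot(m, beside = TRUE, names.arg = paste("Y", x$incremental$year),
                    col = c("darkgreen", "grey60"),
                    ylab = "PHP millions (undiscounted)",
                    main = "Five-year budget impact", ...)
  graphics::legend("topright", rownames(m), fill = c("darkgreen", "grey60"),
                   bty = "n")
  invisible(x)
}
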
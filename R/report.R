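# Reproducible report runner: executes the requested analyses, writes CSV
# tables and plot files to an output directory, and records a manifest
# (seed, package version, settings, options, warnings) sufficient to re-run
# any result.

#' Run analyses and write a report directory
#'
#' Thin orchestration over the analysis functions: runs the requested
#' stages on one parameter table and writes their tabular outputs (CSV),
#' plots (PDF) and a JSON manifest to `outdir`. With the same parameter
#' file, seed and options the written CSVs are identical across runs.
#'
#' @param outdir output directory, created if needed.
#' @param params a `"param_table"` or path to a YAML parameter file.
#' @param what analyses to run, any of `"base"`, `"psa"`, `"dsa"`, `"bia"`,
#'   `"threshold"`.
#' @param n_psa PSA replications.
#' @param seed PSA seed.
#' @param options a [cua_options()] list.
#' @param plots logical; also write PDF figures.
#' @return the manifest, invisibly.
#' @export
run_report <- function(outdir, params = default_parameters(),
                       what = c("base", "psa", "dsa", "bia", "threshold"),
                       n_psa = 50000, seed = 2019, options = cua_options(),
                       plots = TRUE) {
  what <- match.arg(what, several.ok = TRUE)
  if (is.character(params)) params <- read_parameters(params)
  validate_parameters(params)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(outdir, f)
  notes <- character()
  pdf_plot <- function(file, expr) {
    if (!plots) return(invisible())
    grDevices::pdf(out(file), width = 7, height = 5)
    on.exit(grDevices::dev.off())
    force(expr)
  }

  if ("base" %in% what) {
    fit <- cua_model(params, options)
    s <- summary(fit)
    utils::write.csv(s$arms, out("arm_outcomes.csv"), row.names = FALSE)
    cedf <- do.call(rbind, lapply(names(fit$ce), function(p)
      data.frame(perspective = p,
                 delta_cost = fit$ce[[p]]$delta_cost,
                 delta_ly = fit$ce[[p]]$delta_ly,
                 delta_qaly = fit$ce[[p]]$delta_qaly,
                 icer_per_ly = fit$ce[[p]]$icer_per_ly,
                 icer_per_qaly = fit$ce[[p]]$icer_per_qaly)))
    utils::write.csv(cedf, out("ce_results.csv"), row.names = FALSE)
    for (arm in names(fit$trace))
      utils::write.csv(as.data.frame(fit$trace[[arm]]),
                       out(paste0("trace_", arm, ".csv")), row.names = FALSE)
    pdf_plot("traces.pdf", plot(fit))
  }
  if ("psa" %in% what || "threshold" %in% what) lambda <- param_settings(params)$lambda
  if ("psa" %in% what) {
    psa <- run_psa(params, n = n_psa, seed = seed, options = options)
    utils::write.csv(psa$results, out("psa_draws.csv"), row.names = FALSE)
    utils::write.csv(summary(psa), out("psa_summary.csv"), row.names = FALSE)
    cc <- ceac(psa)
    utils::write.csv(as.data.frame(cc), out("ceac.csv"), row.names = FALSE)
    if (psa$resampled > 0)
      notes <- c(notes, sprintf("%d infeasible PSA draw(s) redrawn", psa$resampled))
    pdf_plot("ce_plane.pdf", plot(psa, lambda = lambda))
    pdf_plot("ceac.pdf", plot(cc))
  }
  if ("dsa" %in% what) {
    tor <- one_way_sa(params, options = options)
    utils::write.csv(as.data.frame(tor), out("tornado.csv"), row.names = FALSE)
    tw <- two_way_sa(params, options = options)
    utils::write.csv(as.data.frame(unclass(tw)), out("two_way.csv"))
    pdf_plot("tornado.pdf", plot(tor))
    pdf_plot("two_way.pdf", plot(tw))
  }
  if ("bia" %in% what) {
    bia <- budget_impact(params, options = options)
    utils::write.csv(bia$streams, out("bia_streams.csv"), row.names = FALSE)
    utils::write.csv(bia$incremental, out("bia_incremental.csv"), row.names = FALSE)
    pdf_plot("bia.pdf", plot(bia))
  }
  if ("threshold" %in% what) {
    th <- data.frame(
      perspective = c("healthcare", "societal"),
      lambda = lambda,
      threshold_price = c(
        threshold_price(params, lambda, "healthcare", options),
        threshold_price(params, lambda, "societal", options)))
    utils::write.csv(th, out("threshold_price.csv"), row.names = FALSE)
  }

  cfg <- out("parameters_used.yaml")
  write_parameters(params, cfg)
  manifest <- list(
    package = "adjtrast",
    version = as.character(utils::packageVersion("adjtrast")),
    analyses = what, n_psa = if ("psa" %in% what) n_psa, seed = seed,
    settings = param_settings(params), options = unclass(options),
    parameter_file = basename(cfg),
    parameter_file_md5 = unname(tools::md5sum(cfg)),
    notes = notes)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  invisible(manifest)
}
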
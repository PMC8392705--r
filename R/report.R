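#' Collate stage outputs into a structured report
#'
#' Builds a machine-readable summary (suitable for JSON export) from
#' whichever stages have been run: the base-case incremental table per
#' targeting variant, PSA uncertainty intervals, quadrant proportions and
#' CEAC grid, tornado rankings, and scenario deltas. Sections for absent
#' stages are omitted cleanly. All currency is labelled 2019 A$.
#'
#' @param base_case A `csc_result` from [run_base_case()] (required), or a
#'   named list of them (one per targeting variant).
#' @param psa Optional `csc_psa` from [run_psa()].
#' @param tornado Optional tornado tibble from [tornado()].
#' @param scenarios Optional list of `csc_scenario` objects.
#' @param manifest Optional [run_manifest()].
#' @return A list of class `csc_report`; `print()` renders a plain-text
#'   narrative, [write_report()] exports JSON + CSVs.
#' @export
render_report <- function(base_case, psa = NULL, tornado = NULL,
                          scenarios = NULL, manifest = NULL) {
  if (inherits(base_case, "csc_result")) base_case <- list(base_case)
  stopifnot(length(base_case) >= 1L,
            all(vapply(base_case, inherits, TRUE, "csc_result")))
  bc_row <- function(r) list(
    target = r$target,
    n_eligible = r$n_eligible,
    cost_csc = r$arms$CSC$pathway_cost,
    cost_cau = r$arms$CAU$pathway_cost,
    dalys_averted_csc = r$arms$CSC$dalys_averted,
    dalys_averted_cau = r$arms$CAU$dalys_averted,
    delta_cost_pathway = r$delta_cost_pathway,
    cost_offset = r$cost_offset,
    net_delta_cost = r$net_delta_cost,
    delta_dalys_averted = r$delta_dalys_averted,
    icer = if (r$icer_label == "icer") r$icer else r$icer_label,
    quadrant = r$quadrant
  )
  rep <- list(currency = "2019 A$",
              base_case = lapply(base_case, bc_row))
  if (!is.null(psa)) {
    stopifnot(inherits(psa, "csc_psa"))
    rep$psa <- list(
      n_iterations = psa$n_iterations,
      n_rejected = psa$n_rejected,
      icer = psa$icer_summary,
      ui_net_cost = psa$ui_cost,
      ui_dalys_averted = psa$ui_dalys,
      quadrant_props = as.list(psa$quadrant_props),
      prob_dominated = psa$prob_dominated,
      prob_cost_effective_at_wtp = psa$prob_cost_effective,
      wtp = psa$wtp,
      ceac = psa$ceac
    )
  }
  if (!is.null(tornado)) {
    rep$tornado <- tornado
    rep$tornado_icer_base <- attr(tornado, "icer_base")
  }
  if (!is.null(scenarios)) {
    stopifnot(all(vapply(scenarios, inherits, TRUE, "csc_scenario")))
    rep$scenarios <- lapply(scenarios, function(s) list(
      id = s$scenario$id,
      description = s$scenario$description,
      icer = if (s$result$icer_label == "icer") s$result$icer
             else s$result$icer_label,
      icer_base = if (s$base$icer_label == "icer") s$base$icer
                  else s$base$icer_label
    ))
  }
  if (!is.null(manifest)) rep$manifest <- manifest
  structure(rep, class = "csc_report")
}

#' Write a report to disk as JSON plus plot-ready CSVs
#'
#' Emits `summary.json` (full machine-readable report), `base_case.csv`
#' (one row per targeting variant), and where present `psa_draws.csv`
#' (ΔC, ΔE per iteration, for cost-effectiveness plane plotting),
#' `ceac.csv` and `tornado.csv`.
#'
#' @param report A `csc_report` from [render_report()].
#' @param dir Output directory (created if needed).
#' @param psa Optional `csc_psa`, to export the per-iteration draws.
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(report, dir, psa = NULL) {
  stopifnot(inherits(report, "csc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  emit <- function(name) {
    files[[length(files) + 1L]] <<- file.path(dir, name)
    file.path(dir, name)
  }
  jsonlite::write_json(unclass(report), emit("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  bc <- do.call(rbind, lapply(report$base_case, function(r)
    data.frame(lapply(r, function(v) if (is.null(v)) NA else v))))
  utils::write.csv(bc, emit("base_case.csv"), row.names = FALSE)
  if (!is.null(psa)) {
    utils::write.csv(psa$draws, emit("psa_draws.csv"), row.names = FALSE)
    utils::write.csv(psa$ceac, emit("ceac.csv"), row.names = FALSE)
  }
  if (!is.null(report$tornado))
    utils::write.csv(report$tornado, emit("tornado.csv"), row.names = FALSE)
  invisible(files)
}

#' @export
print.csc_report <- function(x, ...) {
  cat("Cost-utility report (collaborative stepped care v. care-as-usual)\n")
  cat("Currency:", x$currency, "\n\n")
  for (r in x$base_case) {
    icer <- if (is.numeric(r$icer)) sprintf("A$%.0f/DALY", r$icer) else r$icer
    cat(sprintf(
      "  [%s] net incr. cost A$%.0f; incr. DALYs averted %.1f; ICER %s\n",
      r$target, r$net_delta_cost, r$delta_dalys_averted, icer))
  }
  if (!is.null(x$psa)) {
    f <- function(e) if (is.character(e)) e else sprintf("%.0f", e)
    cat(sprintf(
      "\n  PSA (%d iterations): ICER %s (95%% UI: %s to %s)\n",
      x$psa$n_iterations, f(x$psa$icer$point), f(x$psa$icer$lower),
      f(x$psa$icer$upper)))
    cat(sprintf("  P(cost-effective at A$%s/DALY) = %.3f; P(dominated) = %.3f\n",
                format(x$psa$wtp, big.mark = " "),
                x$psa$prob_cost_effective_at_wtp, x$psa$prob_dominated))
  }
  if (!is.null(x$scenarios)) {
    cat("\n  Scenarios:\n")
    for (s in x$scenarios) {
      icer <- if (is.numeric(s$icer)) sprintf("A$%.0f/DALY", s$icer) else s$icer
      cat(sprintf("    %s (%s): ICER %s\n", s$id, s$description, icer))
    }
  }
  invisible(x)
}

#' Record the provenance of a model run
#'
#' A manifest makes a run reproducible from (parameter file, seed,
#' version) alone: it stores the command, an MD5 digest of the parameter
#' file, the seed, a timestamp, the package version and the output paths.
#'
#' @param command Name of the stage that was run.
#' @param parameter_file Path to the parameter file used.
#' @param seed Master seed of the run.
#' @param outputs Character vector of files written.
#' @return A list of class `csc_manifest`.
#' @export
run_manifest <- function(command, parameter_file, seed, outputs = character()) {
  structure(
    list(command = command,
         parameter_file = parameter_file,
         parameter_digest = unname(tools::md5sum(parameter_file)),
         seed = as.integer(seed),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         version = as.character(utils::packageVersion("steppedcea")),
         outputs = outputs),
    class = "csc_manifest"
  )
}
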
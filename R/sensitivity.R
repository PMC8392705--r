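#' Univariate ±10% tornado analysis
#'
#' Re-runs the deterministic base case with each named point estimate
#' scaled to 90% and 110% of its value, all else held fixed, and reports
#' the resulting ICER swing per parameter sorted descending. Uncertainty
#' families are untouched — this is a deterministic univariate design.
#' A perturbed run landing in a dominance quadrant records the label
#' instead of a numeric ICER, carries `NA` swing and sorts last, with a
#' warning.
#'
#' @param params A validated `csc_parameters` object.
#' @param parameter_ids Dotted parameter ids to perturb; defaults to every
#'   addressable point estimate (see [parameter_ids()]).
#' @param factors Length-2 multipliers, default `c(0.9, 1.1)`.
#' @param ... Passed to [run_base_case()].
#' @return A tibble sorted by `swing` (|ICER_high − ICER_low|) descending:
#'   `parameter_id`, `icer_low`, `icer_high`, `label_low`, `label_high`,
#'   `swing`, `relative_change`; the base-case ICER is attached as
#'   attribute `"icer_base"`.
#' @examples
#' params <- generate_parameters(synthetic_config(seed = 1))
#' tornado(params, c("costs.CSC0.unit_cost", "weights.dw_background"))
#' @export
tornado <- function(params, parameter_ids = NULL, factors = c(0.9, 1.1),
                    ...) {
  validate_parameters(params)
  stopifnot(length(factors) == 2L, all(factors > 0))
  if (is.null(parameter_ids)) parameter_ids <- parameter_ids(params)
  base <- run_base_case(params, validate = FALSE, ...)
  if (base$icer_label != "icer")
    stop("tornado requires a numeric base-case ICER (got '",
         base$icer_label, "')", call. = FALSE)

  one <- function(id, f) {
    scaled <- suppressWarnings(scale_parameter(params, id, f))
    run_base_case(scaled, validate = FALSE, ...)
  }
  k <- length(parameter_ids)
  icer_lo <- icer_hi <- numeric(k)
  lab_lo <- lab_hi <- character(k)
  for (i in seq_len(k)) {
    r_lo <- one(parameter_ids[i], factors[1])
    r_hi <- one(parameter_ids[i], factors[2])
    icer_lo[i] <- r_lo$icer; lab_lo[i] <- r_lo$icer_label
    icer_hi[i] <- r_hi$icer; lab_hi[i] <- r_hi$icer_label
  }
  labelled <- lab_lo != "icer" | lab_hi != "icer"
  if (any(labelled))
    warning(sum(labelled), " perturbed run(s) produced a dominance label; ",
            "their swing is undefined and they sort last", call. = FALSE)
  swing <- ifelse(labelled, NA_real_, abs(icer_hi - icer_lo))
  rel <- ifelse(labelled, NA_real_,
                pmax(abs(icer_lo - base$icer),
                     abs(icer_hi - base$icer)) / abs(base$icer))
  out <- tibble::tibble(parameter_id = parameter_ids,
                        icer_low = icer_lo, icer_high = icer_hi,
                        label_low = lab_lo, label_high = lab_hi,
                        swing = swing, relative_change = rel)
  out <- out[order(-ifelse(is.na(out$swing), -Inf, out$swing)), ]
  attr(out, "icer_base") <- base$icer
  out
}

#' Specify a scenario analysis
#'
#' Two named scenarios mirror the model's sensitivity design: `SA1`
#' excludes cost offsets from the net incremental cost, and `SA2` adds
#' patient time and travel costs to both arms. `custom` applies only the
#' supplied parameter overrides.
#'
#' @param id `"SA1"`, `"SA2"` or `"custom"`.
#' @param description Free-text description.
#' @param overrides Named list of parameter overrides, dotted id →
#'   multiplicative factor, applied via [scale_parameter()].
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(id = c("SA1", "SA2", "custom"),
                          description = NULL, overrides = list()) {
  id <- match.arg(id)
  structure(
    list(id = id,
         description = description %||% switch(
           id,
           SA1 = "exclude cost offsets",
           SA2 = "include patient time and travel costs",
           custom = "custom parameter overrides"),
         overrides = overrides),
    class = "scenario_spec"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario analysis against the base case
#'
#' Applies the scenario's structural edits (and any parameter overrides)
#' and re-runs the deterministic pipeline; the input parameter set is
#' never mutated. `SA2` requires a `TIME_TRAVEL` cost item.
#'
#' @param params A validated `csc_parameters` object.
#' @param scenario A [scenario_spec()].
#' @param ... Passed to [run_base_case()].
#' @return A list of class `csc_scenario`: `scenario`, `result` (the
#'   scenario `csc_result`) and `base` (the unmodified base case).
#' @examples
#' params <- generate_parameters(synthetic_config(seed = 1))
#' run_scenario(params, scenario_spec("SA1"))
#' @export
run_scenario <- function(params, scenario, ...) {
  stopifnot(inherits(scenario, "scenario_spec"))
  validate_parameters(params)
  p <- params
  for (id in names(scenario$overrides))
    p <- scale_parameter(p, id, scenario$overrides[[id]])
  validate_mode <- if (length(scenario$overrides)) "scaled" else FALSE
  if (scenario$id == "SA2" && is.null(p$costs$TIME_TRAVEL))
    stop("scenario SA2 requires a TIME_TRAVEL cost item", call. = FALSE)
  result <- run_base_case(
    p,
    include_offsets = scenario$id != "SA1",
    include_time_travel = scenario$id == "SA2",
    validate = validate_mode, ...
  )
  structure(
    list(scenario = scenario, result = result,
         base = run_base_case(params, validate = FALSE, ...)),
    class = "csc_scenario"
  )
}

#' @export
print.csc_scenario <- function(x, ...) {
  cat(sprintf("<csc_scenario> %s: %s\n", x$scenario$id,
              x$scenario$description))
  cat(sprintf("  base-case ICER: %s | scenario ICER: %s\n",
              format_icer(x$base$icer, x$base$icer_label),
              format_icer(x$result$icer, x$result$icer_label)))
  invisible(x)
}
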
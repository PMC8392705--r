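#' Classify an incremental result on the cost-effectiveness plane
#'
#' Incremental DALYs averted are plotted on the x-axis and net incremental
#' costs on the y-axis, the origin being the comparator. A more effective,
#' more costly intervention (NE) gets a numeric ICER; more effective and
#' no more costly (SE) is "dominant"; less effective and no cheaper (NW)
#' is "dominated"; less effective and cheaper (SW) gets a numeric ICER
#' read against the threshold from the south-west convention. Boundary
#' ties go to the more favourable label (SE over NE, NW kept for
#' dominated). Zero incremental effect yields "equivalent" when costs are
#' also zero, else "indeterminate".
#'
#' @param net_delta_cost Net incremental cost (A$), intervention minus
#'   comparator.
#' @param delta_dalys_averted Incremental DALYs averted.
#' @return A list with `quadrant` (`"NE"`, `"SE"`, `"SW"`, `"NW"` or `NA`
#'   on the ΔE = 0 boundary), `icer` (numeric or `NA`) and `label`
#'   (`"icer"`, `"dominant"`, `"dominated"`, `"indeterminate"` or
#'   `"equivalent"`).
#' @examples
#' classify_icer(100, 0.02)   # NE, ICER 5000
#' classify_icer(-50, 0.01)   # SE, dominant
#' @export
classify_icer <- function(net_delta_cost, delta_dalys_averted) {
  dc <- net_delta_cost
  de <- delta_dalys_averted
  if (!is.finite(dc) || !is.finite(de))
    stop("classify_icer requires finite inputs", call. = FALSE)
  if (de > 0) {
    if (dc > 0) list(quadrant = "NE", icer = dc / de, label = "icer")
    else list(quadrant = "SE", icer = NA_real_, label = "dominant")
  } else if (de < 0) {
    if (dc >= 0) list(quadrant = "NW", icer = NA_real_, label = "dominated")
    else list(quadrant = "SW", icer = dc / de, label = "icer")
  } else {
    if (dc == 0) list(quadrant = NA_character_, icer = NA_real_,
                      label = "equivalent")
    else list(quadrant = NA_character_, icer = NA_real_,
              label = "indeterminate")
  }
}

#' Run the deterministic base-case analysis
#'
#' Executes the full pipeline on point estimates: eligible population by
#' stratum, remission propagation for both arms, healthy-equivalent life
#' years via `(1 - DW) x LY` with background-adjusted weights, pathway
#' costing, cost offsets, and the incremental comparison. Deterministic
#' for fixed parameters.
#'
#' @param params A validated `csc_parameters` object.
#' @param target Targeting variant; defaults to `params$target`.
#' @param remission_model `"conditional"` (default) or `"cumulative"`
#'   reading of the per-interval remission probabilities; see
#'   [propagate_remission()].
#' @param offset_basis Burden measure for cost offsets; see
#'   [compute_cost_offsets()].
#' @param training_mode CSC training amortisation; see
#'   [cost_csc_pathway()].
#' @param include_time_travel Add patient time/travel costs to both arms
#'   (scenario SA2).
#' @param include_offsets Include cost offsets in the net incremental cost
#'   (disabled under scenario SA1).
#' @param validate Revalidate `params` before running; internal callers
#'   that perturb a single point estimate pass `"scaled"` to skip the
#'   sum-to-1 checks.
#' @return An object of class `csc_result`: per-arm summaries
#'   (`arms$<arm>$pathway_cost`, `dalys_averted`, ...), the strata and
#'   propagated trajectories, and the incremental fields
#'   `delta_cost_pathway`, `cost_offset`, `net_delta_cost`,
#'   `delta_dalys_averted`, `icer`, `icer_label`, `quadrant`.
#' @examples
#' params <- generate_parameters(synthetic_config(seed = 1))
#' run_base_case(params)
#' @export
run_base_case <- function(params, target = params$target,
                          remission_model = "conditional",
                          offset_basis = "person_years",
                          training_mode = "per_person",
                          include_time_travel = FALSE,
                          include_offsets = TRUE,
                          validate = TRUE) {
  if (isTRUE(validate)) validate_parameters(params)
  else if (identical(validate, "scaled"))
    validate_parameters(params, strict_sums = FALSE)

  strata <- build_eligible_population(params, target)
  traj_csc <- propagate_arm(strata, params, "CSC", remission_model)
  traj_cau <- propagate_arm(strata, params, "CAU", remission_model)

  cost_csc <- cost_csc_pathway(traj_csc, params, training_mode,
                               include_time_travel)
  cost_cau <- cost_cau_pathway(traj_cau, params, include_time_travel)

  dalys_csc <- arm_dalys_averted(traj_csc, params)
  dalys_cau <- arm_dalys_averted(traj_cau, params)

  offset <- if (include_offsets)
    compute_cost_offsets(traj_csc, traj_cau, params, offset_basis)
  else 0
  delta_pathway <- (cost_csc$pathway_cost + cost_csc$time_travel_cost) -
    (cost_cau$pathway_cost + cost_cau$time_travel_cost)
  net_dc <- delta_pathway + offset
  de <- dalys_csc - dalys_cau
  cls <- classify_icer(net_dc, de)

  structure(
    list(
      target = target,
      wtp = params$wtp,
      n_eligible = sum(strata$n_persons),
      strata = strata,
      trajectories = list(CSC = traj_csc, CAU = traj_cau),
      arms = list(
        CSC = list(pathway_cost = cost_csc$pathway_cost,
                   cost_by_category = cost_csc$cost_by_category,
                   time_travel_cost = cost_csc$time_travel_cost,
                   unremitted_treatment_cost =
                     cost_csc$unremitted_treatment_cost,
                   dalys_averted = dalys_csc),
        CAU = list(pathway_cost = cost_cau$pathway_cost,
                   cost_by_category = cost_cau$cost_by_category,
                   time_travel_cost = cost_cau$time_travel_cost,
                   unremitted_treatment_cost =
                     cost_cau$unremitted_treatment_cost,
                   dalys_averted = dalys_cau)
      ),
      delta_cost_pathway = delta_pathway,
      cost_offset = offset,
      net_delta_cost = net_dc,
      delta_dalys_averted = de,
      icer = cls$icer,
      icer_label = cls$label,
      quadrant = cls$quadrant
    ),
    class = "csc_result"
  )
}

format_icer <- function(icer, label) {
  if (label == "icer") sprintf("A$%.0f/DALY", icer) else label
}

#' @export
print.csc_result <- function(x, ...) {
  cat("<csc_result> base-case incremental analysis (2019 A$)\n")
  cat(sprintf("  target: %s | eligible persons: %.0f\n",
              x$target, x$n_eligible))
  cat(sprintf("  pathway cost     CSC A$%.0f | CAU A$%.0f\n",
              x$arms$CSC$pathway_cost, x$arms$CAU$pathway_cost))
  cat(sprintf("  DALYs averted    CSC %.1f | CAU %.1f\n",
              x$arms$CSC$dalys_averted, x$arms$CAU$dalys_averted))
  cat(sprintf("  net incr. cost A$%.0f (pathway %.0f + offsets %.0f)\n",
              x$net_delta_cost, x$delta_cost_pathway, x$cost_offset))
  cat(sprintf("  incr. DALYs averted %.1f\n", x$delta_dalys_averted))
  cat(sprintf("  ICER: %s [%s]\n", format_icer(x$icer, x$icer_label),
              ifelse(is.na(x$quadrant), "boundary", x$quadrant)))
  invisible(x)
}
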
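# Pathway costing. Both arms reduce to: persons per branch x unit cost x
# quantity x coverage per cost item, with training (CSC0) and the
# benzodiazepine add-ons (CSC9/CAU9) applied across all treated persons.

item_cost <- function(item, persons) {
  item$unit_cost$point * item$quantity * item$coverage * persons
}

# Persons per cost category for one arm. CSC: mild -> step 1a, moderate ->
# step 1b, severe -> step 2 directly; mild/moderate non-remitters at 4
# months step up; step-2 entrants split over 2a/2b/2c by the allocation.
# CAU: baseline split over CAU1/CAU2/CAU3 held fixed over the 8 months.
branch_persons <- function(traj, params, arm) {
  total <- sum(traj$n_persons)
  if (arm == "CSC") {
    n_mild <- sum(traj$n_persons[traj$severity == "mild"])
    n_mod <- sum(traj$n_persons[traj$severity == "moderate"])
    n_sev <- sum(traj$n_persons[traj$severity == "severe"])
    n_step2 <- n_sev + sum(traj$n_stepup)
    split <- vapply(csc_step2_categories,
                    function(k) params$allocations$CSC$step2[[k]]$point, 0)
    c(CSC0 = total, CSC1a = n_mild, CSC1b = n_mod,
      stats::setNames(n_step2 * split, csc_step2_categories), CSC9 = total)
  } else {
    split <- vapply(cau_branch_categories,
                    function(k) params$allocations$CAU$branches[[k]]$point, 0)
    c(stats::setNames(total * split, cau_branch_categories), CAU9 = total)
  }
}

arm_cost_result <- function(traj, params, arm, training_mode, include_tt) {
  persons <- branch_persons(traj, params, arm)
  by_cat <- vapply(names(persons), function(cat)
    item_cost(params$costs[[cat]], persons[[cat]]), 0)
  if (arm == "CSC" && training_mode == "fixed_program") {
    it <- params$costs$CSC0
    by_cat[["CSC0"]] <- it$unit_cost$point * it$quantity * it$coverage
  }
  offset_item <- params$costs$OFFSET_ANNUAL
  annual_per_case <- offset_item$unit_cost$point * offset_item$quantity *
    offset_item$coverage
  tt <- 0
  if (include_tt) {
    if (is.null(params$costs$TIME_TRAVEL))
      stop("time/travel scenario enabled but no TIME_TRAVEL cost item ",
           "is configured", call. = FALSE)
    tt_it <- params$costs$TIME_TRAVEL
    visits <- vapply(names(persons),
                     function(cat) params$costs[[cat]]$visits, 0)
    tt <- tt_it$unit_cost$point * tt_it$coverage * sum(visits * persons)
  }
  structure(
    list(arm = arm,
         pathway_cost = sum(by_cat),
         cost_by_category = by_cat,
         unremitted_treatment_cost = annual_per_case * sum(traj$ly_unremitted),
         time_travel_cost = tt),
    class = "csc_arm_cost"
  )
}

#' Cost the collaborative stepped care pathway
#'
#' Costs the CSC arm over its 8-month delivery period: mild strata receive
#' guided self-help (CSC1a), moderate strata guided self-help plus
#' antidepressants (CSC1b), severe strata enter specialised care (step 2)
#' from month 0, and mild/moderate non-remitters at 4 months step up to
#' step 2, with step-2 entrants split over antidepressants, psychotherapy
#' or both (CSC2a/2b/2c) by the allocation proportions. Provider training
#' (CSC0) is amortised per treated person under steady-state conditions
#' (or charged once as a fixed programme cost), and the benzodiazepine
#' add-on (CSC9) applies to its coverage proportion of all patients.
#'
#' @param traj Propagated CSC-arm strata from the internal arm propagation
#'   (the tibble produced inside [run_base_case()]); must carry
#'   `n_persons`, `severity`, `n_stepup` and `ly_unremitted` columns.
#' @param params A `csc_parameters` object.
#' @param training_mode `"per_person"` (default: CSC0 unit cost is per
#'   treated person) or `"fixed_program"` (a single lump sum).
#' @param include_time_travel Add patient time and travel costs (scenario
#'   SA2); requires a `TIME_TRAVEL` cost item.
#' @return A `csc_arm_cost` list: `pathway_cost`, `cost_by_category`,
#'   `unremitted_treatment_cost` (annual treatment cost attributed to the
#'   arm's unremitted person-years, the basis of cost offsets) and
#'   `time_travel_cost` (0 unless enabled).
#' @export
cost_csc_pathway <- function(traj, params, training_mode = "per_person",
                             include_time_travel = FALSE) {
  stopifnot(all(traj$arm == "CSC"))
  arm_cost_result(traj, params, "CSC", training_mode, include_time_travel)
}

#' Cost the care-as-usual pathway
#'
#' Splits the treated population across antidepressants only (CAU1),
#' specialised mental healthcare (CAU2) and no treatment (CAU3, which
#' absorbs dropouts) by the CAU allocation proportions, plus the
#' benzodiazepine add-on (CAU9).
#'
#' @inheritParams cost_csc_pathway
#' @param traj Propagated CAU-arm strata.
#' @return A `csc_arm_cost` list; see [cost_csc_pathway()].
#' @export
cost_cau_pathway <- function(traj, params, include_time_travel = FALSE) {
  stopifnot(all(traj$arm == "CAU"))
  arm_cost_result(traj, params, "CAU", "per_person", include_time_travel)
}

#' Treatment cost offsets from averted unremitted person-time
#'
#' The offset is the difference in annual treatment costs attributed to
#' unremitted cases between the arms:
#' `annual_cost_per_case * (burden_CSC - burden_CAU)`, negative when the
#' intervention leaves fewer unremitted person-years. The default burden
#' measure is unremitted person-years from the AUC engine; the
#' `"cases_12m"` alternative uses cases still unremitted at 12 months.
#'
#' @param traj_csc,traj_cau Propagated strata for the two arms, built on
#'   identical strata.
#' @param params A `csc_parameters` object (supplies the `OFFSET_ANNUAL`
#'   cost item).
#' @param offset_basis `"person_years"` (default) or `"cases_12m"`.
#' @return Offset in 2019 A$ (sign carries direction).
#' @export
compute_cost_offsets <- function(traj_csc, traj_cau, params,
                                 offset_basis = c("person_years",
                                                  "cases_12m")) {
  offset_basis <- match.arg(offset_basis)
  if (nrow(traj_csc) != nrow(traj_cau) ||
      !all(traj_csc$disorder == traj_cau$disorder) ||
      !all(traj_csc$severity == traj_cau$severity) ||
      !all(abs(traj_csc$n_persons - traj_cau$n_persons) < 1e-9))
    stop("cost offsets require both arms on identical strata",
         call. = FALSE)
  it <- params$costs$OFFSET_ANNUAL
  annual <- it$unit_cost$point * it$quantity * it$coverage
  burden <- function(traj) {
    if (offset_basis == "person_years") sum(traj$ly_unremitted)
    else sum(traj$n_persons - traj$remitted_12m)
  }
  annual * (burden(traj_csc) - burden(traj_cau))
}

#' Patient time and travel costs for one arm
#'
#' Values the clinic visits of every pathway branch at the `TIME_TRAVEL`
#' per-visit unit cost: `unit_cost * sum over branches of visits x
#' persons`. Excluded from the base case; added to both arms under
#' scenario SA2.
#'
#' @param traj Propagated strata for the arm.
#' @param params A `csc_parameters` object with a `TIME_TRAVEL` item.
#' @param arm `"CSC"` or `"CAU"`.
#' @return Time and travel cost in 2019 A$.
#' @export
compute_time_travel_costs <- function(traj, params, arm = traj$arm[1]) {
  if (is.null(params$costs$TIME_TRAVEL))
    stop("time/travel scenario enabled but no TIME_TRAVEL cost item ",
         "is configured", call. = FALSE)
  persons <- branch_persons(traj, params, arm)
  visits <- vapply(names(persons), function(cat) params$costs[[cat]]$visits, 0)
  it <- params$costs$TIME_TRAVEL
  it$unit_cost$point * it$coverage * sum(visits * persons)
}
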
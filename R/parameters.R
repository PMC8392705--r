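#' Assemble a complete model parameter set
#'
#' The parameter set drives every stage of the cost-utility model: cohort
#' construction, remission propagation, disability weighting, pathway
#' costing, incremental analysis and the probabilistic sensitivity analysis.
#' All proportions/probabilities and unit costs are [uncertain_value()]s;
#' the base case uses their points, the PSA draws from their families.
#'
#' @param cohorts List of cohorts, each a list with `age_group`, `sex`
#'   (`"female"`/`"male"`), `population` (2019 person count),
#'   `gp_mh_consult_prop` (uncertain proportion who consulted a GP for
#'   mental health in the past year), `prevalence` (list of uncertain
#'   proportions by disorder) and `severity_split` (per disorder, uncertain
#'   mild/moderate/severe proportions summing to 1).
#' @param remission Nested list `remission[[arm]][[disorder]]`, arms
#'   `"CSC"`/`"CAU"`, disorders `"depression"`/`"anxiety"`; each a list of
#'   exactly three uncertain per-interval remission probabilities
#'   (0–4, 4–8, 8–12 months, conditional on being unremitted at entry).
#' @param weights List with `dw_unremitted[[disorder]][[severity]]`,
#'   `dw_remitted` (residual weight of the remitted state) and
#'   `dw_background` (background-morbidity weight), all uncertain weights
#'   in \[0, 1).
#' @param costs Named list of pathway cost items keyed by category id
#'   (`CSC0`, `CSC1a`, `CSC1b`, `CSC2a`, `CSC2b`, `CSC2c`, `CSC9`, `CAU1`,
#'   `CAU2`, `CAU3`, `CAU9`, `OFFSET_ANNUAL`, optionally `TIME_TRAVEL`),
#'   each a list with `unit_cost` (uncertain 2019 A$), `quantity` (units
#'   per treated person), `coverage` (proportion of the branch receiving
#'   the item) and `visits` (clinic visits per person in the branch, used
#'   only by the patient time/travel scenario layer).
#' @param allocations List with `CSC$step2` (uncertain split of step-2
#'   entrants over `CSC2a`/`CSC2b`/`CSC2c`) and `CAU$branches` (uncertain
#'   split over `CAU1`/`CAU2`/`CAU3`); each set sums to 1.
#' @param wtp Willingness-to-pay threshold in A$ per DALY averted.
#' @param n_iterations Monte Carlo iterations for the PSA.
#' @param seed Master seed for the PSA.
#' @param target Disorder targeting variant: `"both"`, `"depression_only"`
#'   or `"anxiety_only"`.
#' @param horizon_years Analytic horizon; the model is defined for 1 year.
#'
#' @return A validated object of class `csc_parameters`.
#' @seealso [generate_parameters()] for a complete synthetic set,
#'   [load_parameters()] / [write_parameters()] for file I/O.
#' @export
model_parameters <- function(cohorts, remission, weights, costs, allocations,
                             wtp = 50000, n_iterations = 3000, seed = 42L,
                             target = "both", horizon_years = 1) {
  params <- structure(
    list(
      schema_version = "steppedcea-1",
      target = target,
      wtp = wtp,
      horizon_years = horizon_years,
      n_iterations = as.integer(n_iterations),
      seed = as.integer(seed),
      cohorts = cohorts,
      remission = remission,
      weights = weights,
      costs = costs,
      allocations = allocations
    ),
    class = "csc_parameters"
  )
  validate_parameters(params)
  params
}

model_arms <- c("CSC", "CAU")
model_disorders <- c("depression", "anxiety")
model_severities <- c("mild", "moderate", "severe")
csc_step1_categories <- c(mild = "CSC1a", moderate = "CSC1b")
csc_step2_categories <- c("CSC2a", "CSC2b", "CSC2c")
cau_branch_categories <- c("CAU1", "CAU2", "CAU3")
required_cost_categories <- c(
  "CSC0", "CSC1a", "CSC1b", csc_step2_categories, "CSC9",
  cau_branch_categories, "CAU9", "OFFSET_ANNUAL"
)

fail_schema <- function(field) {
  stop(sprintf("parameter schema error: missing field '%s'", field),
       call. = FALSE)
}

fail_valid <- function(type, field, msg) {
  stop(sprintf("parameter validation error: %s.%s %s", type, field, msg),
       call. = FALSE)
}

check_prop <- function(x, type, field, upper_open = FALSE) {
  if (!is_uncertain_value(x)) fail_schema(paste0(type, ".", field))
  validate_uncertain_value(x, paste(type, field))
  if (x$point < 0 || x$point > 1 || (upper_open && x$point >= 1))
    fail_valid(type, field,
               sprintf("value %g outside %s", x$point,
                       if (upper_open) "[0, 1)" else "[0, 1]"))
  invisible(x)
}

#' Validate a model parameter set
#'
#' Checks every structural and numeric invariant of the parameter schema:
#' proportions in \[0, 1\], severity splits and allocation sets summing to
#' 1 (within 1e-9), exactly one remission schedule of three intervals per
#' arm and disorder, disability weights in \[0, 1) with the remitted-state
#' weight no larger than any unremitted weight, non-negative costs and
#' quantities, and a positive willingness-to-pay threshold.
#'
#' @param params A `csc_parameters` object (or plain list with the schema).
#' @param strict_sums If `FALSE`, the sum-to-1 checks on severity splits
#'   and allocations are skipped. Used internally when a single point
#'   estimate has been deliberately perturbed (tornado analysis), which
#'   necessarily unbalances its proportion set.
#' @return `params`, invisibly; errors name the violated field.
#' @export
validate_parameters <- function(params, strict_sums = TRUE) {
  for (f in c("schema_version", "target", "wtp", "horizon_years",
              "n_iterations", "seed", "cohorts", "remission", "weights",
              "costs", "allocations"))
    if (is.null(params[[f]])) fail_schema(f)

  if (!params$target %in% c("both", "depression_only", "anxiety_only"))
    fail_valid("ModelParameters", "target",
               sprintf("'%s' not one of both/depression_only/anxiety_only",
                       params$target))
  if (!is.numeric(params$wtp) || params$wtp <= 0)
    fail_valid("ModelParameters", "wtp", "must be > 0")
  if (params$horizon_years != 1)
    fail_valid("ModelParameters", "horizon_years", "model is 1-year only")
  if (params$n_iterations < 1 ||
      params$n_iterations != round(params$n_iterations))
    fail_valid("ModelParameters", "n_iterations",
               "must be a positive integer")

  if (length(params$cohorts) == 0L)
    fail_valid("ModelParameters", "cohorts", "must be non-empty")
  for (i in seq_along(params$cohorts)) {
    co <- params$cohorts[[i]]
    tag <- sprintf("CohortSpec[%d]", i)
    for (f in c("age_group", "sex", "population", "gp_mh_consult_prop",
                "prevalence", "severity_split"))
      if (is.null(co[[f]])) fail_schema(paste0(tag, ".", f))
    if (!co$sex %in% c("female", "male"))
      fail_valid(tag, "sex", sprintf("'%s' not female/male", co$sex))
    if (!is.numeric(co$population) || co$population < 0)
      fail_valid(tag, "population", "must be >= 0")
    check_prop(co$gp_mh_consult_prop, tag, "gp_mh_consult_prop")
    for (d in model_disorders) {
      check_prop(co$prevalence[[d]], tag, paste0("prevalence.", d))
      sp <- co$severity_split[[d]]
      if (is.null(sp)) fail_schema(paste0(tag, ".severity_split.", d))
      for (s in model_severities)
        check_prop(sp[[s]], tag, paste0("severity_split.", d, ".", s))
      tot <- sum(vapply(model_severities, function(s) sp[[s]]$point, 0))
      if (strict_sums && abs(tot - 1) > 1e-9)
        fail_valid(tag, paste0("severity_split.", d),
                   sprintf("sums to %g", tot))
    }
  }

  for (arm in model_arms) for (d in model_disorders) {
    sched <- params$remission[[arm]][[d]]
    tag <- sprintf("RemissionSchedule[%s,%s]", arm, d)
    if (is.null(sched)) fail_schema(tag)
    if (length(sched) != 3L)
      fail_valid(tag, "p_interval",
                 sprintf("has %d intervals, expected 3", length(sched)))
    for (t in 1:3) check_prop(sched[[t]], tag, paste0("p_interval.", t))
  }

  w <- params$weights
  for (f in c("dw_unremitted", "dw_remitted", "dw_background"))
    if (is.null(w[[f]])) fail_schema(paste0("DisabilityWeights.", f))
  check_prop(w$dw_remitted, "DisabilityWeights", "dw_remitted",
             upper_open = TRUE)
  check_prop(w$dw_background, "DisabilityWeights", "dw_background",
             upper_open = TRUE)
  for (d in model_disorders) {
    for (s in model_severities)
      check_prop(w$dw_unremitted[[d]][[s]], "DisabilityWeights",
                 paste0("dw_unremitted.", d, ".", s), upper_open = TRUE)
    min_dw <- min(vapply(model_severities,
                         function(s) w$dw_unremitted[[d]][[s]]$point, 0))
    if (w$dw_remitted$point > min_dw + 1e-12)
      fail_valid("DisabilityWeights", "dw_remitted",
                 sprintf("%g exceeds min unremitted weight %g for %s",
                         w$dw_remitted$point, min_dw, d))
  }

  for (cat in required_cost_categories)
    if (is.null(params$costs[[cat]]))
      fail_schema(paste0("PathwayCostItem.", cat))
  for (cat in names(params$costs)) {
    it <- params$costs[[cat]]
    tag <- sprintf("PathwayCostItem[%s]", cat)
    if (!is_uncertain_value(it$unit_cost)) fail_schema(paste0(tag, ".unit_cost"))
    validate_uncertain_value(it$unit_cost, paste0(tag, ".unit_cost"))
    if (it$unit_cost$point < 0)
      fail_valid(tag, "unit_cost", "must be >= 0")
    if (is.null(it$quantity) || it$quantity < 0)
      fail_valid(tag, "quantity", "must be >= 0")
    if (is.null(it$coverage) || it$coverage < 0 || it$coverage > 1)
      fail_valid(tag, "coverage", "must be in [0, 1]")
    if (is.null(it$visits) || it$visits < 0)
      fail_valid(tag, "visits", "must be >= 0")
  }

  al <- params$allocations
  if (is.null(al$CSC$step2)) fail_schema("PathwayAllocation.CSC.step2")
  if (is.null(al$CAU$branches)) fail_schema("PathwayAllocation.CAU.branches")
  for (spec in list(list(set = al$CSC$step2, keys = csc_step2_categories,
                         tag = "PathwayAllocation[CSC]", field = "step2"),
                    list(set = al$CAU$branches, keys = cau_branch_categories,
                         tag = "PathwayAllocation[CAU]", field = "branches"))) {
    for (k in spec$keys)
      check_prop(spec$set[[k]], spec$tag, paste0(spec$field, ".", k))
    tot <- sum(vapply(spec$keys, function(k) spec$set[[k]]$point, 0))
    if (strict_sums && abs(tot - 1) > 1e-9)
      fail_valid(spec$tag, spec$field, sprintf("sums to %g", tot))
  }

  invisible(params)
}

# ---- serialisation ----------------------------------------------------------

pack_node <- function(x) {
  if (is_uncertain_value(x))
    list(point = x$point, family = x$family,
         params = if (length(x$params)) x$params else NULL)
  else if (is.list(x)) lapply(x, pack_node)
  else x
}

unpack_node <- function(x) {
  if (is.list(x)) {
    nm <- names(x)
    if (!is.null(nm) && all(c("point", "family") %in% nm) &&
        is.character(x$family) && x$family %in% uv_families) {
      ps <- x$params
      return(uncertain_value(x$point, x$family,
                             if (is.null(ps)) list() else lapply(ps, as.numeric)))
    }
    lapply(x, unpack_node)
  } else x
}

params_to_json <- function(params) {
  jsonlite::toJSON(pack_node(unclass(params)), auto_unbox = TRUE,
                   digits = NA, null = "null", pretty = TRUE)
}

#' Write a parameter set to a JSON parameter file
#'
#' The file is a structured UTF-8 text document with named sections
#' mirroring the parameter schema (cohorts, remission, weights, costs,
#' allocations) and a `schema_version` string. Doubles are written at full
#' precision so that [load_parameters()] round-trips the set exactly.
#'
#' @param params A validated `csc_parameters` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  writeLines(params_to_json(params), path, useBytes = TRUE)
  invisible(path)
}

#' Read and validate a parameter file
#'
#' @param path Path to a JSON parameter file written by [write_parameters()]
#'   (or assembled by hand to the same schema).
#' @return A validated `csc_parameters` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  params <- structure(unpack_node(raw), class = "csc_parameters")
  for (f in c("wtp", "horizon_years"))
    if (!is.null(params[[f]])) params[[f]] <- as.numeric(params[[f]])
  for (f in c("n_iterations", "seed"))
    if (!is.null(params[[f]])) params[[f]] <- as.integer(params[[f]])
  for (i in seq_along(params$cohorts))
    params$cohorts[[i]]$population <-
      as.numeric(params$cohorts[[i]]$population)
  validate_parameters(params)
  params
}

#' @export
print.csc_parameters <- function(x, ...) {
  cat("<csc_parameters>", x$schema_version, "\n")
  cat(sprintf("  target: %s | WTP: A$%s/DALY | horizon: %g y\n",
              x$target, format(x$wtp, big.mark = " "), x$horizon_years))
  cat(sprintf("  cohorts: %d | cost items: %d | PSA: %d iterations, seed %d\n",
              length(x$cohorts), length(x$costs), x$n_iterations, x$seed))
  invisible(x)
}

# ---- dotted-path addressing -------------------------------------------------

split_path <- function(id) strsplit(id, ".", fixed = TRUE)[[1]]

path_get <- function(x, parts, id) {
  for (p in parts) {
    if (!is.list(x)) stop("unknown parameter id: ", id, call. = FALSE)
    idx <- suppressWarnings(as.integer(p))
    x <- if (!is.na(idx) && !(p %in% names(x))) x[[idx]] else x[[p]]
    if (is.null(x)) stop("unknown parameter id: ", id, call. = FALSE)
  }
  x
}

path_set <- function(x, parts, value) {
  p <- parts[[1]]
  idx <- suppressWarnings(as.integer(p))
  key <- if (!is.na(idx) && !(p %in% names(x))) idx else p
  if (length(parts) == 1L) x[[key]] <- value
  else x[[key]] <- path_set(x[[key]], parts[-1], value)
  x
}

# locations whose point estimates are probabilities/proportions/weights and
# must stay inside the unit interval when perturbed
prob_path_regex <- paste0(
  "(^|\\.)(gp_mh_consult_prop|prevalence|severity_split|coverage|",
  "dw_unremitted|dw_remitted|dw_background)(\\.|$)|^remission\\.|^allocations\\.")

#' Multiply one point estimate by a factor
#'
#' Addresses a single stored value by its dotted path — for example
#' `"costs.CSC1a.unit_cost"`, `"remission.CSC.depression.1"`,
#' `"cohorts.1.prevalence.depression"` or
#' `"allocations.CAU.branches.CAU1"` — and returns a copy of the parameter
#' set with that point estimate multiplied by `factor`. Everything else,
#' including the uncertainty families, is untouched. Probabilities,
#' proportions and disability weights are clipped back into the unit
#' interval with a warning when the scaling pushes them out. This is the
#' primitive behind the ±10% tornado analysis.
#'
#' @param params A `csc_parameters` object.
#' @param parameter_id Dotted path naming exactly one point estimate; see
#'   [parameter_ids()] for the full list.
#' @param factor Positive multiplier.
#' @return A modified copy of `params`. Note a perturbed proportion leaves
#'   its sum-to-1 set deliberately unbalanced; downstream runs on scaled
#'   sets validate with `strict_sums = FALSE`.
#' @export
scale_parameter <- function(params, parameter_id, factor) {
  stopifnot(is.numeric(factor), length(factor) == 1L, factor > 0)
  parts <- split_path(parameter_id)
  node <- path_get(params, parts, parameter_id)
  is_prob <- grepl(prob_path_regex, parameter_id)
  clip <- function(v, open_top) {
    hi <- if (open_top) 1 - 1e-12 else 1
    if (v < 0 || v > hi) {
      warning(sprintf("'%s' scaled to %g; clipped to [0, %g]",
                      parameter_id, v, hi), call. = FALSE)
      v <- min(max(v, 0), hi)
    }
    v
  }
  open_top <- grepl("(^|\\.)dw_", parameter_id)
  if (is_uncertain_value(node)) {
    node$point <- node$point * factor
    if (is_prob || node$family == "beta")
      node$point <- clip(node$point, open_top)
  } else if (is.numeric(node) && length(node) == 1L) {
    node <- node * factor
    if (is_prob) node <- clip(node, open_top)
  } else {
    stop("parameter id does not address a scalar point estimate: ",
         parameter_id, call. = FALSE)
  }
  path_set(params, parts, node)
}

#' Enumerate the addressable point estimates of a parameter set
#'
#' Returns every dotted path accepted by [scale_parameter()]: all uncertain
#' values (remission probabilities, prevalences, severity splits, disability
#' weights, unit costs, allocation proportions) plus the plain numeric
#' leaves (cohort populations, cost quantities/coverages/visit counts and
#' the WTP threshold). This is the default parameter list for [tornado()].
#'
#' @param params A `csc_parameters` object.
#' @return Character vector of dotted parameter ids.
#' @export
parameter_ids <- function(params) {
  ids <- character()
  walk <- function(x, prefix) {
    if (is_uncertain_value(x)) {
      ids[[length(ids) + 1L]] <<- prefix
    } else if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) {
        key <- if (is.null(nm) || nm[i] == "") as.character(i) else nm[i]
        walk(x[[i]], paste0(prefix, ".", key))
      }
    }
  }
  for (i in seq_along(params$cohorts)) {
    pre <- paste0("cohorts.", i)
    ids <- c(ids, paste0(pre, ".population"))
    walk(params$cohorts[[i]]$gp_mh_consult_prop,
         paste0(pre, ".gp_mh_consult_prop"))
    walk(params$cohorts[[i]]$prevalence, paste0(pre, ".prevalence"))
    walk(params$cohorts[[i]]$severity_split, paste0(pre, ".severity_split"))
  }
  walk(params$remission, "remission")
  walk(params$weights, "weights")
  for (cat in names(params$costs)) {
    pre <- paste0("costs.", cat)
    walk(params$costs[[cat]]$unit_cost, paste0(pre, ".unit_cost"))
    ids <- c(ids, paste0(pre, ".quantity"), paste0(pre, ".coverage"),
             paste0(pre, ".visits"))
  }
  walk(params$allocations, "allocations")
  c(ids, "wtp")
}

#' Collapse all uncertainty families to fixed points
#'
#' Useful for degenerate-PSA checks: with every family fixed, all Monte
#' Carlo draws reproduce the base case exactly.
#'
#' @param params A `csc_parameters` object.
#' @return A copy with every [uncertain_value()] replaced by
#'   `uv_fixed(point)`.
#' @export
fix_parameters <- function(params) {
  fix <- function(x) {
    if (is_uncertain_value(x)) uv_fixed(x$point)
    else if (is.list(x)) lapply(x, fix)
    else x
  }
  structure(fix(unclass(params)), class = "csc_parameters")
}
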
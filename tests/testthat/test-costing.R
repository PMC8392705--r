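# 100 depressed persons in one severity class: population 1000, consult 1,
# prevalence 0.1, severity mass on one level, target depression_only.
one_branch_params <- function(severity, ...) {
  sev <- c(mild = 0, moderate = 0, severe = 0)
  sev[severity] <- 1
  toy_params(target = "depression_only",
             prevalence = c(depression = 0.1, anxiety = 0.1),
             severity = sev, ...)
}

csc_traj <- function(params)
  steppedcea:::propagate_arm(build_eligible_population(params), params, "CSC")
cau_traj <- function(params)
  steppedcea:::propagate_arm(build_eligible_population(params), params, "CAU")

test_that("mild patients who all remit at 4 months incur no step-2 cost", {
  params <- one_branch_params(
    "mild", p_csc = c(1, 0, 0),
    costs = list(CSC0 = toy_cost_item(30),
                 CSC1a = toy_cost_item(350),
                 CSC2a = toy_cost_item(999), CSC2b = toy_cost_item(999),
                 CSC2c = toy_cost_item(999),
                 CSC9 = toy_cost_item(40, coverage = 0.2))
  )
  res <- cost_csc_pathway(csc_traj(params), params)
  expect_equal(res$cost_by_category[["CSC1a"]], 100 * 350)
  expect_equal(res$cost_by_category[["CSC0"]], 100 * 30)
  expect_equal(res$cost_by_category[["CSC9"]], 100 * 40 * 0.2)
  expect_equal(sum(res$cost_by_category[c("CSC2a", "CSC2b", "CSC2c")]), 0)
  expect_equal(res$pathway_cost, 100 * (350 + 30 + 40 * 0.2))
})

test_that("severe patients go straight to step 2 with no step-1 cost", {
  params <- one_branch_params(
    "severe", p_csc = c(0.5, 0.5, 0.5),
    step2_split = c(CSC2a = 0.25, CSC2b = 0.4, CSC2c = 0.35),
    costs = list(CSC1a = toy_cost_item(999), CSC1b = toy_cost_item(999),
                 CSC2a = toy_cost_item(250), CSC2b = toy_cost_item(800),
                 CSC2c = toy_cost_item(1000))
  )
  res <- cost_csc_pathway(csc_traj(params), params)
  expect_equal(res$cost_by_category[["CSC1a"]], 0)
  expect_equal(res$cost_by_category[["CSC1b"]], 0)
  expect_equal(res$cost_by_category[["CSC2a"]], 100 * 0.25 * 250)
  expect_equal(res$cost_by_category[["CSC2b"]], 100 * 0.40 * 800)
  expect_equal(res$cost_by_category[["CSC2c"]], 100 * 0.35 * 1000)
})

test_that("mild/moderate non-remitters at 4 months step up", {
  params <- one_branch_params(
    "moderate", p_csc = c(0.3, 0.5, 0.5),
    step2_split = c(CSC2a = 1, CSC2b = 0, CSC2c = 0),
    costs = list(CSC1b = toy_cost_item(430), CSC2a = toy_cost_item(500))
  )
  traj <- csc_traj(params)
  expect_equal(sum(traj$n_stepup), 100 * 0.7) # (1 - p1) x branch n
  res <- cost_csc_pathway(traj, params)
  expect_equal(res$cost_by_category[["CSC1b"]], 100 * 430)
  expect_equal(res$cost_by_category[["CSC2a"]], 70 * 500)
})

test_that("category lines are additive and degree-1 homogeneous in costs", {
  params <- generate_parameters(synthetic_config(seed = 8))
  strata <- build_eligible_population(params)
  traj <- steppedcea:::propagate_arm(strata, params, "CSC")
  res <- cost_csc_pathway(traj, params)
  expect_equal(res$pathway_cost, sum(res$cost_by_category),
               tolerance = 1e-6)
  # halving the training unit cost removes exactly half the training line
  half <- scale_parameter(params, "costs.CSC0.unit_cost", 0.5)
  res_half <- cost_csc_pathway(traj, half)
  expect_equal(res$pathway_cost - res_half$pathway_cost,
               res$cost_by_category[["CSC0"]] / 2, tolerance = 1e-9)
  # scaling every unit cost by k scales all outputs by k exactly
  k <- 1.7
  scaled <- params
  for (cat in names(scaled$costs))
    scaled <- scale_parameter(scaled, paste0("costs.", cat, ".unit_cost"), k)
  res_k <- cost_csc_pathway(traj, scaled)
  expect_equal(res_k$pathway_cost, k * res$pathway_cost, tolerance = 1e-9)
  expect_equal(res_k$cost_by_category, k * res$cost_by_category,
               tolerance = 1e-9)
  expect_equal(res_k$unremitted_treatment_cost,
               k * res$unremitted_treatment_cost, tolerance = 1e-9)
})

test_that("CAU costs follow the baseline allocation", {
  params <- toy_params(cau_split = c(CAU1 = 1, CAU2 = 0, CAU3 = 0),
                       prevalence = c(depression = 0.1, anxiety = 0.1),
                       target = "depression_only",
                       costs = list(CAU1 = toy_cost_item(300),
                                    CAU9 = toy_cost_item(40, coverage = 0.25)))
  res <- cost_cau_pathway(cau_traj(params), params)
  expect_equal(res$pathway_cost, 100 * 300 + 100 * 40 * 0.25)

  # all no-treatment with zero-cost item and no benzodiazepines: zero cost
  params0 <- toy_params(cau_split = c(CAU1 = 0, CAU2 = 0, CAU3 = 1))
  expect_equal(cost_cau_pathway(cau_traj(params0), params0)$pathway_cost, 0)

  # allocations act linearly: a 50/50 mix costs the average of the extremes
  params_mix <- toy_params(cau_split = c(CAU1 = 0.5, CAU2 = 0.5, CAU3 = 0),
                           prevalence = c(depression = 0.1, anxiety = 0.1),
                           target = "depression_only",
                           costs = list(CAU1 = toy_cost_item(300),
                                        CAU2 = toy_cost_item(1100)))
  res_mix <- cost_cau_pathway(cau_traj(params_mix), params_mix)
  expect_equal(res_mix$pathway_cost, 100 * (0.5 * 300 + 0.5 * 1100))
})

test_that("cost offsets price the difference in unremitted burden", {
  params <- toy_params(p_csc = c(0.5, 0.5, 0.5), p_cau = c(0.3, 2 / 7, 0.6),
                       target = "depression_only",
                       prevalence = c(depression = 0.1, anxiety = 0.1),
                       costs = list(OFFSET_ANNUAL = toy_cost_item(1000)))
  tc <- csc_traj(params); tu <- cau_traj(params)
  # CSC unremitted person-years 43.75 (oracle); CAU: u=(70,50,20) -> 60
  expect_equal(sum(tc$ly_unremitted), 43.75)
  expect_equal(sum(tu$ly_unremitted), 60, tolerance = 1e-9)
  expect_equal(compute_cost_offsets(tc, tu, params), -16250,
               tolerance = 1e-6)
  # identical arms offset nothing; a free unremitted year offsets nothing
  expect_equal(compute_cost_offsets(tc, tc, params), 0)
  free <- toy_params(costs = list(OFFSET_ANNUAL = toy_cost_item(0)))
  expect_equal(compute_cost_offsets(csc_traj(free), cau_traj(free), free), 0)
  # the cases-at-12-months basis uses end-of-year counts instead
  expect_equal(
    compute_cost_offsets(tc, tu, params, offset_basis = "cases_12m"),
    1000 * (12.5 - 20), tolerance = 1e-9)
  expect_error(compute_cost_offsets(tc, tu[1:2, ], params), "identical strata")
})

test_that("time and travel costs value visits per branch", {
  params <- one_branch_params(
    "mild", p_csc = c(1, 0, 0),
    costs = list(CSC1a = toy_cost_item(0, visits = 5),
                 TIME_TRAVEL = toy_cost_item(20))
  )
  traj <- csc_traj(params)
  expect_equal(compute_time_travel_costs(traj, params, "CSC"),
               100 * 5 * 20)
  zero <- one_branch_params("mild",
                            costs = list(CSC1a = toy_cost_item(0, visits = 5),
                                         TIME_TRAVEL = toy_cost_item(0)))
  expect_equal(compute_time_travel_costs(csc_traj(zero), zero, "CSC"), 0)
  # disabled layer leaves the arm result's field at zero
  res <- cost_csc_pathway(traj, params)
  expect_equal(res$time_travel_cost, 0)
  # missing TIME_TRAVEL item is a configuration error
  no_tt <- params; no_tt$costs$TIME_TRAVEL <- NULL
  expect_error(compute_time_travel_costs(traj, no_tt, "CSC"), "TIME_TRAVEL")
  expect_error(cost_csc_pathway(traj, no_tt, include_time_travel = TRUE),
               "TIME_TRAVEL")
})
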
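test_that("write then load is the identity on a valid parameter set", {
  params <- generate_parameters(synthetic_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters(params, path)
  reloaded <- load_parameters(path)
  expect_identical(as.character(steppedcea:::params_to_json(params)),
                   as.character(steppedcea:::params_to_json(reloaded)))
  expect_equal(reloaded$n_iterations, 3000L)
  expect_length(unlist(reloaded$remission, recursive = FALSE), 4L)
  # a second round trip is byte-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_parameters(reloaded, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("validation rejects broken invariants naming the field", {
  params <- toy_params()
  bad <- params
  bad$cohorts[[1]]$severity_split$depression <-
    lapply(list(mild = 0.5, moderate = 0.3, severe = 0.1), uv_fixed)
  expect_error(validate_parameters(bad), "severity_split.*sums to 0.9")

  bad <- params
  bad$cohorts[[1]]$gp_mh_consult_prop <- NULL
  expect_error(validate_parameters(bad), "missing field.*gp_mh_consult_prop")

  bad <- params
  bad$cohorts <- list()
  expect_error(validate_parameters(bad), "cohorts.*non-empty")
  expect_error(write_parameters(bad, tempfile()), "cohorts")

  bad <- params
  bad$remission$CSC$depression <- bad$remission$CSC$depression[1:2]
  expect_error(validate_parameters(bad), "2 intervals, expected 3")

  bad <- params
  bad$weights$dw_remitted <- uv_fixed(0.5)
  expect_error(validate_parameters(bad), "dw_remitted.*exceeds")

  bad <- params
  bad$wtp <- -1
  expect_error(validate_parameters(bad), "wtp")

  bad <- params
  bad$costs$CAU2$coverage <- 1.4
  expect_error(validate_parameters(bad), "CAU2.*coverage")
})

test_that("validation rejects randomly perturbed parameter sets", {
  params <- generate_parameters(synthetic_config(seed = 5))
  ids <- parameter_ids(params)
  prob_ids <- grep("remission|prevalence|consult|dw_|severity",
                   ids, value = TRUE)
  set.seed(20)
  for (id in sample(prob_ids, 12)) {
    broken <- params
    parts <- strsplit(id, ".", fixed = TRUE)[[1]]
    node <- steppedcea:::path_get(broken, parts, id)
    node$point <- 1.7  # outside every probability/weight domain
    broken <- steppedcea:::path_set(broken, parts, node)
    expect_error(validate_parameters(broken),
                 "validation error|outside \\[0, 1")
  }
})

test_that("scale_parameter touches exactly one stored value", {
  params <- generate_parameters(synthetic_config(seed = 2))
  before <- strsplit(as.character(steppedcea:::params_to_json(params)),
                     "\n")[[1]]
  scaled <- scale_parameter(params, "costs.CSC1a.unit_cost", 1.1)
  after <- strsplit(as.character(steppedcea:::params_to_json(scaled)),
                    "\n")[[1]]
  expect_length(before, length(after))
  expect_equal(sum(before != after), 1L)
  old <- params$costs$CSC1a$unit_cost$point
  expect_equal(scaled$costs$CSC1a$unit_cost$point, old * 1.1,
               tolerance = 1e-12)
})

test_that("scale_parameter clips probabilities with a warning", {
  params <- toy_params(p_csc = c(0.95, 0.5, 0.5))
  expect_warning(
    scaled <- scale_parameter(params, "remission.CSC.depression.1", 1.1),
    "clipped"
  )
  expect_equal(scaled$remission$CSC$depression[[1]]$point, 1)
  # plain numeric proportion leaves clip too
  params2 <- toy_params(costs = list(CSC9 = toy_cost_item(10, coverage = 0.95)))
  expect_warning(s2 <- scale_parameter(params2, "costs.CSC9.coverage", 1.2),
                 "clipped")
  expect_equal(s2$costs$CSC9$coverage, 1)
})

test_that("scale_parameter at factor 1 is the identity and unknown ids fail", {
  params <- generate_parameters(synthetic_config(seed = 2))
  expect_identical(
    as.character(steppedcea:::params_to_json(
      scale_parameter(params, "weights.dw_background", 1))),
    as.character(steppedcea:::params_to_json(params))
  )
  expect_error(scale_parameter(params, "costs.CSC1a.nope", 1.1),
               "unknown parameter id")
  expect_error(scale_parameter(params, "no.such.path", 1.1),
               "unknown parameter id")
})

test_that("every advertised parameter id is addressable", {
  params <- generate_parameters(synthetic_config(seed = 4))
  ids <- parameter_ids(params)
  expect_gt(length(ids), 100)
  for (id in ids)
    expect_silent(suppressWarnings(scale_parameter(params, id, 1.01)))
})
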
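test_that("all-fixed families collapse the PSA onto the base case", {
  params <- fix_parameters(generate_parameters(synthetic_config(seed = 1)))
  params$n_iterations <- 40L
  psa <- run_psa(params)
  base <- run_base_case(params)
  expect_true(all(psa$draws$delta_cost == base$net_delta_cost))
  expect_true(all(psa$draws$delta_dalys == base$delta_dalys_averted))
  expect_equal(psa$ui_cost, rep(base$net_delta_cost, 2))
  expect_equal(psa$ui_dalys, rep(base$delta_dalys_averted, 2))
  expect_equal(psa$icer_summary$lower, base$icer, tolerance = 1e-12)
  expect_equal(psa$icer_summary$upper, base$icer, tolerance = 1e-12)
  expect_equal(psa$n_rejected, 0L)
})

test_that("the PSA is reproducible from the master seed", {
  params <- generate_parameters(synthetic_config(seed = 4))
  params$n_iterations <- 60L
  a <- run_psa(params)
  b <- run_psa(params)
  expect_identical(a$draws, b$draws)
  expect_identical(a$icer_summary, b$icer_summary)
  params$seed <- 99L
  c <- run_psa(params)
  expect_false(identical(a$draws, c$draws))
})

test_that("PSA invariants hold on a stochastic run", {
  params <- generate_parameters(synthetic_config(seed = 4))
  params$n_iterations <- 200L
  psa <- run_psa(params)
  expect_equal(nrow(psa$draws), 200L)
  expect_equal(sum(psa$quadrant_props), 1, tolerance = 1e-9)
  # threshold probability equals the CEAC evaluated at the WTP
  expect_equal(psa$prob_cost_effective,
               ceac(psa$draws, params$wtp)$probability)
  # CEAC at 0 is the proportion of cost-saving draws
  expect_equal(ceac(psa$draws, 0)$probability,
               mean(psa$draws$delta_cost <= 0))
  # with a large CSC advantage and modest spread, domination is negligible
  expect_lt(psa$prob_dominated, 0.01)
})

test_that("CEAC follows the net-monetary-benefit rule", {
  draws <- psa_draws(rep(100, 50), rep(0.02, 50))
  grid <- c(0, 4999, 5000, 5001, 1e6)
  curve <- ceac(draws, grid)
  expect_equal(curve$probability, c(0, 0, 1, 1, 1)) # step at 5000
  expect_error(ceac(draws, numeric(0)), "non-empty")
  # monotone non-decreasing whenever all draws have non-negative effect
  set.seed(8)
  mixed <- psa_draws(stats::rnorm(300, 50, 200), stats::runif(300, 0, 0.05))
  p <- ceac(mixed, seq(0, 1e5, by = 1000))$probability
  expect_true(all(diff(p) >= 0))
  # all effects positive: probability tends to 1 as the threshold grows
  expect_equal(ceac(mixed, 1e12)$probability, 1)
})

test_that("quadrant proportions and mirror symmetry on the plane", {
  draws <- psa_draws(rep(-1, 10), rep(0.01, 10))
  stats <- plane_statistics(draws, 50000)
  expect_equal(stats$quadrant_props[["SE"]], 1)
  expect_equal(stats$below_threshold_prop, 1)
  set.seed(9)
  dc <- stats::rnorm(400, 20, 50); de <- stats::rnorm(400, 0.001, 0.01)
  ps <- plane_statistics(psa_draws(dc, de), 5e4)$quadrant_props
  pm <- plane_statistics(psa_draws(-dc, -de), 5e4)$quadrant_props
  expect_equal(ps[["NE"]], pm[["SW"]])
  expect_equal(ps[["SE"]], pm[["NW"]])
})

test_that("ICER interval endpoints order dominance around numeric values", {
  base_ne <- list(icer = 5000, icer_label = "icer")
  # all draws dominant
  all_se <- psa_draws(rep(-10, 100), rep(0.01, 100))
  ui <- summarise_icer_ui(all_se, base_ne)
  expect_identical(ui$lower, "dominant")
  expect_identical(ui$upper, "dominant")
  # dominant lower tail, numeric upper tail
  mix <- psa_draws(c(rep(-10, 30), seq(10, 100, length.out = 70)),
                   rep(0.01, 100))
  ui2 <- summarise_icer_ui(mix, base_ne)
  expect_identical(ui2$lower, "dominant")
  expect_true(is.numeric(ui2$upper))
  # a dominated upper tail surfaces as the label
  mix3 <- psa_draws(c(rep(-10, 30), rep(50, 60), rep(50, 10)),
                    c(rep(0.01, 30), rep(0.01, 60), rep(-0.01, 10)))
  ui3 <- summarise_icer_ui(mix3, base_ne)
  expect_identical(ui3$lower, "dominant")
  expect_identical(ui3$upper, "dominated")
  # purely numeric draws interpolate percentiles
  num <- psa_draws(seq_len(101), rep(0.01, 101))
  ui4 <- summarise_icer_ui(num, base_ne)
  expect_equal(ui4$lower, stats::quantile(seq_len(101) / 0.01, 0.025,
                                          names = FALSE), tolerance = 1e-9)
})

test_that("rejected draws are redrawn and counted", {
  params <- toy_params()
  # remitted weight distribution sits above the unremitted weights half the
  # time: rejections must occur and resolve
  params$weights$dw_unremitted$depression <-
    lapply(list(mild = 0.10, moderate = 0.3, severe = 0.5), uv_fixed)
  params$weights$dw_remitted <- uv_beta_spread(0.10, 0.3)
  params$n_iterations <- 30L
  psa <- run_psa(params)
  expect_gt(psa$n_rejected, 0L)
  expect_equal(nrow(psa$draws), 30L)
})
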
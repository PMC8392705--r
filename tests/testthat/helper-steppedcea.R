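# Hand-built fixtures with fixed (degenerate) uncertainty so that every
# downstream quantity has a closed form.

toy_cost_item <- function(unit = 0, quantity = 1, coverage = 1, visits = 0,
                          family = "fixed", cv = 0.1) {
  uc <- if (family == "fixed") uv_fixed(unit) else uv_gamma_cv(unit, cv)
  list(unit_cost = uc, quantity = quantity, coverage = coverage,
       visits = visits)
}

# One cohort, all-fixed families, all costs zero unless overridden.
toy_params <- function(p_csc = c(0.5, 0.5, 0.5),
                       p_cau = c(0.25, 0.25, 0.25),
                       severity = c(mild = 1, moderate = 0, severe = 0),
                       population = 1000, consult = 1,
                       prevalence = c(depression = 0.5, anxiety = 0.5),
                       dw_unremitted = 0.3, dw_remitted = 0,
                       dw_background = 0,
                       costs = list(),
                       step2_split = c(CSC2a = 1, CSC2b = 0, CSC2c = 0),
                       cau_split = c(CAU1 = 1, CAU2 = 0, CAU3 = 0),
                       target = "both", wtp = 50000, n_iterations = 10L,
                       seed = 7L) {
  sev_uv <- lapply(as.list(severity), uv_fixed)
  cohort <- list(
    age_group = "18+", sex = "female", population = population,
    gp_mh_consult_prop = uv_fixed(consult),
    prevalence = list(depression = uv_fixed(prevalence[["depression"]]),
                      anxiety = uv_fixed(prevalence[["anxiety"]])),
    severity_split = list(depression = sev_uv, anxiety = sev_uv)
  )
  remission <- list(
    CSC = list(depression = lapply(p_csc, uv_fixed),
               anxiety = lapply(p_csc, uv_fixed)),
    CAU = list(depression = lapply(p_cau, uv_fixed),
               anxiety = lapply(p_cau, uv_fixed))
  )
  dwu <- lapply(as.list(c(mild = dw_unremitted, moderate = dw_unremitted,
                          severe = dw_unremitted)), uv_fixed)
  weights <- list(
    dw_unremitted = list(depression = dwu, anxiety = dwu),
    dw_remitted = uv_fixed(dw_remitted),
    dw_background = uv_fixed(dw_background)
  )
  cats <- c("CSC0", "CSC1a", "CSC1b", "CSC2a", "CSC2b", "CSC2c", "CSC9",
            "CAU1", "CAU2", "CAU3", "CAU9", "OFFSET_ANNUAL", "TIME_TRAVEL")
  cost_list <- stats::setNames(
    lapply(cats, function(cat) costs[[cat]] %||% toy_cost_item()), cats)
  allocations <- list(
    CSC = list(step2 = lapply(as.list(step2_split), uv_fixed)),
    CAU = list(branches = lapply(as.list(cau_split), uv_fixed))
  )
  model_parameters(list(cohort), remission, weights, cost_list, allocations,
                   wtp = wtp, n_iterations = n_iterations, seed = seed,
                   target = target)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent midpoint-recursion oracle for the AUC person-time split:
# persons remitting in interval t contribute 1/6 year to each state in t,
# persons already remitted contribute 1/3 year to the remitted state.
midpoint_oracle <- function(n, p) {
  u_prev <- n
  ly_rem <- ly_unrem <- 0
  for (t in 1:3) {
    remit_now <- u_prev * p[t]
    u <- u_prev - remit_now
    ly_unrem <- ly_unrem + u / 3 + remit_now / 6
    ly_rem <- ly_rem + (n - u_prev) / 3 + remit_now / 6
    u_prev <- u
  }
  list(ly_remitted = ly_rem, ly_unremitted = ly_unrem)
}

psa_draws <- function(delta_cost, delta_dalys) {
  tibble::tibble(iteration = seq_along(delta_cost),
                 delta_cost = delta_cost, delta_dalys = delta_dalys)
}
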
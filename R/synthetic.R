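#' Configuration for the synthetic parameter generator
#'
#' @param seed Integer seed; identical configs generate identical sets.
#' @param n_cohorts Even positive integer: number of age-sex cohorts
#'   (age bands times two sexes). The default 12 gives six adult age bands
#'   (18–29 through 70+) for each sex.
#' @param csc_remission_advantage Additive increment of the CSC remission
#'   probability over CAU in every 4-month interval; must keep all
#'   probabilities inside \[0, 1\].
#' @param cost_scale Multiplier applied to all default unit costs.
#' @param uncertainty_spread Width dial for the uncertainty distributions:
#'   the coefficient of variation of gamma-distributed costs and the
#'   relative spread of beta-distributed proportions (see
#'   [uv_beta_spread()]).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 42L, n_cohorts = 12L,
                             csc_remission_advantage = 0.15,
                             cost_scale = 1, uncertainty_spread = 0.12) {
  stopifnot(n_cohorts > 0, n_cohorts %% 2 == 0, cost_scale > 0,
            uncertainty_spread >= 0, uncertainty_spread < 1)
  structure(
    list(seed = as.integer(seed), n_cohorts = as.integer(n_cohorts),
         csc_remission_advantage = csc_remission_advantage,
         cost_scale = cost_scale, uncertainty_spread = uncertainty_spread),
    class = "synthetic_config"
  )
}

# Baseline CAU remission probabilities per 4-month interval. Chosen to
# reflect a care-as-usual arm in which roughly half of cases remit within
# a year, with anxiety remitting somewhat more slowly than depression.
synthetic_cau_remission <- list(
  depression = c(0.35, 0.30, 0.25),
  anxiety    = c(0.30, 0.25, 0.20)
)

# GBD-2019-style disability weights for the unremitted states.
synthetic_dw <- list(
  depression = c(mild = 0.145, moderate = 0.396, severe = 0.658),
  anxiety    = c(mild = 0.030, moderate = 0.133, severe = 0.523)
)

# Default unit costs in 2019 A$ (per treated person over the relevant
# delivery window) and the branch structure they attach to.
synthetic_cost_table <- list(
  # category        unit_cost quantity coverage visits
  CSC0          = list(30,   1, 1.00, 0),   # provider training, amortised
  CSC1a         = list(350,  1, 1.00, 5),   # guided self-help (nurse)
  CSC1b         = list(430,  1, 1.00, 7),   # guided self-help + antidepressants
  CSC2a         = list(250,  1, 1.00, 4),   # step 2: antidepressants
  CSC2b         = list(800,  1, 1.00, 8),   # step 2: psychotherapy
  CSC2c         = list(1000, 1, 1.00, 10),  # step 2: combined
  CSC9          = list(40,   1, 0.20, 0),   # benzodiazepine add-on
  CAU1          = list(300,  1, 1.00, 4),   # antidepressants only
  CAU2          = list(1100, 1, 1.00, 8),   # specialised mental healthcare
  CAU3          = list(0,    1, 1.00, 0),   # no treatment
  CAU9          = list(40,   1, 0.25, 0),
  OFFSET_ANNUAL = list(2000, 1, 1.00, 0),   # annual cost per unremitted case
  TIME_TRAVEL   = list(25,   1, 1.00, 0)    # A$ per clinic visit (time+travel)
)

#' Generate a complete, internally consistent synthetic parameter set
#'
#' Builds a full [model_parameters()] object with the structure the model
#' expects from its tabulated inputs: age-sex cohorts with populations,
#' GP mental-health consultation proportions, primary-diagnosis prevalences
#' and severity splits; four remission schedules (two arms by two
#' disorders) with the CSC arm exceeding CAU by
#' `csc_remission_advantage` in every interval; GBD-style disability
#' weights; and fully costed CSC/CAU pathways with offset and time/travel
#' items. All probabilities and proportions carry beta uncertainty and all
#' unit costs carry gamma uncertainty, parameterised by moment-matching
#' the point estimate with the `uncertainty_spread` dial. Generation is
#' deterministic in `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A validated `csc_parameters` object.
#' @examples
#' params <- generate_parameters(synthetic_config(seed = 1))
#' params
#' @export
generate_parameters <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  adv <- config$csc_remission_advantage
  for (d in model_disorders)
    if (any(synthetic_cau_remission[[d]] + adv > 1) || adv < -1)
      stop("csc_remission_advantage pushes a remission probability ",
           "outside [0, 1]", call. = FALSE)

  rng <- local({
    set.seed(config$seed)
    function(n, lo, hi) stats::runif(n, lo, hi)
  })
  sp <- config$uncertainty_spread

  n_bands <- config$n_cohorts %/% 2L
  lower <- c(18, seq(30, by = 10, length.out = max(n_bands - 1L, 0)))
  bands <- if (n_bands == 1L) "18+" else
    c(paste0(lower[-n_bands], "-", lower[-1] - 1),
      paste0(lower[n_bands], "+"))

  cohorts <- list()
  for (b in seq_len(n_bands)) for (sex in c("female", "male")) {
    # population declines with age; women consult for mental health more
    pop <- round(1.6e6 * exp(-0.12 * (b - 1)) * (1 + rng(1, -0.05, 0.05)))
    consult <- (if (sex == "female") 0.13 else 0.09) * (1 + rng(1, -0.1, 0.1))
    prev_dep <- 0.28 * (1 + rng(1, -0.1, 0.1))
    prev_anx <- 0.33 * (1 + rng(1, -0.1, 0.1))
    sev <- function() {
      raw <- c(0.50, 0.35, 0.15) * (1 + rng(3, -0.1, 0.1))
      raw <- raw / sum(raw)
      stats::setNames(lapply(raw, uv_beta_spread, spread = sp),
                      model_severities)
    }
    cohorts[[length(cohorts) + 1L]] <- list(
      age_group = bands[b], sex = sex, population = pop,
      gp_mh_consult_prop = uv_beta_spread(consult, sp),
      prevalence = list(depression = uv_beta_spread(prev_dep, sp),
                        anxiety = uv_beta_spread(prev_anx, sp)),
      severity_split = list(depression = sev(), anxiety = sev())
    )
  }

  remission <- list()
  for (arm in model_arms) {
    remission[[arm]] <- list()
    for (d in model_disorders) {
      p <- synthetic_cau_remission[[d]] + if (arm == "CSC") adv else 0
      remission[[arm]][[d]] <- lapply(p, uv_beta_spread, spread = sp)
    }
  }

  weights <- list(
    dw_unremitted = lapply(synthetic_dw, function(dw)
      lapply(as.list(dw), uv_beta_spread, spread = sp)),
    dw_remitted = uv_beta_spread(0.01, sp),
    dw_background = uv_beta_spread(0.08, sp)
  )

  costs <- lapply(synthetic_cost_table, function(it)
    list(unit_cost = uv_gamma_cv(it[[1]] * config$cost_scale, sp),
         quantity = it[[2]], coverage = it[[3]], visits = it[[4]]))

  allocations <- list(
    CSC = list(step2 = list(CSC2a = uv_beta_spread(0.25, sp),
                            CSC2b = uv_beta_spread(0.40, sp),
                            CSC2c = uv_beta_spread(0.35, sp))),
    CAU = list(branches = list(CAU1 = uv_beta_spread(0.30, sp),
                               CAU2 = uv_beta_spread(0.25, sp),
                               CAU3 = uv_beta_spread(0.45, sp)))
  )

  model_parameters(cohorts, remission, weights, costs, allocations,
                   seed = config$seed)
}
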
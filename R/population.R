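#' Construct the eligible treated population by stratum
#'
#' Applies the eligibility cascade to every age-sex cohort: persons aged 18
#' and over, times the proportion who visited a GP clinic in the past year
#' for mental health treatment, times the primary-diagnosis prevalence of
#' the disorder, times the severity split. Comorbid cases carry a single
#' primary diagnosis, so the depression and anxiety streams are additive
#' and the `target` variant simply restricts which streams are emitted.
#' Expected person counts are kept as reals throughout (cohort model, not
#' microsimulation).
#'
#' @param params A validated `csc_parameters` object.
#' @param target Targeting variant; defaults to `params$target`.
#' @return A tibble with one row per cohort x disorder x severity stratum:
#'   `cohort`, `age_group`, `sex`, `disorder`, `severity`, `n_persons`.
#' @examples
#' params <- generate_parameters(synthetic_config(seed = 1))
#' strata <- build_eligible_population(params)
#' sum(strata$n_persons)
#' @export
build_eligible_population <- function(params, target = params$target) {
  disorders <- switch(target,
                      both = model_disorders,
                      depression_only = "depression",
                      anxiety_only = "anxiety",
                      stop("unknown target: ", target, call. = FALSE))
  k <- length(params$cohorts) * length(disorders) * length(model_severities)
  cohort <- integer(k); age_group <- sex <- disorder <- severity <-
    character(k); n_persons <- numeric(k)
  j <- 0L
  for (i in seq_along(params$cohorts)) {
    co <- params$cohorts[[i]]
    base <- co$population * co$gp_mh_consult_prop$point
    for (d in disorders) {
      nd <- base * co$prevalence[[d]]$point
      for (s in model_severities) {
        j <- j + 1L
        cohort[j] <- i; age_group[j] <- co$age_group; sex[j] <- co$sex
        disorder[j] <- d; severity[j] <- s
        n_persons[j] <- nd * co$severity_split[[d]][[s]]$point
      }
    }
  }
  tibble::tibble(cohort, age_group, sex, disorder, severity, n_persons)
}
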
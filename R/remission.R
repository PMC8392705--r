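#' Propagate a stratum through the three 4-month remission intervals
#'
#' The year is divided into three 4-month intervals (0–4, 4–8, 8–12
#' months). Under the default `"conditional"` reading, `p[t]` is the
#' probability that a person still unremitted at the start of interval `t`
#' remits during it; remission is absorbing within the 1-year horizon
#' (no relapse). Person-time in each state is accumulated by
#' area-under-the-curve with the midpoint convention: a person remitting
#' within an interval contributes half the interval (1/6 year) to each
#' state, while a person remitted (unremitted) throughout contributes the
#' full 1/3 year to the remitted (unremitted) state. This equals the
#' trapezoid rule applied to the piecewise-linear unremitted-count curve.
#'
#' Under the alternative `"cumulative"` reading, `p[t]` is taken as the
#' cumulative proportion remitted by the end of interval `t` (made
#' non-decreasing by a running maximum).
#'
#' @param n_persons Number of persons entering the year unremitted
#'   (expected count, may be fractional).
#' @param p Numeric vector of three per-interval remission probabilities.
#' @param method `"conditional"` (default) or `"cumulative"`; see above.
#' @return A list of class `csc_trajectory`: `n_persons`,
#'   `remitted_at_interval_end` (cumulative persons remitted by 4, 8 and
#'   12 months), `ly_remitted`, `ly_unremitted` (person-years over the
#'   year; they sum to `n_persons`).
#' @examples
#' propagate_remission(100, c(0.5, 0.5, 0.5))
#' @export
propagate_remission <- function(n_persons, p,
                                method = c("conditional", "cumulative")) {
  method <- match.arg(method)
  stopifnot(length(p) == 3L, all(p >= 0), all(p <= 1), n_persons >= 0)
  # unremitted counts at the interval boundaries (months 0, 4, 8, 12)
  u <- if (method == "conditional") n_persons * cumprod(1 - p)
       else n_persons * (1 - cummax(p))
  u_bound <- c(n_persons, u)
  # trapezoid AUC on the piecewise-linear unremitted curve, 1/3 y intervals
  ly_unrem <- sum((u_bound[-4] + u_bound[-1]) / 2) / 3
  structure(
    list(n_persons = n_persons,
         remitted_at_interval_end = n_persons - u,
         ly_remitted = n_persons - ly_unrem,
         ly_unremitted = ly_unrem),
    class = "csc_trajectory"
  )
}

#' @export
print.csc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<csc_trajectory> n=%g remitted@(4,8,12m)=(%g, %g, %g) LY(rem)=%g LY(unrem)=%g\n",
    x$n_persons, x$remitted_at_interval_end[1],
    x$remitted_at_interval_end[2], x$remitted_at_interval_end[3],
    x$ly_remitted, x$ly_unremitted))
  invisible(x)
}

# Vectorised propagation of all strata of one arm. Returns the strata
# tibble augmented with trajectory columns plus n_stepup (mild/moderate
# non-remitters at 4 months, who step up to specialised care in the CSC
# arm) for use by the costing stage.
propagate_arm <- function(strata, params, arm,
                          method = c("conditional", "cumulative")) {
  method <- match.arg(method)
  out <- strata
  out$arm <- arm
  k <- nrow(strata)
  r4 <- r8 <- r12 <- ly_u <- p1v <- numeric(k)
  for (d in model_disorders) {
    idx <- which(strata$disorder == d)
    if (!length(idx)) next
    p <- vapply(params$remission[[arm]][[d]], function(v) v$point, 0)
    for (i in idx) {
      tr <- propagate_remission(strata$n_persons[i], p, method)
      r4[i] <- tr$remitted_at_interval_end[1]
      r8[i] <- tr$remitted_at_interval_end[2]
      r12[i] <- tr$remitted_at_interval_end[3]
      ly_u[i] <- tr$ly_unremitted
      p1v[i] <- if (method == "conditional") p[1] else min(max(p[1], 0), 1)
    }
  }
  out$remitted_4m <- r4
  out$remitted_8m <- r8
  out$remitted_12m <- r12
  out$ly_unremitted <- ly_u
  out$ly_remitted <- out$n_persons - ly_u
  out$n_stepup <- ifelse(out$severity %in% c("mild", "moderate"),
                         out$n_persons - r4, 0)
  out
}

#' Combine a condition weight with the background-morbidity weight
#'
#' Disability weights combine multiplicatively on the healthy fraction:
#' `DW_adj = 1 - (1 - dw_condition) * (1 - dw_background)`. The result is
#' at least as large as either input and strictly below 1.
#'
#' @param dw_condition Condition (disorder x severity) weight in \[0, 1).
#' @param dw_background Background-morbidity weight in \[0, 1).
#' @return The combined weight.
#' @examples
#' combine_disability_weights(0.3, 0.1) # 0.37
#' @export
combine_disability_weights <- function(dw_condition, dw_background) {
  if (any(dw_condition < 0) || any(dw_condition >= 1) ||
      any(dw_background < 0) || any(dw_background >= 1))
    stop("disability weights must lie in [0, 1)", call. = FALSE)
  1 - (1 - dw_condition) * (1 - dw_background)
}

#' Convert a state trajectory to healthy-equivalent life years
#'
#' Applies the inverted-DALY formula `(1 - DW) x LY` to the remitted and
#' unremitted person-time of a trajectory, using background-adjusted
#' disability weights: larger values mean more healthy-equivalent time
#' ("DALYs averted").
#'
#' @param trajectory A `csc_trajectory` from [propagate_remission()].
#' @param dw_unremitted Unremitted-state weight for the stratum's disorder
#'   and severity, before background adjustment.
#' @param dw_remitted Residual weight of the remitted state.
#' @param dw_background Background-morbidity weight.
#' @return A list of class `csc_outcome` with the adjusted weights and
#'   `dalys_averted`.
#' @examples
#' tr <- propagate_remission(100, c(0.5, 0.5, 0.5))
#' compute_dalys_averted(tr, dw_unremitted = 0.3, dw_remitted = 0,
#'                       dw_background = 0)
#' @export
compute_dalys_averted <- function(trajectory, dw_unremitted, dw_remitted,
                                  dw_background = 0) {
  dw_u <- combine_disability_weights(dw_unremitted, dw_background)
  dw_r <- combine_disability_weights(dw_remitted, dw_background)
  structure(
    list(dw_unremitted_adj = dw_u, dw_remitted_adj = dw_r,
         dalys_averted = (1 - dw_u) * trajectory$ly_unremitted +
           (1 - dw_r) * trajectory$ly_remitted),
    class = "csc_outcome"
  )
}

# Total healthy-equivalent life years across propagated strata of one arm.
arm_dalys_averted <- function(traj, params) {
  w <- params$weights
  dw_bg <- w$dw_background$point
  dw_r <- combine_disability_weights(w$dw_remitted$point, dw_bg)
  dw_u <- vapply(seq_len(nrow(traj)), function(i)
    w$dw_unremitted[[traj$disorder[i]]][[traj$severity[i]]]$point, 0)
  dw_u <- combine_disability_weights(dw_u, dw_bg)
  sum((1 - dw_u) * traj$ly_unremitted + (1 - dw_r) * traj$ly_remitted)
}
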
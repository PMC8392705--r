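# Probabilistic sensitivity analysis: joint independent Monte Carlo draws
# over every uncertain parameter, full model re-run per iteration.

# One joint draw of the whole parameter set. Severity splits and
# allocation proportion sets are drawn marginally and renormalised to sum
# to 1; a draw violating the remitted-weight invariant is rejected and
# redrawn (attempt count returned via attribute).
draw_parameter_set <- function(params, max_attempts = 1000L) {
  draw_node <- function(x) {
    if (is_uncertain_value(x)) { x$point <- sample_uncertain(x); x }
    else if (is.list(x)) lapply(x, draw_node)
    else x
  }
  renorm <- function(set, keys) {
    tot <- sum(vapply(keys, function(k) set[[k]]$point, 0))
    for (k in keys) set[[k]]$point <- set[[k]]$point / tot
    set
  }
  for (attempt in seq_len(max_attempts)) {
    p <- structure(draw_node(unclass(params)), class = "csc_parameters")
    for (i in seq_along(p$cohorts)) for (d in model_disorders)
      p$cohorts[[i]]$severity_split[[d]] <-
        renorm(p$cohorts[[i]]$severity_split[[d]], model_severities)
    p$allocations$CSC$step2 <- renorm(p$allocations$CSC$step2,
                                      csc_step2_categories)
    p$allocations$CAU$branches <- renorm(p$allocations$CAU$branches,
                                         cau_branch_categories)
    ok <- TRUE
    for (d in model_disorders) {
      min_dw <- min(vapply(model_severities, function(s)
        p$weights$dw_unremitted[[d]][[s]]$point, 0))
      if (p$weights$dw_remitted$point > min_dw) { ok <- FALSE; break }
    }
    if (ok) {
      attr(p, "rejections") <- attempt - 1L
      return(p)
    }
  }
  stop("PSA draw rejected ", max_attempts, " times; uncertainty ",
       "distributions are inconsistent with the remitted-weight invariant",
       call. = FALSE)
}

#' Monte Carlo probabilistic sensitivity analysis
#'
#' Runs `params$n_iterations` iterations. In each, every uncertain
#' parameter is drawn independently from its family (severity splits and
#' allocation sets renormalised to sum to 1; draws violating the
#' remitted-weight invariant are rejected and redrawn, with the rejection
#' count reported), the full base-case pipeline is re-run and the pair
#' (net incremental cost, incremental DALYs averted) recorded. One master
#' seed (`params$seed`) deterministically derives a substream per
#' iteration, so results do not depend on execution order.
#'
#' @param params A validated `csc_parameters` object.
#' @param wtp_grid Willingness-to-pay grid (A$/DALY) for the
#'   cost-effectiveness acceptability curve.
#' @param ... Passed to [run_base_case()] (e.g. `target`,
#'   `include_time_travel`).
#' @return An object of class `csc_psa`: `draws` (tibble of iteration,
#'   `delta_cost`, `delta_dalys`), `base` (the point-estimate
#'   [run_base_case()] result), 95% uncertainty intervals `ui_cost` and
#'   `ui_dalys`, `icer_summary` (see [summarise_icer_ui()]),
#'   `quadrant_props`, `prob_dominated`, `prob_cost_effective` (at
#'   `params$wtp`), `ceac` (tibble over `wtp_grid`) and `n_rejected`.
#' @examples
#' params <- generate_parameters(synthetic_config(seed = 1))
#' params$n_iterations <- 100L
#' psa <- run_psa(params)
#' psa$prob_cost_effective
#' @export
run_psa <- function(params, wtp_grid = seq(0, 100000, by = 2500), ...) {
  validate_parameters(params)
  n <- params$n_iterations
  set.seed(params$seed)
  iter_seeds <- sample.int(.Machine$integer.max, n)
  dc <- de <- numeric(n)
  rejected <- 0L
  for (i in seq_len(n)) {
    set.seed(iter_seeds[i])
    drawn <- draw_parameter_set(params)
    rejected <- rejected + attr(drawn, "rejections")
    res <- run_base_case(drawn, validate = FALSE, ...)
    dc[i] <- res$net_delta_cost
    de[i] <- res$delta_dalys_averted
  }
  draws <- tibble::tibble(iteration = seq_len(n), delta_cost = dc,
                          delta_dalys = de)
  base <- run_base_case(params, validate = FALSE, ...)
  plane <- plane_statistics(draws, params$wtp)
  structure(
    list(
      draws = draws,
      base = base,
      ui_cost = stats::quantile(dc, c(0.025, 0.975), names = FALSE, type = 7),
      ui_dalys = stats::quantile(de, c(0.025, 0.975), names = FALSE, type = 7),
      icer_summary = summarise_icer_ui(draws, base),
      quadrant_props = plane$quadrant_props,
      prob_dominated = plane$quadrant_props[["NW"]],
      prob_cost_effective = plane$below_threshold_prop,
      ceac = ceac(draws, wtp_grid),
      n_rejected = rejected,
      wtp = params$wtp,
      n_iterations = n
    ),
    class = "csc_psa"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold λ, the probability of
#' cost-effectiveness is the fraction of Monte Carlo draws with
#' non-negative net monetary benefit, `λ x ΔE - ΔC >= 0`. The net-benefit
#' rule handles all four quadrants coherently (at λ = 0 it reduces to the
#' proportion of cost-saving draws).
#'
#' @param draws Tibble with `delta_cost` and `delta_dalys` columns (from
#'   [run_psa()]'s `draws`).
#' @param wtp_grid Non-empty numeric vector of thresholds (A$/DALY).
#' @return A tibble with columns `wtp` and `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  if (length(wtp_grid) == 0L)
    stop("ceac requires a non-empty WTP grid", call. = FALSE)
  stopifnot(nrow(draws) > 0L)
  prob <- vapply(wtp_grid, function(l)
    mean(l * draws$delta_dalys - draws$delta_cost >= 0), 0)
  tibble::tibble(wtp = as.numeric(wtp_grid), probability = prob)
}

# plane ordering tiers for the ICER uncertainty interval:
# dominant (SE) < numeric ICERs (NE and SW, by value) < dominated (NW)
icer_tiers <- function(draws) {
  dc <- draws$delta_cost
  de <- draws$delta_dalys
  tier <- ifelse(de > 0 & dc <= 0, 0L,
          ifelse(de < 0 & dc >= 0, 2L,
          ifelse(de == 0, ifelse(dc <= 0, 0L, 2L), 1L)))
  value <- ifelse(tier == 1L, dc / de, NA_real_)
  list(tier = tier, value = value)
}

#' 95% uncertainty interval around the ICER
#'
#' ICER percentiles are not well-defined when draws change quadrant, so the
#' interval is taken over a plane-based ordering: dominant draws (SE,
#' cheaper and more effective) rank below every numeric ICER, numeric
#' ICERs rank by value, and dominated draws (NW) rank above all. Endpoints
#' at the 2.5th/97.5th positions are linearly interpolated when both
#' neighbours are numeric, and reported as the labels `"dominant"` /
#' `"dominated"` when the position falls on a labelled draw — matching
#' the reporting style "dominant to <number>".
#'
#' @param draws Tibble with `delta_cost` and `delta_dalys` columns.
#' @param base The base-case `csc_result` (supplies the point ICER).
#' @return A list with `point` (numeric ICER or label), `lower`, `upper`
#'   (each numeric or `"dominant"`/`"dominated"`).
#' @export
summarise_icer_ui <- function(draws, base) {
  stopifnot(nrow(draws) > 0L)
  tiers <- icer_tiers(draws)
  ord <- order(tiers$tier, tiers$value, na.last = FALSE)
  tier_s <- tiers$tier[ord]
  value_s <- tiers$value[ord]
  n <- length(ord)
  endpoint <- function(prob) {
    h <- (n - 1) * prob
    lo <- floor(h) + 1L
    hi <- ceiling(h) + 1L
    if (tier_s[lo] == 1L && tier_s[hi] == 1L)
      return(value_s[lo] + (h - floor(h)) * (value_s[hi] - value_s[lo]))
    at <- round(h) + 1L
    if (tier_s[at] == 0L) "dominant"
    else if (tier_s[at] == 2L) "dominated"
    else value_s[at]
  }
  list(
    point = if (base$icer_label == "icer") base$icer else base$icer_label,
    lower = endpoint(0.025),
    upper = endpoint(0.975)
  )
}

#' Quadrant proportions and threshold probability on the CE plane
#'
#' Classifies every draw into a quadrant (boundary ties to the more
#' favourable label: ΔC = 0 with ΔE > 0 counts as SE) and computes the
#' fraction of draws that are cost-effective at the willingness-to-pay
#' threshold by the net-monetary-benefit rule.
#'
#' @param draws Tibble with `delta_cost` and `delta_dalys` columns.
#' @param wtp Willingness-to-pay threshold (A$/DALY).
#' @return A list with `quadrant_props` (named NE/SE/SW/NW, summing to 1)
#'   and `below_threshold_prop`.
#' @export
plane_statistics <- function(draws, wtp) {
  stopifnot(nrow(draws) > 0L)
  dc <- draws$delta_cost
  de <- draws$delta_dalys
  quad <- ifelse(de > 0 & dc > 0, "NE",
          ifelse(de > 0, "SE",
          ifelse(de < 0 & dc < 0, "SW",
          ifelse(de < 0, "NW", ifelse(dc <= 0, "SE", "NW")))))
  props <- vapply(c("NE", "SE", "SW", "NW"),
                  function(q) mean(quad == q), 0)
  list(quadrant_props = props,
       below_threshold_prop = mean(wtp * de - dc >= 0))
}

#' @export
print.csc_psa <- function(x, ...) {
  fmt_ep <- function(e) if (is.character(e)) e else sprintf("%.0f", e)
  cat(sprintf("<csc_psa> %d iterations (%d rejected draws)\n",
              x$n_iterations, x$n_rejected))
  cat(sprintf("  ICER %s (95%% UI: %s to %s)\n",
              fmt_ep(x$icer_summary$point), fmt_ep(x$icer_summary$lower),
              fmt_ep(x$icer_summary$upper)))
  cat(sprintf("  net incr. cost 95%% UI: A$%.0f to A$%.0f\n",
              x$ui_cost[1], x$ui_cost[2]))
  cat(sprintf("  incr. DALYs averted 95%% UI: %.1f to %.1f\n",
              x$ui_dalys[1], x$ui_dalys[2]))
  cat(sprintf("  quadrants NE/SE/SW/NW: %.3f/%.3f/%.3f/%.3f\n",
              x$quadrant_props[["NE"]], x$quadrant_props[["SE"]],
              x$quadrant_props[["SW"]], x$quadrant_props[["NW"]]))
  cat(sprintf("  P(cost-effective at A$%s/DALY) = %.3f\n",
              format(x$wtp, big.mark = " "), x$prob_cost_effective))
  invisible(x)
}
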
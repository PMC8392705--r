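#' Uncertain model parameters
#'
#' An `uncertain_value` couples a point estimate with the probability
#' distribution used for it in probabilistic sensitivity analysis. The base
#' case uses only the point; [sample_uncertain()] draws from the family.
#'
#' Supported families and their parameter lists:
#' * `"fixed"` — no parameters; draws always return the point.
#' * `"beta"` — `shape1`, `shape2`; for probabilities and proportions.
#' * `"gamma"` — `shape`, `scale`; for non-negative unit costs.
#' * `"lognormal"` — `meanlog`, `sdlog`.
#' * `"uniform"` — `low`, `high` with `low <= high`.
#'
#' @param point Point estimate (finite numeric scalar).
#' @param family Distribution family, one of
#'   `"fixed"`, `"beta"`, `"gamma"`, `"lognormal"`, `"uniform"`.
#' @param params Named list of family-specific parameters (see above).
#'
#' @return An object of class `uncertain_value`.
#' @examples
#' uncertain_value(0.4, "beta", list(shape1 = 4, shape2 = 6))
#' uv_fixed(5207)
#' @export
uncertain_value <- function(point, family = "fixed", params = list()) {
  x <- structure(
    list(point = as.numeric(point), family = family, params = params),
    class = "uncertain_value"
  )
  validate_uncertain_value(x)
  x
}

#' @rdname uncertain_value
#' @export
uv_fixed <- function(point) uncertain_value(point, "fixed")

#' Beta-distributed proportion from a point estimate and a spread dial
#'
#' Moment-matches a beta distribution to mean `point` and standard deviation
#' `spread * sqrt(point * (1 - point))`, i.e. `spread` acts like
#' `1/sqrt(n0 + 1)` for an effective prior sample size `n0`. Degenerate
#' points (0 or 1) or zero spread fall back to a fixed value.
#'
#' @param point Proportion in \[0, 1\].
#' @param spread Spread dial in \[0, 1); larger means wider uncertainty.
#' @return An `uncertain_value` with family `"beta"` (or `"fixed"` when
#'   degenerate).
#' @export
uv_beta_spread <- function(point, spread = 0.1) {
  stopifnot(point >= 0, point <= 1, spread >= 0, spread < 1)
  if (spread == 0 || point == 0 || point == 1) return(uv_fixed(point))
  # mean p, var = spread^2 * p(1-p)  =>  n0 = 1/spread^2 - 1
  n0 <- 1 / spread^2 - 1
  uncertain_value(point, "beta",
                  list(shape1 = point * n0, shape2 = (1 - point) * n0))
}

#' Gamma-distributed cost from a point estimate and a coefficient of variation
#'
#' Matches mean `point` and CV `spread`: `shape = 1/spread^2`,
#' `scale = point * spread^2`.
#'
#' @param point Non-negative mean (e.g. a unit cost in 2019 A$).
#' @param spread Coefficient of variation (> 0 for a proper gamma).
#' @return An `uncertain_value` with family `"gamma"` (or `"fixed"` when
#'   `spread == 0` or `point == 0`).
#' @export
uv_gamma_cv <- function(point, spread = 0.1) {
  stopifnot(point >= 0, spread >= 0)
  if (spread == 0 || point == 0) return(uv_fixed(point))
  uncertain_value(point, "gamma",
                  list(shape = 1 / spread^2, scale = point * spread^2))
}

uv_families <- c("fixed", "beta", "gamma", "lognormal", "uniform")

validate_uncertain_value <- function(x, what = "uncertain_value") {
  if (!is.numeric(x$point) || length(x$point) != 1L || !is.finite(x$point))
    stop(sprintf("%s: point must be a finite numeric scalar", what),
         call. = FALSE)
  if (!x$family %in% uv_families)
    stop(sprintf("%s: unknown family '%s'", what, x$family), call. = FALSE)
  p <- x$params
  switch(
    x$family,
    fixed = NULL,
    beta = {
      if (x$point < 0 || x$point > 1)
        stop(sprintf("%s: beta point %g outside [0, 1]", what, x$point),
             call. = FALSE)
      if (is.null(p$shape1) || is.null(p$shape2) ||
          p$shape1 <= 0 || p$shape2 <= 0)
        stop(sprintf("%s: beta requires positive shape1/shape2", what),
             call. = FALSE)
    },
    gamma = {
      if (x$point < 0)
        stop(sprintf("%s: gamma point %g negative", what, x$point),
             call. = FALSE)
      if (is.null(p$shape) || is.null(p$scale) || p$shape <= 0 || p$scale <= 0)
        stop(sprintf("%s: gamma requires positive shape/scale", what),
             call. = FALSE)
    },
    lognormal = {
      if (x$point < 0)
        stop(sprintf("%s: lognormal point %g negative", what, x$point),
             call. = FALSE)
      if (is.null(p$meanlog) || is.null(p$sdlog) || p$sdlog <= 0)
        stop(sprintf("%s: lognormal requires meanlog and positive sdlog",
                     what), call. = FALSE)
    },
    uniform = {
      if (is.null(p$low) || is.null(p$high) || p$low > p$high)
        stop(sprintf("%s: uniform requires low <= high", what), call. = FALSE)
    }
  )
  invisible(x)
}

is_uncertain_value <- function(x) inherits(x, "uncertain_value")

#' Draw one value from an uncertain parameter
#'
#' Uses the current R random number stream; seed it with [set.seed()] (the
#' PSA engine derives one substream per iteration from the master seed).
#'
#' @param value An [uncertain_value()].
#' @return A single numeric draw; `fixed` returns the point unchanged.
#' @examples
#' set.seed(1)
#' sample_uncertain(uv_beta_spread(0.5, 0.2))
#' @export
sample_uncertain <- function(value) {
  stopifnot(is_uncertain_value(value))
  p <- value$params
  switch(
    value$family,
    fixed = value$point,
    beta = stats::rbeta(1L, p$shape1, p$shape2),
    gamma = stats::rgamma(1L, shape = p$shape, scale = p$scale),
    lognormal = stats::rlnorm(1L, meanlog = p$meanlog, sdlog = p$sdlog),
    uniform = stats::runif(1L, p$low, p$high),
    stop("unsupported family: ", value$family, call. = FALSE)
  )
}

# analytic mean of the family, used by tests and the generator docs
uv_mean <- function(value) {
  p <- value$params
  switch(
    value$family,
    fixed = value$point,
    beta = p$shape1 / (p$shape1 + p$shape2),
    gamma = p$shape * p$scale,
    lognormal = exp(p$meanlog + p$sdlog^2 / 2),
    uniform = (p$low + p$high) / 2
  )
}

uv_var <- function(value) {
  p <- value$params
  switch(
    value$family,
    fixed = 0,
    beta = {
      s <- p$shape1 + p$shape2
      p$shape1 * p$shape2 / (s^2 * (s + 1))
    },
    gamma = p$shape * p$scale^2,
    lognormal = (exp(p$sdlog^2) - 1) * exp(2 * p$meanlog + p$sdlog^2),
    uniform = (p$high - p$low)^2 / 12
  )
}

#' @export
print.uncertain_value <- function(x, ...) {
  ps <- if (length(x$params))
    paste0("(", paste(names(x$params), unlist(x$params), sep = "=",
                      collapse = ", "), ")")
  else ""
  cat(sprintf("<uncertain_value> point=%g family=%s%s\n",
              x$point, x$family, ps))
  invisible(x)
}
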
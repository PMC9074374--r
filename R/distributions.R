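#' Convert an observed event proportion to a per-cycle transition probability
#'
#' Clinical effectiveness data arrive as event counts over an observation
#' window (typically one year), while the Markov model needs probabilities per
#' model cycle (typically three months). Assuming a constant event rate, the
#' observed chance `events / at_risk` over `observation_time` years is first
#' converted to a rate `r = -log(1 - events / at_risk) / observation_time`
#' and then back to a probability over one cycle, `1 - exp(-r * cycle_length)`.
#'
#' When `observation_time == cycle_length` the conversion is the identity and
#' returns exactly `events / at_risk`.
#'
#' @param events Number of events observed (non-negative integer, vectorised).
#' @param at_risk Number of patients at risk (positive integer, vectorised).
#' @param observation_time Length of the observation window in years.
#' @param cycle_length Model cycle length in years (default 0.25, i.e. three
#'   months).
#'
#' @return Numeric vector of per-cycle probabilities in `[0, 1)`.
#'
#' @examples
#' # 11 of 16 patients progressed within one year: per three-month cycle
#' observed_to_cycle_prob(11, 16)
#' # no events means zero probability
#' observed_to_cycle_prob(0, 85)
#' @export
observed_to_cycle_prob <- function(events, at_risk, observation_time = 1,
                                   cycle_length = 0.25) {
  if (any(observation_time <= 0) || any(cycle_length <= 0)) {
    abort("`observation_time` and `cycle_length` must be positive.")
  }
  if (any(at_risk <= 0)) {
    abort("`at_risk` must be positive: the event proportion is undefined otherwise.")
  }
  if (any(events < 0) || any(events > at_risk)) {
    abort("`events` must lie in [0, at_risk].")
  }
  if (any(events == at_risk)) {
    abort(paste0(
      "`events` equals `at_risk`: an observed chance of 1 implies an ",
      "infinite event rate and cannot be converted."
    ))
  }
  chance <- events / at_risk
  rate <- -log(1 - chance) / observation_time
  1 - exp(-rate * cycle_length)
}

#' Fit a beta distribution by the method of moments
#'
#' Returns the `(shape1, shape2)` pair of the beta distribution with the given
#' mean and standard error, used for probabilities and utilities in the
#' probabilistic sensitivity analysis.
#'
#' @param mean Mean in (0, 1) (vectorised).
#' @param se Standard error; must satisfy `se^2 < mean * (1 - mean)`.
#'
#' @return A tibble with columns `shape1` and `shape2`.
#'
#' @examples
#' beta_from_moments(0.93, 0.0665)
#' # mean 1/2, variance 1/12 recovers the uniform distribution
#' beta_from_moments(0.5, sqrt(1 / 12))
#' @export
beta_from_moments <- function(mean, se) {
  if (any(mean <= 0) || any(mean >= 1)) {
    abort("beta moments require 0 < mean < 1.")
  }
  if (any(se <= 0)) {
    abort("beta moments require se > 0; use a fixed parameter for se = 0.")
  }
  if (any(se^2 >= mean * (1 - mean))) {
    abort(paste0(
      "infeasible beta moments: se^2 must be smaller than mean * (1 - mean) (",
      "got se^2 = ", format(max(se^2)), ")."
    ))
  }
  nu <- mean * (1 - mean) / se^2 - 1
  tibble(shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Fit a gamma distribution by the method of moments
#'
#' Returns the shape/scale pair of the gamma distribution with the given mean
#' and standard error, used for cost parameters in the probabilistic
#' sensitivity analysis.
#'
#' @param mean Positive mean (vectorised).
#' @param se Positive standard error.
#'
#' @return A tibble with columns `shape` and `scale`.
#'
#' @examples
#' gamma_from_moments(10970, 1399)
#' # mean == se gives shape 1, the exponential distribution
#' gamma_from_moments(500, 500)
#' @export
gamma_from_moments <- function(mean, se) {
  if (any(mean <= 0) || any(se <= 0)) {
    abort("infeasible gamma moments: mean and se must be positive.")
  }
  tibble(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Create a distribution specification for one uncertain parameter
#'
#' A distribution specification is a `(family, mean, se)` triple: `"beta"` for
#' probabilities and utilities, `"gamma"` for costs, and `"fixed"` for
#' constants that are excluded from probabilistic analysis.
#'
#' @param family One of `"beta"`, `"gamma"`, `"fixed"`.
#' @param mean Parameter mean.
#' @param se Standard error (must be 0 for `"fixed"`).
#'
#' @return A list of class `navcea_dist` with elements `family`, `mean`, `se`.
#' @export
dist_spec <- function(family = c("beta", "gamma", "fixed"), mean, se = 0) {
  family <- arg_match(family)
  if (!is.numeric(mean) || length(mean) != 1 || !is.finite(mean)) {
    abort("`mean` must be a single finite number.")
  }
  if (!is.numeric(se) || length(se) != 1 || !is.finite(se) || se < 0) {
    abort("`se` must be a single non-negative number.")
  }
  if (family == "fixed" && se != 0) {
    abort("a fixed parameter must have se = 0.")
  }
  if (family == "beta" && (mean <= 0 || mean >= 1)) {
    abort("a beta parameter requires 0 < mean < 1.")
  }
  if (family == "gamma" && mean <= 0) {
    abort("a gamma parameter requires mean > 0.")
  }
  # validate moment feasibility eagerly so configuration errors surface early
  if (family == "beta" && se > 0) beta_from_moments(mean, se)
  structure(list(family = family, mean = mean, se = se), class = "navcea_dist")
}

#' @export
print.navcea_dist <- function(x, ...) {
  cat(sprintf("<dist %s mean=%g se=%g>\n", x$family, x$mean, x$se))
  invisible(x)
}

# Draw n sampled values for one distribution spec. Fixed parameters (or se 0)
# return the mean replicated, so a zero-uncertainty PSA collapses to the base
# case exactly.
draw_from_spec <- function(spec, n) {
  if (spec$family == "fixed" || spec$se == 0) {
    return(rep(spec$mean, n))
  }
  if (spec$family == "beta") {
    sh <- beta_from_moments(spec$mean, spec$se)
    rbeta(n, sh$shape1, sh$shape2)
  } else {
    sh <- gamma_from_moments(spec$mean, spec$se)
    rgamma(n, shape = sh$shape, scale = sh$scale)
  }
}

# 95% normal-approximation interval clipped to the parameter's domain; used as
# the default low/high inputs of the one-way sensitivity analysis.
spec_interval <- function(spec, z = 1.96) {
  lo <- spec$mean - z * spec$se
  hi <- spec$mean + z * spec$se
  if (spec$family == "beta") {
    lo <- max(lo, 0)
    hi <- min(hi, 1)
  } else {
    lo <- max(lo, 0)
  }
  c(low = lo, high = hi)
}
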
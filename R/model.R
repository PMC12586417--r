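#' Response density of the continuous rating scale model
#'
#' Probability density (per scale unit) of observing mark `x` on a line with
#' geometry `geom`, for a person at `beta`, an item at `delta` and dispersion
#' `theta`. The model is a doubly truncated normal on the closed support with
#' location `c + (beta - delta) / (2 theta)` and squared scale `1 / (2 theta)`:
#' small `theta` spreads responses over the whole line (high discrimination),
#' large `theta` concentrates them near the model location.
#'
#' The density is evaluated through the truncated-normal (quadratic-exponent)
#' form with the normalising Gaussian mass computed from standard-normal CDF
#' differences in log space. For `theta < 1e-4` that parameterisation degrades
#' (the location term diverges), so the exponential-family form
#' `exp[x(beta - delta) + x(2c - x) theta] / gamma` is used instead, with its
#' normaliser integrated numerically in log space.
#'
#' @param x Numeric vector of responses, inside the closed support.
#' @param beta,delta,theta Person location, item location, dispersion
#'   (`theta > 0`). Recycled against `x`.
#' @param geom A [scale_geometry()] (or a `c(min, max)` range).
#' @return Numeric vector of densities.
#' @examples
#' g <- scale_geometry(1, 0.5)
#' corsm_density(c(0.3, 0.7), beta = 1, delta = 0, theta = 0.5, geom = g)
#' @export
corsm_density <- function(x, beta, delta, theta, geom) {
  geom <- .as_geometry(geom)
  .check_theta(theta)
  n <- max(length(x), length(beta), length(delta), length(theta))
  x <- rep_len(x, n)
  beta <- rep_len(beta, n)
  delta <- rep_len(delta, n)
  theta <- rep_len(theta, n)
  if (any(!is.na(x) & (x < geom$lower - 1e-12 | x > geom$upper + 1e-12))) {
    stop(sprintf(
      "`x` outside the closed support [%g, %g].",
      geom$lower, geom$upper
    ), call. = FALSE)
  }
  u <- x - geom$midpoint # centre the line at 0 (wlog)
  d <- beta - delta
  half <- geom$length / 2
  out <- numeric(n)
  hi <- theta >= 1e-4
  if (any(hi)) {
    m <- d[hi] / (2 * theta[hi])
    lg <- .log_kernel_norm(m, theta[hi], -half, half)
    out[hi] <- exp(-theta[hi] * (u[hi] - m)^2 - lg)
  }
  if (any(!hi)) {
    idx <- which(!hi)
    for (k in idx) {
      lg <- .log_exp_norm(d[k], theta[k], half)
      out[k] <- exp(u[k] * d[k] - theta[k] * u[k]^2 - lg)
    }
  }
  out
}

# log of int_{-half}^{half} exp(u d - theta u^2) du by numeric integration in
# log space; only used in the tiny-theta regime where the quadratic form of
# the normaliser loses precision.
.log_exp_norm <- function(d, theta, half) {
  f <- function(u) u * d - theta * u^2
  peak <- max(f(-half), f(half), f(min(max(d / (2 * theta), -half), half)))
  val <- stats::integrate(function(u) exp(f(u) - peak), -half, half,
    rel.tol = 1e-12
  )$value
  peak + log(val)
}

#' Normalising factor of the model and its derivatives
#'
#' Computes `gamma`, the normalising integral of the exponential-family form
#' of the response density over the closed support, together with its first
#' and second derivatives in the item location and in the dispersion. These
#' are the building blocks of the Newton-Raphson estimation stages: the
#' dispersion score uses `A'_theta - gamma'_theta / gamma`, where `A` is the
#' exponent of the density at the observed score.
#'
#' The integral is evaluated in closed form as a Gaussian tail mass
#' (standard-normal CDF differences in log space); derivatives follow from
#' truncated-normal moments.
#'
#' @param beta,delta,theta Scalar model parameters (`theta > 0`).
#' @param geom A [scale_geometry()].
#' @param x Optional observed score at which the exponent derivatives
#'   `A'_theta = x (2c - x)` and `A''_theta = 0` are also returned.
#' @return A list with `gamma`, `log_gamma`, `d_delta`, `d2_delta`,
#'   `d_theta`, `d2_theta`, and (when `x` is given) `a_prime_theta`,
#'   `a_dprime_theta`.
#' @export
corsm_normalizer <- function(beta, delta, theta, geom, x = NULL) {
  geom <- .as_geometry(geom)
  .check_theta(theta)
  d <- beta - delta
  cc <- geom$midpoint
  a <- geom$lower
  b <- geom$upper
  m <- cc + d / (2 * theta) # location of the truncated normal, user units
  s <- 1 / sqrt(2 * theta)
  if (theta >= 1e-4) {
    # complete the square: t d + t (2c - t) theta = -theta (t - m)^2 + theta m^2
    lg <- theta * m^2 + .log_kernel_norm(m, theta, a, b)
  } else {
    # centred exponential form: substituting t = u + c gives
    # exponent u d - theta u^2 + (c d + c^2 theta)
    lg <- (cc * d + theta * cc^2) + .log_exp_norm(d, theta, geom$length / 2)
  }
  if (!is.finite(lg)) {
    stop(sprintf(
      "Non-finite normaliser (log gamma = %g) at beta = %g, delta = %g, theta = %g.",
      lg, beta, delta, theta
    ), call. = FALSE)
  }
  mom <- .tn_stats(m, s, a, b)
  gamma <- exp(lg)
  out <- list(
    gamma = gamma,
    log_gamma = lg,
    d_delta = -gamma * mom$mean,
    d2_delta = gamma * mom$ex2,
    d_theta = gamma * (2 * cc * mom$mean - mom$ex2),
    d2_theta = gamma * (4 * cc^2 * mom$ex2 - 4 * cc * mom$ex3 + mom$ex4)
  )
  if (!is.null(x)) {
    out$a_prime_theta <- x * (2 * cc - x)
    out$a_dprime_theta <- 0
  }
  out
}

#' Expected score and score variance under the model
#'
#' Mean and variance of the doubly truncated normal response distribution for
#' given person, item and dispersion parameters. These are the `p` and `V`
#' entering the outfit mean square statistic.
#'
#' @inheritParams corsm_density
#' @return A tibble with columns `mean` and `var` (one row per parameter
#'   combination, recycled).
#' @examples
#' corsm_moments(beta = 0, delta = 0, theta = 0.5, geom = scale_geometry(1, 0.5))
#' @export
corsm_moments <- function(beta, delta, theta, geom) {
  geom <- .as_geometry(geom)
  .check_theta(theta)
  n <- max(length(beta), length(delta), length(theta))
  beta <- rep_len(beta, n)
  delta <- rep_len(delta, n)
  theta <- rep_len(theta, n)
  m <- geom$midpoint + (beta - delta) / (2 * theta)
  s <- 1 / sqrt(2 * theta)
  mom <- .tn_stats(m, s, geom$lower, geom$upper)
  tibble::tibble(mean = mom$mean, var = mom$var)
}

#' Re-express parameters under an affine rescaling of the data
#'
#' If observed scores are divided by `s` (so a 0-5 line becomes a 0-1 line),
#' the latent unit changes with them: abilities and difficulties multiply by
#' `s`, the dispersion multiplies by `s^2`, and the line geometry shrinks by
#' `s`. The density transforms as a proper change of variable, so model
#' probabilities are untouched. This is the unit-accommodation rule used to
#' report estimates in the scoring unit the user declared, regardless of the
#' unit the data were stored in (halving the data doubles the person
#' estimates, and so on).
#'
#' @param params A `corsm_fit` object or a list with any of `abilities`,
#'   `difficulties`, `theta`, `geom` (plus optional `ability_sds`,
#'   `difficulty_ses`, `theta_se`).
#' @param s Positive scale factor: the data transformation is `x -> x / s`.
#' @return The same structure with all parameters re-expressed.
#' @export
transform_parameters <- function(params, s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0) {
    stop("`s` must be a single positive number.", call. = FALSE)
  }
  if (inherits(params, "corsm_fit")) {
    fit <- params
    fit$items$difficulty <- fit$items$difficulty * s
    if ("se" %in% names(fit$items)) fit$items$se <- fit$items$se * s
    fit$persons$ability <- fit$persons$ability * s
    if ("posterior_sd" %in% names(fit$persons)) {
      fit$persons$posterior_sd <- fit$persons$posterior_sd * s
    }
    fit$dispersion$theta <- fit$dispersion$theta * s^2
    if ("se" %in% names(fit$dispersion)) {
      fit$dispersion$se <- fit$dispersion$se * s^2
    }
    fit$geometry <- scale_geometry(
      fit$geometry$length / s,
      fit$geometry$midpoint / s
    )
    fit$prior <- list(mean = fit$prior$mean * s, sd = fit$prior$sd * s)
    # densities pick up a Jacobian factor s per observed cell
    fit$logLik <- fit$logLik + fit$n_obs * log(s)
    return(fit)
  }
  out <- params
  if (!is.null(out$abilities)) out$abilities <- out$abilities * s
  if (!is.null(out$ability_sds)) out$ability_sds <- out$ability_sds * s
  if (!is.null(out$difficulties)) out$difficulties <- out$difficulties * s
  if (!is.null(out$difficulty_ses)) out$difficulty_ses <- out$difficulty_ses * s
  if (!is.null(out$theta)) out$theta <- out$theta * s^2
  if (!is.null(out$theta_se)) out$theta_se <- out$theta_se * s^2
  if (!is.null(out$geom)) {
    g <- .as_geometry(out$geom)
    out$geom <- scale_geometry(g$length / s, g$midpoint / s)
  }
  out
}
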
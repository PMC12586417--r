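#' Category probabilities of the rating scale model
#'
#' Probability of scoring `k = 0, ..., m` on an item under the rating scale
#' model: the log-odds of category `k` over `k - 1` is
#' `beta - (delta + tau_k)`, with the empty sum for `k = 0` defined as zero.
#' Computed with log-sum-exp stabilisation.
#'
#' @param beta Person ability (scalar).
#' @param delta Overall item difficulty (scalar).
#' @param tau Step difficulty vector (`m` thresholds for `m + 1` categories).
#' @return Numeric vector of `m + 1` probabilities summing to one.
#' @examples
#' rsm_category_probs(0.5, 0, rsm_tau_preset(5))
#' @export
rsm_category_probs <- function(beta, delta, tau) {
  stopifnot(length(tau) >= 1)
  lognum <- c(0, cumsum(beta - (delta + tau)))
  w <- exp(lognum - max(lognum))
  w / sum(w)
}

# matrix version: rows over persons x items (flattened), columns categories
.rsm_logprobs <- function(bd, tau) {
  m <- length(tau)
  lognum <- cbind(0, outer(bd, seq_len(m)) -
    matrix(cumsum(tau), length(bd), m, byrow = TRUE))
  mx <- apply(lognum, 1, max)
  p <- exp(lognum - mx)
  p / rowSums(p)
}

#' Step difficulty presets for 5, 7 and 9 response categories
#'
#' The fixed generating threshold sets used by the discrete recovery
#' experiments (four, six and eight thresholds respectively, ranging from
#' -2.3 to 2.5 and summing to zero).
#'
#' @param n_categories 5, 7 or 9.
#' @return Numeric vector of `n_categories - 1` thresholds.
#' @export
rsm_tau_preset <- function(n_categories) {
  switch(as.character(n_categories),
    "5" = c(-2.3, -0.9, 0.7, 2.5),
    "7" = c(-2.3, -1.3, -0.5, 0.2, 1.4, 2.5),
    "9" = c(-2.3, -1.6, -0.8, -0.3, 0.1, 0.9, 1.5, 2.5),
    stop("Presets exist for 5, 7 or 9 categories.", call. = FALSE)
  )
}

#' Simulate rating scale model responses
#'
#' Draws each response by inverse-CDF sampling: a uniform draw is compared
#' with the cumulative category probabilities and the smallest category whose
#' cumulative probability reaches it is returned.
#'
#' @param abilities Person ability vector.
#' @param difficulties Overall item difficulty vector.
#' @param tau Step difficulty vector.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A wide tibble (`id` plus item columns) of integer scores
#'   `0, ..., length(tau)`.
#' @export
simulate_rsm <- function(abilities, difficulties, tau, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nn <- length(abilities)
  ii <- length(difficulties)
  bd <- as.vector(
    matrix(abilities, nn, ii) - matrix(difficulties, nn, ii, byrow = TRUE)
  )
  p <- .rsm_logprobs(bd, tau)
  cum <- t(apply(p, 1, cumsum))
  u <- stats::runif(length(bd))
  k <- rowSums(u > cum) # smallest k with cumulative >= u
  x <- matrix(as.integer(k), nn, ii)
  colnames(x) <- paste0("item_", seq_len(ii))
  dplyr::bind_cols(
    tibble::tibble(id = paste0("p", seq_len(nn))),
    tibble::as_tibble(as.data.frame(x))
  )
}

#' Support points for discrete categories on the unit line
#'
#' Category `k` of `K` maps to support point `k / (K - 1)` on the closed unit
#' interval, so the lowest and highest categories sit exactly on the
#' endpoints and adjacent categories are `spacing = 1 / (K - 1)` apart.
#'
#' @param n_categories Number of categories `K >= 2`.
#' @return A tibble with columns `category`, `support_point`, and attribute
#'   `spacing`.
#' @export
category_map <- function(n_categories) {
  stopifnot(n_categories >= 2)
  m <- n_categories - 1
  out <- tibble::tibble(
    category = 0:m,
    support_point = (0:m) / m
  )
  attr(out, "spacing") <- 1 / m
  out
}

#' Equidistant step difficulties implied by a dispersion
#'
#' The continuous model evaluated at equally spaced support points is exactly
#' a rating scale model with equidistant thresholds: the adjacent-category
#' log-odds give `tau_k = theta * spacing^2 * (2k - 1 - m)` for
#' `k = 1, ..., m`. The thresholds are symmetric about zero, sum to zero, and
#' follow the ratio pattern `(-3, -1, 1, 3)` when `m = 4`.
#'
#' @param theta Dispersion (in the metric of the chosen support).
#' @param n_categories Number of categories.
#' @param spacing Distance between adjacent support points (defaults to the
#'   unit-line spacing `1 / (n_categories - 1)`).
#' @return Numeric vector of `n_categories - 1` thresholds.
#' @export
step_difficulties <- function(theta, n_categories,
                              spacing = 1 / (n_categories - 1)) {
  .check_theta(theta)
  stopifnot(n_categories >= 2)
  m <- n_categories - 1
  theta * spacing^2 * (2 * seq_len(m) - 1 - m)
}

#' Fit the continuous model to Likert-type (discrete) data
#'
#' A `K`-category rating item is treated as a discretisation of a continuous
#' line of length `K`: category `k` is the midpoint `k + 1/2` of the `k`-th
#' unit-width bin, so the truncation bounds sit half a bin beyond the extreme
#' categories. The continuous model is calibrated on those support points
#' with [fit_corsm()]. Because the continuous density evaluated at equally
#' spaced points is exactly a rating scale model with equidistant thresholds,
#' the fit reports parameters directly in the adjacent-category (rating
#' scale model) metric: person abilities, mean-centred overall difficulties,
#' and the equidistant step difficulties `tau_k = theta_hat (2k - K)`
#' implied by the fitted dispersion.
#'
#' @inheritParams fit_corsm
#' @param n_categories Number of response categories `K >= 2`.
#' @param score_range Declared score range of the raw categories, e.g.
#'   `c(1, 5)` for a 1-5 Likert item (default `c(0, K - 1)`).
#' @return A `corsm_fit` with additional class `corsm_discrete_fit` and a
#'   `steps` tibble of step difficulties.
#' @examples
#' sim <- simulate_rsm(rnorm(60), c(-0.5, 0, 0.5), rsm_tau_preset(5), seed = 7)
#' fit <- fit_corsm_discrete(sim, n_categories = 5)
#' fit$steps
#' @export
fit_corsm_discrete <- function(data, n_categories, score_range = NULL,
                               id_col = NULL, prior_mean = 0, prior_sd = 1,
                               variant = c("muller", "verhelst"),
                               config = fit_config()) {
  variant <- match.arg(variant)
  stopifnot(n_categories >= 2)
  m <- n_categories - 1
  rm_ <- .as_response_matrix(data, id_col)
  x <- rm_$x
  if (is.null(score_range)) score_range <- c(0, m)
  stopifnot(length(score_range) == 2L, score_range[1] < score_range[2])
  # map declared categories onto 0..m and insist they are whole categories
  x <- (x - score_range[1]) / diff(score_range) * m
  off <- which(!is.na(x) & abs(x - round(x)) > 1e-8, arr.ind = TRUE)
  if (nrow(off) > 0L) {
    stop(sprintf(
      "Non-category score (person %s, item %s): not one of the %d declared categories.",
      rm_$ids[off[1, 1]], rm_$items[off[1, 2]], n_categories
    ), call. = FALSE)
  }
  x <- round(x)
  if (any(!is.na(x) & (x < 0 | x > m))) {
    stop("Scores outside the declared category range.", call. = FALSE)
  }
  df <- dplyr::bind_cols(
    tibble::tibble(id = rm_$ids),
    tibble::as_tibble(as.data.frame(x + 0.5)) # bin midpoints on [0, K]
  )
  # the midpoint grid has unit spacing and 2c/spacing = K, so the fitted
  # parameters are already in the adjacent-category metric with
  # tau_k = theta (2k - K)
  fit <- fit_corsm(df,
    score_range = c(0, n_categories), prior_mean = prior_mean,
    prior_sd = prior_sd, variant = variant, config = config
  )
  theta_hat <- mean(fit$dispersion$theta)
  fit$steps <- tibble::tibble(
    step = seq_len(m),
    tau = theta_hat * (2 * seq_len(m) - n_categories)
  )
  fit$n_categories <- n_categories
  fit$category_map <- category_map(n_categories)
  class(fit) <- c("corsm_discrete_fit", class(fit))
  fit
}
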
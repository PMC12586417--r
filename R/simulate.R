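#' Simulate continuous rating responses
#'
#' Draws one response per person-item pair from the model's doubly truncated
#' normal distribution by inverse-CDF sampling, so every draw lies inside the
#' closed support of the line.
#'
#' @param abilities Person ability vector (length N).
#' @param difficulties Item difficulty vector (length I).
#' @param theta Dispersion (scalar, or one value per item).
#' @param geom A [scale_geometry()] or `c(min, max)` range.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A wide tibble: `id` column plus one column per item.
#' @examples
#' simulate_corsm(rnorm(5), c(-1, 0, 1), theta = 0.5,
#'   geom = scale_geometry(5), seed = 42
#' )
#' @export
simulate_corsm <- function(abilities, difficulties, theta, geom, seed = NULL) {
  geom <- .as_geometry(geom)
  .check_theta(theta)
  if (!is.null(seed)) set.seed(seed)
  nn <- length(abilities)
  ii <- length(difficulties)
  theta <- rep_len(theta, ii)
  thmat <- matrix(theta, nn, ii, byrow = TRUE)
  m <- geom$midpoint +
    (matrix(abilities, nn, ii) - matrix(difficulties, nn, ii, byrow = TRUE)) /
      (2 * thmat)
  s <- 1 / sqrt(2 * thmat)
  plo <- stats::pnorm((geom$lower - m) / s)
  phi <- stats::pnorm((geom$upper - m) / s)
  u <- matrix(stats::runif(nn * ii), nn, ii)
  x <- m + s * stats::qnorm(plo + u * (phi - plo))
  x[!is.finite(x)] <- m[!is.finite(x)] # fully degenerate tail mass
  x <- pmin(pmax(x, geom$lower), geom$upper)
  colnames(x) <- paste0("item_", seq_len(ii))
  dplyr::bind_cols(
    tibble::tibble(id = paste0("p", seq_len(nn))),
    tibble::as_tibble(as.data.frame(x))
  )
}

#' Fleishman polynomial coefficients
#'
#' Coefficients of the cubic polynomial `a + b x + c x^2 + d x^3` of a
#' standard normal variate used to generate non-normal ability
#' distributions. `fleishman_coefficients()` is the identity;
#' [fleishman_nonnormal()] is the skewed, heavy-tailed preset used in the
#' recovery experiments.
#'
#' @param a,b,c_coef,d Polynomial coefficients (`c_coef` so named to avoid
#'   clashing with the line midpoint `c`).
#' @return A list of class `fleishman_coefficients`.
#' @export
fleishman_coefficients <- function(a = 0, b = 1, c_coef = 0, d = 0) {
  structure(
    list(a = a, b = b, c_coef = c_coef, d = d),
    class = "fleishman_coefficients"
  )
}

#' @rdname fleishman_coefficients
#' @export
fleishman_nonnormal <- function() {
  fleishman_coefficients(a = -0.22, b = 0.78, c_coef = 0.22, d = 0.06)
}

#' Draw abilities from a Fleishman-transformed normal
#'
#' Draws `x ~ N(0, 1)` and returns `a + b x + c x^2 + d x^3`. With the
#' identity coefficients this is exactly a standard normal sample; the
#' analytic mean is `a + c` and the analytic variance
#' `b^2 + 2 c^2 + 6 b d + 15 d^2`.
#'
#' @param n Number of draws.
#' @param coeffs A [fleishman_coefficients()].
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return Numeric vector of length `n`.
#' @export
fleishman_abilities <- function(n, coeffs = fleishman_coefficients(),
                                seed = NULL) {
  stopifnot(n >= 1, inherits(coeffs, "fleishman_coefficients"))
  if (!is.null(seed)) set.seed(seed)
  x <- stats::rnorm(n)
  coeffs$a + coeffs$b * x + coeffs$c_coef * x^2 + coeffs$d * x^3
}

#' Mean absolute deviation and root mean squared error
#'
#' The two recovery metrics: `MAD = mean(|estimate - truth|)` and
#' `RMSE = sqrt(mean((estimate - truth)^2))`. RMSE is never below MAD.
#'
#' @param estimates,truths Numeric vectors of equal length.
#' @return A one-row tibble with columns `mad`, `rmse`.
#' @examples
#' mad_rmse(c(0, 2), c(0, 0)) # mad 1, rmse sqrt(2)
#' @export
mad_rmse <- function(estimates, truths) {
  if (length(estimates) != length(truths)) {
    stop("`estimates` and `truths` must have equal length.", call. = FALSE)
  }
  e <- estimates - truths
  tibble::tibble(mad = mean(abs(e)), rmse = sqrt(mean(e^2)))
}

#' Design a continuous-data parameter-recovery study
#'
#' Builds the full factorial of sample sizes, test lengths, dispersions and
#' scenario (ability distribution and line geometry) conditions. The default
#' scenarios are the three study conditions: unit-normal abilities on a
#' length-1 line, unit-normal abilities on a length-5 line, and
#' Fleishman-non-normal abilities on a length-5 line. True item difficulties
#' are equally spaced on `[-2, 2]`; abilities are drawn per replication.
#'
#' @param sample_sizes,test_lengths,dispersions Factor levels.
#' @param scenarios Named list; each element a list with `distribution`
#'   (`"normal"` or `"nonnormal"`), `length`, `midpoint`.
#' @param replications Replications per condition.
#' @param base_seed Integer; every replication seed derives from it.
#' @return A tibble of class `recovery_design`, one row per condition.
#' @export
recovery_design <- function(sample_sizes = c(200, 500, 1000),
                            test_lengths = c(20, 40, 60),
                            dispersions = c(0.5, 2.0),
                            scenarios = list(
                              normal_L1 = list(
                                distribution = "normal",
                                length = 1, midpoint = 0.5
                              ),
                              normal_L5 = list(
                                distribution = "normal",
                                length = 5, midpoint = 2.5
                              ),
                              nonnormal_L5 = list(
                                distribution = "nonnormal",
                                length = 5, midpoint = 2.5
                              )
                            ),
                            replications = 100, base_seed = 20240101) {
  stopifnot(replications >= 1, length(scenarios) >= 1)
  des <- tidyr::expand_grid(
    dispersion = dispersions,
    test_length = test_lengths,
    sample_size = sample_sizes,
    scenario = names(scenarios)
  )
  des$distribution <- purrr::map_chr(
    des$scenario, ~ scenarios[[.x]]$distribution
  )
  des$line_length <- purrr::map_dbl(des$scenario, ~ scenarios[[.x]]$length)
  des$midpoint <- purrr::map_dbl(des$scenario, ~ scenarios[[.x]]$midpoint)
  attr(des, "replications") <- replications
  attr(des, "base_seed") <- base_seed
  class(des) <- c("recovery_design", class(des))
  des
}

# deterministic per-replication seed, kept inside 32-bit integer range
.rep_seed <- function(base_seed, cond, rep) {
  (as.numeric(base_seed) + 100003 * cond + rep) %% 2147483647
}

#' Run a Monte Carlo parameter-recovery study
#'
#' For every condition and replication: draw true abilities (normal or
#' Fleishman non-normal), set difficulties equally spaced on `[-2, 2]`,
#' simulate responses on the condition's line, rescale them to the unit
#' interval, fit the model with the original range declared (so estimates
#' come back in the original latent unit), and score MAD/RMSE per parameter
#' class against the truths. Metrics are averaged over replications;
#' non-converged replications are excluded and counted.
#'
#' @param design A [recovery_design()].
#' @param variant Model variant passed to [fit_corsm()].
#' @param progress Print a line per condition.
#' @return A tibble of class `recovery_report`: one row per condition and
#'   parameter class (`person`, `item`, `dispersion`) with `mad`, `rmse`,
#'   `n_converged`, `n_excluded`.
#' @export
run_recovery_study <- function(design, variant = "muller", progress = FALSE) {
  stopifnot(inherits(design, "recovery_design"))
  reps <- attr(design, "replications")
  base_seed <- attr(design, "base_seed")
  rows <- list()
  for (ci in seq_len(nrow(design))) {
    cond <- design[ci, ]
    geom <- scale_geometry(cond$line_length, cond$midpoint)
    acc <- list(person = NULL, item = NULL, dispersion = NULL)
    excluded <- 0L
    for (r in seq_len(reps)) {
      seed <- .rep_seed(base_seed, ci, r)
      set.seed(seed)
      ab <- if (cond$distribution == "nonnormal") {
        fleishman_abilities(cond$sample_size, fleishman_nonnormal())
      } else {
        stats::rnorm(cond$sample_size)
      }
      dif <- seq(-2, 2, length.out = cond$test_length)
      sim <- simulate_corsm(ab, dif, cond$dispersion, geom)
      unit <- rescale_scores(sim, c(geom$lower, geom$upper), c(0, 1))
      fit <- tryCatch(
        fit_corsm(unit,
          score_range = c(geom$lower, geom$upper),
          stored_range = c(0, 1), variant = variant
        ),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        excluded <- excluded + 1L
        next
      }
      theta_hat <- fit$dispersion$theta
      theta_true <- rep_len(cond$dispersion, length(theta_hat))
      acc$person <- dplyr::bind_rows(
        acc$person, mad_rmse(fit$persons$ability, ab)
      )
      acc$item <- dplyr::bind_rows(
        acc$item, mad_rmse(fit$items$difficulty, dif)
      )
      acc$dispersion <- dplyr::bind_rows(
        acc$dispersion, mad_rmse(theta_hat, theta_true)
      )
    }
    for (cls in names(acc)) {
      if (is.null(acc[[cls]])) next
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        cond,
        tibble::tibble(
          parameter = cls,
          mad = mean(acc[[cls]]$mad), rmse = mean(acc[[cls]]$rmse),
          n_converged = nrow(acc[[cls]]), n_excluded = excluded
        )
      )
    }
    if (progress) {
      message(sprintf(
        "condition %d/%d done (%d excluded)", ci, nrow(design), excluded
      ))
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_report", class(out))
  out
}

#' Run a discrete-data (Likert) parameter-recovery study
#'
#' Rating scale model data are generated with the stated threshold presets
#' ([rsm_tau_preset()]), unit-normal abilities and equally spaced
#' difficulties on `[-2, 2]`, then calibrated with the continuous model via
#' [fit_corsm_discrete()]. MAD/RMSE are scored for person abilities, overall
#' difficulties, and step difficulties (the fitted equidistant thresholds
#' against the generating ones).
#'
#' @param n_categories Vector of category counts (5, 7 or 9 use the shipped
#'   threshold presets).
#' @param test_lengths Vector of test lengths.
#' @param sample_size Persons per replication.
#' @param replications Replications per condition.
#' @param base_seed Integer seed root.
#' @return A tibble of class `recovery_report` with parameter classes
#'   `person`, `overall_difficulty`, `step_difficulty`.
#' @export
run_discrete_recovery <- function(n_categories = c(5, 7, 9),
                                  test_lengths = c(5, 10, 20, 30),
                                  sample_size = 500, replications = 100,
                                  base_seed = 20240102) {
  des <- tidyr::expand_grid(
    n_categories = n_categories, test_length = test_lengths
  )
  rows <- list()
  for (ci in seq_len(nrow(des))) {
    kk <- des$n_categories[ci]
    ii <- des$test_length[ci]
    tau <- rsm_tau_preset(kk)
    acc <- list(
      person = NULL, overall_difficulty = NULL, step_difficulty = NULL
    )
    excluded <- 0L
    for (r in seq_len(replications)) {
      set.seed(.rep_seed(base_seed, ci, r))
      ab <- stats::rnorm(sample_size)
      dif <- seq(-2, 2, length.out = ii)
      sim <- simulate_rsm(ab, dif, tau)
      fit <- tryCatch(
        fit_corsm_discrete(sim, n_categories = kk),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        excluded <- excluded + 1L
        next
      }
      acc$person <- dplyr::bind_rows(
        acc$person, mad_rmse(fit$persons$ability, ab)
      )
      acc$overall_difficulty <- dplyr::bind_rows(
        acc$overall_difficulty, mad_rmse(fit$items$difficulty, dif)
      )
      acc$step_difficulty <- dplyr::bind_rows(
        acc$step_difficulty, mad_rmse(fit$steps$tau, tau)
      )
    }
    for (cls in names(acc)) {
      if (is.null(acc[[cls]])) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        n_categories = kk, test_length = ii, sample_size = sample_size,
        parameter = cls,
        mad = mean(acc[[cls]]$mad), rmse = mean(acc[[cls]]$rmse),
        n_converged = nrow(acc[[cls]]), n_excluded = excluded
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("recovery_report", class(out))
  out
}
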
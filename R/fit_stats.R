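#' Outfit mean square statistics per item
#'
#' The unweighted mean of squared standardised residuals for each item:
#' `MNSQ_i = sum_n ((x_ni - p_ni) / sqrt(V_ni))^2 / N_i`, where `p` and `V`
#' are the model's expected score and score variance at the fitted
#' parameters and `N_i` counts the persons observed on item `i`. Values near
#' one indicate fit; the conventional acceptance band is 0.6 to 1.4, but only
#' the upper bound (underfit) triggers removal — low values still carry
#' information. For discrete-mode fits the continuous truncated-normal
#' moments at the fitted parameters are used.
#'
#' @param fit A `corsm_fit` (the response data stored in the fit are used
#'   unless `data` overrides them).
#' @param data Optional replacement response table on the fit's score range.
#' @return A tibble with columns `item`, `outfit`, `n_used`, `retained`.
#'   Items whose model variance collapses below `1e-12` anywhere get
#'   `outfit = NA` and are flagged unreliable (not retained).
#' @export
outfit_mnsq <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "corsm_fit"))
  x <- if (is.null(data)) fit$data$x else .as_response_matrix(data)$x
  geom <- fit$geometry
  .check_support(x, geom)
  nn <- nrow(x)
  ii <- ncol(x)
  stopifnot(ii == nrow(fit$items))
  theta <- rep_len(fit$dispersion$theta, ii)
  beta <- fit$persons$ability
  delta <- fit$items$difficulty
  m <- geom$midpoint +
    (matrix(beta, nn, ii) - matrix(delta, nn, ii, byrow = TRUE)) /
      (2 * matrix(theta, nn, ii, byrow = TRUE))
  ts <- .tn_stats(m, 1 / sqrt(2 * matrix(theta, nn, ii, byrow = TRUE)),
    geom$lower, geom$upper)
  z2 <- (x - ts$mean)^2 / ts$var
  obs <- !is.na(x)
  unreliable <- vapply(
    seq_len(ii),
    function(i) any(obs[, i] & ts$var[, i] < 1e-12),
    logical(1)
  )
  outfit <- vapply(seq_len(ii), function(i) {
    if (unreliable[i]) return(NA_real_)
    mean(z2[obs[, i], i])
  }, numeric(1))
  tibble::tibble(
    item = fit$items$item,
    outfit = outfit,
    n_used = colSums(obs),
    retained = !unreliable & outfit <= 1.4
  )
}

#' Items retained by the outfit rule
#'
#' Keeps every item whose outfit mean square does not exceed 1.4. Low-outfit
#' (overfitting) items are deliberately kept.
#'
#' @param records A tibble from [outfit_mnsq()].
#' @return Character vector of retained item names.
#' @export
retention_filter <- function(records) {
  stopifnot(all(c("item", "outfit") %in% names(records)))
  records$item[!is.na(records$outfit) & records$outfit <= 1.4]
}

#' Split-sample stability of item fit
#'
#' Repeatedly splits the sample into two random halves, refits the model on
#' each half, and classifies each item as fitting (outfit at or below 1.4)
#' or misfitting in every half. An item fitting in fewer than seven of ten
#' repeats within a half-stream is flagged as a consistent misfit.
#'
#' @inheritParams fit_corsm
#' @param n_repeats Number of random splits.
#' @param seed Integer seed for the splits.
#' @param ... Further arguments passed to [fit_corsm()].
#' @return A tibble with columns `item`, `half`, `fit_count`,
#'   `consistent_misfit`, plus attribute `n_failed` counting halves that
#'   failed to converge (those repeats are skipped for that half).
#' @export
split_sample_stability <- function(data, score_range, n_repeats = 10,
                                   seed = NULL, ...) {
  rm_ <- .as_response_matrix(data)
  nn <- nrow(rm_$x)
  if (nn < 40) {
    stop("Need at least 40 persons so each half supports a fit.",
      call. = FALSE
    )
  }
  if (!is.null(seed)) set.seed(seed)
  ii <- ncol(rm_$x)
  counts <- matrix(0L, ii, 2)
  used <- matrix(0L, ii, 2)
  n_failed <- 0L
  for (r in seq_len(n_repeats)) {
    idx <- sample.int(nn, floor(nn / 2))
    halves <- list(idx, setdiff(seq_len(nn), idx))
    for (h in 1:2) {
      fit <- tryCatch(
        fit_corsm(rm_$x[halves[[h]], , drop = FALSE],
          score_range = score_range, ...
        ),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        n_failed <- n_failed + 1L
        next
      }
      rec <- outfit_mnsq(fit)
      counts[, h] <- counts[, h] +
        as.integer(!is.na(rec$outfit) & rec$outfit <= 1.4)
      used[, h] <- used[, h] + 1L
    }
  }
  out <- tibble::tibble(
    item = rep(rm_$items, 2),
    half = rep(1:2, each = ii),
    fit_count = c(counts[, 1], counts[, 2]),
    n_repeats = c(used[, 1], used[, 2])
  )
  out$consistent_misfit <- out$fit_count < ceiling(0.7 * out$n_repeats)
  attr(out, "n_failed") <- n_failed
  out
}
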
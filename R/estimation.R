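#' Quadrature grid for marginalising the ability prior
#'
#' Gauss-Hermite nodes and weights transformed to represent a normal ability
#' prior `N(mean, sd^2)`: node `q` carries prior mass `weight_q`, and the
#' weights are normalised to sum to one. Twenty-one nodes are ample for a
#' unidimensional latent trait.
#'
#' @param q Number of nodes.
#' @param mean,sd Prior mean and standard deviation.
#' @return A tibble with columns `node`, `weight` (class `quadrature_grid`).
#' @export
quadrature_grid <- function(q = 21, mean = 0, sd = 1) {
  stopifnot(q >= 2, sd > 0)
  gh <- pracma::gaussHermite(q)
  w <- gh$w / sum(gh$w)
  out <- tibble::tibble(node = mean + sqrt(2) * sd * gh$x, weight = w)
  class(out) <- c("quadrature_grid", class(out))
  out
}

#' Estimation settings
#'
#' Controls for the alternating estimation loop. The inner Newton-Raphson
#' rule (stop when the largest parameter change drops below 0.001, or after
#' 25 iterations) applies within each stage; the outer loop alternates
#' item, person and dispersion stages until the largest change across all
#' parameters falls below `outer_tol`.
#'
#' @param inner_tol,inner_max_iter Within-stage Newton stopping rule.
#' @param outer_tol,outer_max_cycles Whole-loop stopping rule.
#' @param quad_q Number of quadrature nodes for the marginal likelihood.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(inner_tol = 1e-3, inner_max_iter = 25,
                       outer_tol = 1e-4, outer_max_cycles = 100,
                       quad_q = 21) {
  stopifnot(
    inner_tol > 0, inner_max_iter >= 1,
    outer_tol > 0, outer_max_cycles >= 1, quad_q >= 2
  )
  structure(
    list(
      inner_tol = inner_tol, inner_max_iter = inner_max_iter,
      outer_tol = outer_tol, outer_max_cycles = outer_max_cycles,
      quad_q = quad_q
    ),
    class = "fit_config"
  )
}

# ---------------------------------------------------------------------------
# internal engine: all computation on the centred line (midpoint at 0),
# responses U (N x I, NA for missing), mask O, half-length `half`,
# dispersion as a length-I vector (shared value replicated under the
# shared-dispersion variant).

# truncated-normal summaries at each (item, node) combination
.node_stats <- function(delta, theta, nodes, half) {
  ii <- length(delta)
  qq <- length(nodes)
  m <- (matrix(nodes, ii, qq, byrow = TRUE) - delta) / (2 * theta)
  s <- matrix(1 / sqrt(2 * theta), ii, qq)
  ts <- .tn_stats(m, s, -half, half)
  lg <- log(s) + 0.5 * log(2 * pi) + ts$logZ
  list(m = m, p = ts$mean, v = ts$var, lg = lg)
}

# log-likelihood of every person at every node: ll[n, q] = log L_n(V_q)
.ll_nodes <- function(UZ, O, theta, ns) {
  t1 <- rowSums(sweep(UZ^2, 2, theta, "*"))
  t2 <- sweep(UZ, 2, theta, "*") %*% ns$m
  t3 <- O %*% (ns$m^2 * theta)
  t4 <- O %*% ns$lg
  -t1 + 2 * t2 - t3 - t4
}

# posterior node weights and marginal log-likelihood per person
.posterior <- function(ll, logw) {
  a <- sweep(ll, 2, logw, "+")
  mx <- apply(a, 1, max)
  w <- exp(a - mx)
  den <- rowSums(w)
  list(W = w / den, marg = mx + log(den))
}

# one full Newton solve of the item MML equations at fixed dispersion
.items_newton <- function(UZ, O, delta, theta, nodes, logw, half,
                          tol, maxit, hessian_only = FALSE) {
  nn <- nrow(UZ)
  ii <- ncol(UZ)
  colx <- unname(colSums(UZ))
  iter <- 0L
  converged <- FALSE
  repeat {
    ns <- .node_stats(delta, theta, nodes, half)
    post <- .posterior(.ll_nodes(UZ, O, theta, ns), logw)
    W <- post$W
    OtW <- crossprod(O, W)
    g <- rowSums(OtW * ns$p) - colx
    T1 <- matrix(0, ii, ii)
    A <- matrix(0, nn, ii)
    for (q in seq_along(nodes)) {
      Sq <- sweep(O, 2, ns$p[, q], "*") - UZ
      SqW <- Sq * W[, q]
      T1 <- T1 + crossprod(SqW, Sq)
      A <- A + SqW
    }
    H <- T1 - crossprod(A)
    diag(H) <- diag(H) - rowSums(OtW * ns$v)
    if (hessian_only) {
      return(list(
        delta = delta, hessian = H, gradient = g,
        marg = post$marg, iterations = iter, converged = converged
      ))
    }
    if (iter >= maxit) break
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      # singular Hessian: retreat to a damped diagonal step
      dh <- diag(H)
      dh[abs(dh) < 1e-10] <- -1e-10
      step <- 0.5 * g / dh
      if (any(!is.finite(step))) {
        stop("Item estimation failed: singular Hessian.", call. = FALSE)
      }
    }
    new <- delta - step
    new <- new - mean(new) # identification: mean difficulty zero
    change <- max(abs(new - delta))
    delta <- new
    iter <- iter + 1L
    if (change < tol) {
      converged <- TRUE
      break
    }
  }
  list(delta = unname(delta), iterations = iter, converged = converged)
}

# vectorised per-person MAP Newton at fixed items and dispersion
.persons_newton <- function(UZ, O, beta, delta, theta, prior, half,
                            tol, maxit) {
  nn <- nrow(UZ)
  ii <- ncol(UZ)
  dmat <- matrix(delta, nn, ii, byrow = TRUE)
  thmat <- matrix(theta, nn, ii, byrow = TRUE)
  smat <- 1 / sqrt(2 * thmat)
  # the MAP solution satisfies |beta - mu| <= sd^2 * I * L, so a start
  # outside that window (possible when theta is tiny) is pulled back in
  bound <- prior$sd^2 * ii * 2 * half + 10 * prior$sd
  beta <- pmin(pmax(beta, prior$mean - bound), prior$mean + bound)
  iter <- 0L
  converged <- FALSE
  repeat {
    m <- (beta - dmat) / (2 * thmat)
    ts <- .tn_stats(m, smat, -half, half)
    grad <- rowSums((UZ - ts$mean) * O) - (beta - prior$mean) / prior$sd^2
    hess <- -rowSums(ts$var * O) - 1 / prior$sd^2
    step <- grad / hess
    # cap oscillation, but let prior-dominated steps travel home
    lim <- pmax(10, abs(beta - prior$mean))
    step <- pmin(pmax(step, -lim), lim)
    beta_new <- beta - step
    change <- max(abs(beta_new - beta))
    beta <- beta_new
    iter <- iter + 1L
    if (change < tol) {
      converged <- TRUE
      break
    }
    if (iter >= maxit) break
  }
  m <- (beta - dmat) / (2 * thmat)
  ts <- .tn_stats(m, smat, -half, half)
  hess <- -rowSums(ts$var * O) - 1 / prior$sd^2
  list(
    beta = beta, posterior_sd = sqrt(-1 / hess),
    iterations = iter, converged = converged
  )
}

# joint log-likelihood in theta at fixed beta, delta (centred line)
.theta_ll <- function(UZ, O, D, theta, half) {
  m <- D / (2 * theta)
  lg <- theta * m^2 + .log_kernel_norm(m, theta, -half, half)
  sum(O * (UZ * D - theta * UZ^2 - lg))
}

# damped Newton on log(theta) for one block of cells (whole matrix for the
# shared variant, one column for the per-item variant)
.theta_newton_block <- function(UZ, O, D, theta, half, tol, maxit) {
  cap <- 10
  iter <- 0L
  converged <- FALSE
  degenerate <- FALSE
  ll <- .theta_ll(UZ, O, D, theta, half)
  repeat {
    m <- D / (2 * theta)
    s <- 1 / sqrt(2 * theta)
    ts <- .tn_stats(m, s, -half, half)
    g <- sum((ts$ex2 - UZ^2) * O)
    h <- -sum((ts$ex4 - ts$ex2^2) * O)
    gu <- theta * g
    hu <- theta^2 * h + theta * g
    step <- if (is.finite(hu) && hu < 0) -gu / hu else sign(gu) * 0.5
    step <- pmin(pmax(step, -2), 2)
    lt_new <- log(theta) + step
    # damp: halve the step while the log-likelihood decreases
    for (k in 1:20) {
      lt_try <- pmin(pmax(lt_new, -cap), cap)
      ll_new <- .theta_ll(UZ, O, D, exp(lt_try), half)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      lt_new <- (lt_new + log(theta)) / 2
    }
    change <- abs(lt_try - log(theta))
    theta <- exp(lt_try)
    ll <- ll_new
    iter <- iter + 1L
    if (change < tol) {
      converged <- TRUE
      break
    }
    if (iter >= maxit) break
  }
  if (abs(log(theta)) >= cap - 1e-8) degenerate <- TRUE
  list(
    theta = theta, iterations = iter, converged = converged,
    degenerate = degenerate
  )
}

.theta_stage <- function(UZ, O, beta, delta, theta, half, variant,
                         tol, maxit) {
  nn <- nrow(UZ)
  ii <- ncol(UZ)
  D <- matrix(beta, nn, ii) - matrix(delta, nn, ii, byrow = TRUE)
  if (variant == "muller") {
    res <- .theta_newton_block(UZ, O, D, theta[1], half, tol, maxit)
    list(
      theta = rep(res$theta, ii), iterations = res$iterations,
      degenerate = rep(res$degenerate, ii)
    )
  } else {
    th <- theta
    its <- 0L
    degen <- logical(ii)
    for (i in seq_len(ii)) {
      res <- .theta_newton_block(
        UZ[, i, drop = FALSE], O[, i, drop = FALSE],
        D[, i, drop = FALSE], th[i], half, tol, maxit
      )
      th[i] <- res$theta
      its <- max(its, res$iterations)
      degen[i] <- res$degenerate
    }
    list(theta = th, iterations = its, degenerate = degen)
  }
}

# the alternating estimation loop
.fit_engine <- function(X, geom, prior, config, variant) {
  nn <- nrow(X)
  ii <- ncol(X)
  half <- geom$length / 2
  U <- X - geom$midpoint
  O <- (!is.na(U)) * 1
  UZ <- U
  UZ[is.na(UZ)] <- 0
  if (any(colSums(O) == 0)) {
    stop("Some items have no observed responses.", call. = FALSE)
  }
  gh <- quadrature_grid(config$quad_q, prior$mean, prior$sd)
  nodes <- gh$node
  logw <- log(gh$weight)

  theta <- rep(1, ii) # dispersion initialised at 1
  delta <- unname(-(colSums(UZ) / colSums(O)) / (2 * theta))
  dbound <- max(abs(nodes)) + 20 * max(theta) * geom$length + 50
  delta <- pmin(pmax(delta, -dbound), dbound)
  delta <- delta - mean(delta)
  beta <- unname((rowSums(UZ) / pmax(rowSums(O), 1)) / (2 * mean(theta)))

  log_rows <- list()
  converged <- FALSE
  cycle <- 0L
  degenerate <- logical(ii)
  repeat {
    cycle <- cycle + 1L
    old <- c(delta, beta, theta)
    it <- .items_newton(
      UZ, O, delta, theta, nodes, logw, half,
      config$inner_tol, config$inner_max_iter
    )
    delta <- it$delta
    pe <- .persons_newton(
      UZ, O, beta, delta, theta, prior, half,
      config$inner_tol, config$inner_max_iter
    )
    beta <- pe$beta
    th <- .theta_stage(
      UZ, O, beta, delta, theta, half, variant,
      config$inner_tol, config$inner_max_iter
    )
    theta <- th$theta
    degenerate <- degenerate | th$degenerate
    change <- max(abs(c(delta, beta, theta) - old))
    log_rows[[cycle]] <- tibble::tibble(
      cycle = cycle,
      item_iter = it$iterations, person_iter = pe$iterations,
      theta_iter = th$iterations, max_change = change
    )
    if (change < config$outer_tol) {
      converged <- TRUE
      break
    }
    if (cycle >= config$outer_max_cycles) break
  }

  # final pass: item standard errors from the marginal Hessian, person
  # posterior SDs, and the marginal log-likelihood
  fin <- .items_newton(UZ, O, delta, theta, nodes, logw, half,
    config$inner_tol, config$inner_max_iter,
    hessian_only = TRUE
  )
  cov <- tryCatch(solve(-fin$hessian), error = function(e) NULL)
  se <- if (is.null(cov)) rep(NA_real_, ii) else sqrt(pmax(diag(cov), 0))
  pe <- .persons_newton(
    UZ, O, beta, delta, theta, prior, half,
    config$inner_tol, config$inner_max_iter
  )
  # dispersion SE from the curvature of the joint log-likelihood
  D <- matrix(pe$beta, nn, ii) - matrix(delta, nn, ii, byrow = TRUE)
  theta_se <- if (variant == "muller") {
    m <- D / (2 * theta[1])
    ts <- .tn_stats(m, 1 / sqrt(2 * theta[1]), -half, half)
    h <- -sum((ts$ex4 - ts$ex2^2) * O)
    rep(if (h < 0) sqrt(-1 / h) else NA_real_, ii)
  } else {
    vapply(seq_len(ii), function(i) {
      m <- D[, i] / (2 * theta[i])
      ts <- .tn_stats(m, 1 / sqrt(2 * theta[i]), -half, half)
      h <- -sum((ts$ex4 - ts$ex2^2) * O[, i])
      if (h < 0) sqrt(-1 / h) else NA_real_
    }, numeric(1))
  }

  list(
    delta = unname(delta), delta_se = unname(se),
    beta = unname(pe$beta), beta_sd = unname(pe$posterior_sd),
    theta = theta, theta_se = theta_se,
    logLik = sum(fin$marg), converged = converged, cycles = cycle,
    degenerate = degenerate,
    stage_log = dplyr::bind_rows(log_rows), n_obs = sum(O)
  )
}

# ---------------------------------------------------------------------------

#' Fit the continuous rating scale model
#'
#' Estimates item difficulties by marginal maximum likelihood (Gauss
#' quadrature over a normal ability prior, Newton-Raphson on the marginal
#' score equations), person abilities by maximum a posteriori estimation
#' (finite even for all-endpoint response vectors), and the dispersion by
#' maximum likelihood, alternating the three stages to joint convergence.
#' The mean item difficulty is fixed at zero for identification.
#'
#' The latent unit follows the declared scoring range: if the data are stored
#' on a different affine range (`stored_range`, e.g. rescaled to the unit
#' interval), they are mapped back to `score_range` before fitting, so
#' estimates are always reported in the unit the scale was scored in.
#'
#' @param data Wide response table: data frame whose first (or `id_col`)
#'   column holds person ids and remaining columns item scores, or a numeric
#'   matrix. Blank cells are missing responses.
#' @param score_range Declared original score range `c(min, max)` (defines
#'   the line length and midpoint).
#' @param stored_range Range the data are currently stored on, if different
#'   from `score_range` (default: data already on `score_range`).
#' @param id_col Name of the id column, if it cannot be auto-detected.
#' @param prior_mean,prior_sd Normal ability prior (defaults `N(0, 1)`).
#' @param variant `"muller"` for one shared dispersion, `"verhelst"` for an
#'   independent dispersion per item.
#' @param config A [fit_config()].
#' @return An object of class `corsm_fit`; see [tidy.corsm_fit()],
#'   [glance.corsm_fit()], [autoplot.corsm_fit()].
#' @examples
#' sim <- simulate_corsm(rnorm(50), seq(-1, 1, length.out = 5),
#'   theta = 0.5, geom = scale_geometry(5), seed = 1
#' )
#' fit <- fit_corsm(sim, score_range = c(0, 5))
#' glance(fit)
#' @export
fit_corsm <- function(data, score_range = NULL, stored_range = NULL,
                      id_col = NULL, prior_mean = 0, prior_sd = 1,
                      variant = c("muller", "verhelst"),
                      config = fit_config()) {
  variant <- match.arg(variant)
  if (is.null(score_range)) {
    stop("Declare the original score range, e.g. score_range = c(0, 800).",
      call. = FALSE
    )
  }
  stopifnot(length(score_range) == 2L, score_range[1] < score_range[2])
  rm_ <- .as_response_matrix(data, id_col)
  x <- rm_$x
  if (!is.null(stored_range)) {
    stopifnot(length(stored_range) == 2L, stored_range[1] < stored_range[2])
    x <- (x - stored_range[1]) / diff(stored_range) * diff(score_range) +
      score_range[1]
  }
  geom <- scale_geometry(diff(score_range), mean(score_range))
  .check_support(x, geom)
  if (ncol(x) < 2L) {
    stop("At least two items are required for identification.", call. = FALSE)
  }
  prior <- list(mean = prior_mean, sd = prior_sd)
  eng <- .fit_engine(x, geom, prior, config, variant)
  dispersion <- if (variant == "muller") {
    tibble::tibble(
      theta = eng$theta[1], se = eng$theta_se[1],
      degenerate = any(eng$degenerate)
    )
  } else {
    tibble::tibble(
      item = rm_$items, theta = eng$theta, se = eng$theta_se,
      degenerate = eng$degenerate
    )
  }
  structure(
    list(
      items = tibble::tibble(
        item = rm_$items, difficulty = eng$delta, se = eng$delta_se
      ),
      persons = tibble::tibble(
        id = rm_$ids, ability = eng$beta, posterior_sd = eng$beta_sd
      ),
      dispersion = dispersion,
      variant = variant,
      geometry = geom,
      prior = prior,
      logLik = eng$logLik,
      n_obs = eng$n_obs,
      converged = eng$converged,
      cycles = eng$cycles,
      stage_log = eng$stage_log,
      config = config,
      data = list(x = x, items = rm_$items, ids = rm_$ids)
    ),
    class = "corsm_fit"
  )
}

# ---------------------------------------------------------------------------
# stage-level interfaces (useful for diagnostics and for cross-checking the
# Newton solutions against brute-force maximisers)

#' Marginal log-likelihood of a response matrix
#'
#' Quadrature approximation of the marginal likelihood: each person's ability
#' is integrated out over the normal prior represented by `grid`.
#'
#' @inheritParams fit_corsm
#' @param difficulties Item difficulty vector.
#' @param theta Dispersion (scalar, or one value per item).
#' @param geom A [scale_geometry()] or `c(min, max)` range.
#' @param grid A [quadrature_grid()] matching the prior.
#' @return A single number.
#' @export
marginal_loglik <- function(data, difficulties, theta, geom,
                            grid = quadrature_grid()) {
  geom <- .as_geometry(geom)
  .check_theta(theta)
  rm_ <- .as_response_matrix(data)
  .check_support(rm_$x, geom)
  ii <- ncol(rm_$x)
  theta <- rep_len(theta, ii)
  stopifnot(length(difficulties) == ii)
  U <- rm_$x - geom$midpoint
  O <- (!is.na(U)) * 1
  UZ <- U
  UZ[is.na(UZ)] <- 0
  ns <- .node_stats(difficulties, theta, grid$node, geom$length / 2)
  post <- .posterior(.ll_nodes(UZ, O, theta, ns), log(grid$weight))
  if (any(!is.finite(post$marg))) {
    stop(
      "Zero marginal density for person(s): ",
      paste(rm_$ids[!is.finite(post$marg)], collapse = ", "),
      call. = FALSE
    )
  }
  sum(post$marg)
}

#' Item difficulties by marginal maximum likelihood at fixed dispersion
#'
#' Newton-Raphson on the marginal score equations, starting from
#' `-(mean item score) / (2 theta)` and re-centring the mean difficulty to
#' zero after every iteration. Standard errors come from the inverse negative
#' Hessian of the marginal log-likelihood.
#'
#' @inheritParams marginal_loglik
#' @inheritParams fit_corsm
#' @return A tibble with columns `item`, `difficulty`, `se`, plus attributes
#'   `iterations` and `converged`.
#' @export
estimate_item_difficulties <- function(data, theta, geom, prior_mean = 0,
                                       prior_sd = 1, config = fit_config()) {
  geom <- .as_geometry(geom)
  .check_theta(theta)
  rm_ <- .as_response_matrix(data)
  .check_support(rm_$x, geom)
  ii <- ncol(rm_$x)
  theta <- rep_len(theta, ii)
  U <- rm_$x - geom$midpoint
  O <- (!is.na(U)) * 1
  UZ <- U
  UZ[is.na(UZ)] <- 0
  gh <- quadrature_grid(config$quad_q, prior_mean, prior_sd)
  half <- geom$length / 2
  delta <- unname(-(colSums(UZ) / colSums(O)) / (2 * theta))
  dbound <- max(abs(gh$node)) + 20 * max(theta) * geom$length + 50
  delta <- pmin(pmax(delta, -dbound), dbound)
  delta <- delta - mean(delta)
  res <- .items_newton(
    UZ, O, delta, theta, gh$node, log(gh$weight), half,
    config$inner_tol, config$inner_max_iter
  )
  fin <- .items_newton(UZ, O, res$delta, theta, gh$node, log(gh$weight),
    half, config$inner_tol, config$inner_max_iter,
    hessian_only = TRUE
  )
  cov <- tryCatch(solve(-fin$hessian), error = function(e) NULL)
  out <- tibble::tibble(
    item = rm_$items, difficulty = res$delta,
    se = if (is.null(cov)) NA_real_ else sqrt(pmax(diag(cov), 0))
  )
  attr(out, "iterations") <- res$iterations
  attr(out, "converged") <- res$converged
  out
}

#' Person abilities by maximum a posteriori estimation
#'
#' Per-person Newton-Raphson on the log posterior under the normal ability
#' prior, starting from `(mean person score) / (2 theta)`. The proper prior
#' keeps every estimate finite, including for persons who mark an endpoint on
#' every item (where plain maximum likelihood diverges).
#'
#' @inheritParams estimate_item_difficulties
#' @param difficulties Item difficulty vector.
#' @return A tibble with columns `id`, `ability`, `posterior_sd`.
#' @export
estimate_abilities <- function(data, difficulties, theta, geom,
                               prior_mean = 0, prior_sd = 1,
                               config = fit_config()) {
  geom <- .as_geometry(geom)
  .check_theta(theta)
  rm_ <- .as_response_matrix(data)
  .check_support(rm_$x, geom)
  ii <- ncol(rm_$x)
  theta <- rep_len(theta, ii)
  stopifnot(length(difficulties) == ii)
  U <- rm_$x - geom$midpoint
  O <- (!is.na(U)) * 1
  UZ <- U
  UZ[is.na(UZ)] <- 0
  beta <- (rowSums(UZ) / pmax(rowSums(O), 1)) / (2 * mean(theta))
  res <- .persons_newton(
    UZ, O, beta, difficulties, theta,
    list(mean = prior_mean, sd = prior_sd), geom$length / 2,
    config$inner_tol, config$inner_max_iter
  )
  tibble::tibble(
    id = rm_$ids, ability = res$beta, posterior_sd = res$posterior_sd
  )
}

#' Dispersion by maximum likelihood at fixed items and persons
#'
#' Newton-Raphson on the log dispersion for the joint log-likelihood of the
#' observed responses, either one shared value (`"muller"`) or one value per
#' item (`"verhelst"`). The log parameterisation keeps the estimate strictly
#' positive; degenerate (all-constant) response patterns hit the log cap and
#' are flagged.
#'
#' @inheritParams estimate_abilities
#' @param abilities Person ability vector.
#' @param theta_start Starting value.
#' @inheritParams fit_corsm
#' @return A tibble with columns `item` (per-item variant only), `theta`,
#'   `degenerate`.
#' @export
estimate_dispersion <- function(data, abilities, difficulties, geom,
                                variant = c("muller", "verhelst"),
                                theta_start = 1, config = fit_config()) {
  variant <- match.arg(variant)
  geom <- .as_geometry(geom)
  rm_ <- .as_response_matrix(data)
  .check_support(rm_$x, geom)
  ii <- ncol(rm_$x)
  stopifnot(
    length(difficulties) == ii,
    length(abilities) == nrow(rm_$x)
  )
  U <- rm_$x - geom$midpoint
  O <- (!is.na(U)) * 1
  UZ <- U
  UZ[is.na(UZ)] <- 0
  res <- .theta_stage(
    UZ, O, abilities, difficulties, rep(theta_start, ii),
    geom$length / 2, variant, config$inner_tol, config$inner_max_iter
  )
  if (variant == "muller") {
    tibble::tibble(theta = res$theta[1], degenerate = any(res$degenerate))
  } else {
    tibble::tibble(
      item = rm_$items, theta = res$theta,
      degenerate = res$degenerate
    )
  }
}
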
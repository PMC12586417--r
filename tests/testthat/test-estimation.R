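# Marginal likelihood, the three Newton stages against brute-force oracles,
# and the joint fitting loop.

test_that("quadrature grid encodes the prior", {
  gr <- quadrature_grid(21, mean = 0.5, sd = 2)
  expect_equal(sum(gr$weight), 1, tolerance = 1e-10)
  expect_true(all(diff(gr$node) > 0))
  expect_equal(sum(gr$node * gr$weight), 0.5, tolerance = 1e-8)
  expect_equal(sum((gr$node - 0.5)^2 * gr$weight), 4, tolerance = 1e-6)
})

test_that("quadrature marginal log-likelihood matches dense integration", {
  g <- scale_geometry(5)
  x <- matrix(c(1.2, 3.4), nrow = 1)
  ll <- marginal_loglik(x, difficulties = c(-0.3, 0.3), theta = 0.5, geom = g)
  orc <- oracle_marginal_ll(x, c(-0.3, 0.3), 0.5, g)
  expect_equal(ll, orc, tolerance = 1e-6)
})

test_that("independent persons add their marginal log-likelihoods", {
  s <- sim_small(n = 12, i = 3)
  x <- as.matrix(s$data[, -1])
  ll1 <- marginal_loglik(x, s$dif, s$theta, s$geom)
  ll2 <- marginal_loglik(rbind(x, x), s$dif, s$theta, s$geom)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
})

test_that("the marginal likelihood is quadrature-converged at 21 nodes", {
  s <- sim_small(n = 10, i = 3, theta = 2)
  x <- as.matrix(s$data[, -1])
  ll21 <- marginal_loglik(x, s$dif, s$theta, s$geom, quadrature_grid(21))
  ll61 <- marginal_loglik(x, s$dif, s$theta, s$geom, quadrature_grid(61))
  expect_lt(abs(ll21 - ll61), 1e-6)
})

test_that("identical items get identical, centred difficulty estimates", {
  set.seed(55)
  ab <- rnorm(40)
  g <- scale_geometry(5)
  sim <- simulate_corsm(ab, c(0.4, 0.4), 0.8, g, seed = 56)
  x <- as.matrix(sim[, -1])
  x[, 2] <- x[, 1]
  est <- estimate_item_difficulties(x, theta = 0.8, geom = g)
  expect_equal(est$difficulty, c(0, 0), tolerance = 1e-12)
})

test_that("item Newton solutions sit on the grid-search maximiser", {
  s <- sim_small(n = 30, i = 3)
  x <- as.matrix(s$data[, -1])
  est <- estimate_item_difficulties(x, theta = s$theta, geom = s$geom)
  # constrained grid on the mean-zero plane around the Newton answer
  step <- 0.005
  off <- seq(-0.05, 0.05, by = step)
  best <- c(NA, -Inf)
  for (d1 in est$difficulty[1] + off) {
    for (d2 in est$difficulty[2] + off) {
      d <- c(d1, d2, -d1 - d2)
      ll <- marginal_loglik(x, d, s$theta, s$geom)
      if (ll > best[2]) best <- c(d1, ll, d2)
    }
  }
  expect_lt(abs(best[1] - est$difficulty[1]), 0.01)
  expect_lt(abs(best[3] - est$difficulty[2]), 0.01)
})

test_that("MAP abilities sit on the per-person grid maximiser and stay finite", {
  s <- sim_small(n = 8, i = 3)
  x <- as.matrix(s$data[, -1])
  est <- estimate_abilities(x, s$dif, s$theta, s$geom)
  log_post <- function(b, r) {
    sum(log(corsm_density(r, b, s$dif, s$theta, s$geom))) + dnorm(b, log = TRUE)
  }
  for (n in 1:4) {
    bs <- seq(est$ability[n] - 0.02, est$ability[n] + 0.02, by = 1e-4)
    vals <- sapply(bs, log_post, r = x[n, ])
    expect_lt(abs(bs[which.max(vals)] - est$ability[n]), 1e-3)
  }
  # all-endpoint response vectors: MAP stays finite (MLE would diverge)
  ext <- rbind(
    rep(s$geom$upper, 3), rep(s$geom$lower, 3),
    c(2, 3, 2), c(1, 1, 4)
  )
  este <- estimate_abilities(ext, s$dif, s$theta, s$geom)
  expect_true(all(is.finite(este$ability)))
  expect_true(all(is.finite(este$posterior_sd)))
})

test_that("abilities at the midpoint score are zero under a symmetric setup", {
  g <- scale_geometry(4, 0)
  x <- matrix(0, 3, 4) # every response at the midpoint, delta = 0, mu = 0
  est <- estimate_abilities(x, rep(0, 4), theta = 1, geom = g)
  expect_equal(est$ability, rep(0, 3), tolerance = 1e-10)
})

test_that("dispersion Newton solution is bracketed by a log grid search", {
  s <- sim_small(n = 30, i = 3)
  x <- as.matrix(s$data[, -1])
  ab <- estimate_abilities(x, s$dif, s$theta, s$geom)$ability
  est <- estimate_dispersion(x, ab, s$dif, s$geom)
  expect_gt(est$theta, 0)
  grid <- exp(seq(log(0.01), log(10), length.out = 2000))
  ll <- sapply(grid, function(th) {
    sum(log(corsm_density(
      as.vector(x),
      rep(ab, 3), rep(s$dif, each = 30), th, s$geom
    )))
  })
  gstep <- log(grid[2]) - log(grid[1])
  expect_lt(abs(log(grid[which.max(ll)]) - log(est$theta)), gstep + 1e-12)
})

test_that("the joint fit converges, is identified and scale-equivariant", {
  set.seed(77)
  ab <- rnorm(60)
  dif <- seq(-1, 1, length.out = 6)
  g <- scale_geometry(5, 2.5)
  sim <- simulate_corsm(ab, dif, 0.5, g, seed = 78)
  fit <- fit_corsm(sim, score_range = c(0, 5))
  expect_true(fit$converged)
  expect_equal(mean(fit$items$difficulty), 0, tolerance = 1e-10)
  expect_true(is.finite(fit$logLik))
  expect_lt(
    fit$stage_log$max_change[nrow(fit$stage_log)], fit$config$outer_tol
  )
  # declaring the original range for unit-interval data reproduces the fit
  unit <- rescale_scores(sim, c(0, 5), c(0, 1))
  fit2 <- fit_corsm(unit, score_range = c(0, 5), stored_range = c(0, 1))
  expect_equal(fit2$items$difficulty, fit$items$difficulty, tolerance = 1e-6)
  expect_equal(fit2$persons$ability, fit$persons$ability, tolerance = 1e-6)
  expect_equal(fit2$dispersion$theta, fit$dispersion$theta, tolerance = 1e-6)
  # transform_parameters relates fits at two storage scales (the prior is
  # part of the model, so it transforms with the data)
  tr <- transform_parameters(fit, s = 5) # under x -> x/5
  fit3 <- fit_corsm(unit,
    score_range = c(0, 1),
    prior_mean = tr$prior$mean, prior_sd = tr$prior$sd
  )
  expect_equal(fit3$items$difficulty, tr$items$difficulty, tolerance = 1e-3)
  expect_equal(fit3$dispersion$theta, tr$dispersion$theta, tolerance = 1e-3)
  expect_error(fit_corsm(sim[, 1:2], score_range = c(0, 5)), "two items")
})

test_that("missing responses are skipped pairwise-complete", {
  set.seed(88)
  ab <- rnorm(50)
  dif <- c(-0.5, 0, 0.5)
  g <- scale_geometry(5)
  sim <- simulate_corsm(ab, dif, 0.8, g, seed = 89)
  x <- as.matrix(sim[, -1])
  x[sample(length(x), 20)] <- NA
  fit <- fit_corsm(x, score_range = c(0, 5))
  expect_true(all(is.finite(fit$items$difficulty)))
  expect_true(all(is.finite(fit$persons$ability)))
})

test_that("the per-item dispersion variant recovers heterogeneous spread", {
  set.seed(99)
  ab <- rnorm(300)
  dif <- seq(-1.5, 1.5, length.out = 8)
  th <- seq(0.3, 2, length.out = 8)
  g <- scale_geometry(5, 2.5)
  sim <- simulate_corsm(ab, dif, th, g, seed = 100)
  fit <- fit_corsm(sim, score_range = c(0, 5), variant = "verhelst")
  expect_equal(nrow(fit$dispersion), 8)
  expect_true(all(fit$dispersion$theta > 0))
  # recovered per-item dispersions track the generating gradient
  expect_gt(cor(fit$dispersion$theta, th), 0.9)
  expect_lt(mad_rmse(fit$dispersion$theta, th)$mad, 0.25)
  expect_equal(mean(fit$items$difficulty), 0, tolerance = 1e-10)
})

test_that("tidy, glance and plots expose the fitted tables", {
  s <- sim_small(n = 40, i = 4, seed = 140)
  fit <- fit_corsm(s$data, score_range = c(0, 5))
  expect_named(tidy(fit), c("item", "difficulty", "se"))
  expect_named(tidy(fit, "persons"), c("id", "ability", "posterior_sd"))
  expect_equal(glance(fit)$n_persons, 40)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, "persons"), "ggplot")
  expect_error(tidy(fit, "steps"), "discrete")
})
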
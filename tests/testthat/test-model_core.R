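# The response density, its normaliser, moments, and the rescaling algebra.

test_that("density is symmetric at beta = delta and integrates to one", {
  g <- scale_geometry(2, 0)
  xs <- seq(0.05, 0.95, by = 0.1)
  expect_equal(
    corsm_density(xs, 1.3, 1.3, 0.7, g),
    corsm_density(-xs, 1.3, 1.3, 0.7, g)
  )
  set.seed(42)
  for (k in 1:25) {
    beta <- rnorm(1)
    delta <- rnorm(1)
    theta <- exp(runif(1, log(0.05), log(10)))
    geom <- scale_geometry(runif(1, 0.5, 8), rnorm(1))
    total <- integrate(
      function(x) corsm_density(x, beta, delta, theta, geom),
      geom$lower, geom$upper,
      rel.tol = 1e-12
    )$value
    expect_equal(total, 1, tolerance = 1e-8)
  }
})

test_that("density matches the adaptive-quadrature oracle", {
  g <- scale_geometry(1, 0.5)
  expect_equal(
    corsm_density(0.7, beta = 1, delta = 0, theta = 0.5, geom = g),
    oracle_density(0.7, 1, 0, 0.5, g),
    tolerance = 1e-8
  )
  # random sweep across the theta range
  set.seed(7)
  for (k in 1:20) {
    geom <- scale_geometry(runif(1, 0.5, 6), rnorm(1))
    x <- runif(1, geom$lower, geom$upper)
    beta <- rnorm(1)
    theta <- exp(runif(1, log(0.05), log(10)))
    expect_equal(
      corsm_density(x, beta, 0.3, theta, geom),
      oracle_density(x, beta, 0.3, theta, geom),
      tolerance = 1e-8
    )
  }
})

test_that("density rejects out-of-support scores and non-positive theta", {
  g <- scale_geometry(1, 0.5)
  expect_error(corsm_density(1.2, 0, 0, 1, g), "support")
  expect_error(corsm_density(0.5, 0, 0, -1, g), "positive")
  expect_error(corsm_density(0.5, 0, 0, 0, g), "positive")
})

test_that("exponential-family and truncated-normal forms agree", {
  # density computed from gamma (exponential form) against the quadratic form
  set.seed(11)
  for (k in 1:30) {
    geom <- scale_geometry(runif(1, 0.5, 6), rnorm(1))
    x <- runif(1, geom$lower, geom$upper)
    beta <- rnorm(1)
    delta <- rnorm(1)
    theta <- exp(runif(1, log(0.05), log(10)))
    nb <- corsm_normalizer(beta, delta, theta, geom)
    f1 <- exp(
      x * (beta - delta) + x * (2 * geom$midpoint - x) * theta - nb$log_gamma
    )
    f2 <- corsm_density(x, beta, delta, theta, geom)
    expect_equal(f1, f2, tolerance = 1e-10)
  }
})

test_that("closed-form normaliser matches numeric integration over a sweep", {
  set.seed(21)
  for (k in 1:100) {
    geom <- scale_geometry(runif(1, 0.5, 6), rnorm(1))
    beta <- rnorm(1)
    delta <- rnorm(1)
    theta <- exp(runif(1, log(0.05), log(10)))
    nb <- corsm_normalizer(beta, delta, theta, geom)
    expect_rel_equal(nb$gamma, oracle_gamma(beta, delta, theta, geom), 1e-10)
  }
})

test_that("normaliser tends to the untruncated Gaussian integral", {
  g <- scale_geometry(200, 0)
  nb <- corsm_normalizer(0, 0, 2, g)
  expect_equal(nb$gamma, sqrt(pi / 2), tolerance = 1e-12)
})

test_that("normaliser derivatives match central finite differences", {
  g <- scale_geometry(3, 0.4)
  cases <- list(
    c(beta = 0.5, delta = -0.2, theta = 0.5),
    c(beta = -1, delta = 0.8, theta = 2),
    c(beta = 0, delta = 0, theta = 6)
  )
  for (cs in cases) {
    nb <- corsm_normalizer(cs["beta"], cs["delta"], cs["theta"], g, x = 0.9)
    h <- 1e-5
    h2 <- 1e-4 # second differences need a larger step against roundoff
    gd <- function(dd, dt) {
      corsm_normalizer(cs["beta"], cs["delta"] + dd, cs["theta"] + dt, g)$gamma
    }
    fd_d <- (gd(h, 0) - gd(-h, 0)) / (2 * h)
    fd_d2 <- (gd(h2, 0) - 2 * nb$gamma + gd(-h2, 0)) / h2^2
    fd_t <- (gd(0, h) - gd(0, -h)) / (2 * h)
    fd_t2 <- (gd(0, h2) - 2 * nb$gamma + gd(0, -h2)) / h2^2
    expect_rel_equal(nb$d_delta, fd_d, 1e-6)
    expect_rel_equal(nb$d2_delta, fd_d2, 1e-4)
    expect_rel_equal(nb$d_theta, fd_t, 1e-6)
    expect_rel_equal(nb$d2_theta, fd_t2, 1e-4)
    # exponent derivatives at the supplied score
    expect_equal(nb$a_prime_theta, 0.9 * (2 * g$midpoint - 0.9))
    expect_equal(nb$a_dprime_theta, 0)
  }
})

test_that("moments match numeric integration and respect bounds", {
  g <- scale_geometry(1, 0.5)
  mom <- corsm_moments(beta = 1, delta = 0, theta = 2, geom = g)
  orc <- oracle_moments(1, 0, 2, g)
  expect_equal(mom$mean, unname(orc["mean"]), tolerance = 1e-8)
  expect_equal(mom$var, unname(orc["var"]), tolerance = 1e-8)
  # symmetric truncation: expected score is the midpoint
  expect_equal(
    corsm_moments(0.7, 0.7, 0.5, g)$mean, g$midpoint,
    tolerance = 1e-12
  )
  # variance bound on a bounded support
  set.seed(31)
  for (k in 1:30) {
    geom <- scale_geometry(runif(1, 0.5, 6), rnorm(1))
    mm <- corsm_moments(rnorm(1), rnorm(1), exp(runif(1, -3, 2)), geom)
    expect_lte(mm$var, (geom$length / 2)^2)
    expect_gte(mm$mean, geom$lower)
    expect_lte(mm$mean, geom$upper)
  }
})

test_that("parameter transformation is the exact change of variable", {
  g <- scale_geometry(5, 2.5)
  pars <- list(
    abilities = c(-1, 0.3, 2), difficulties = c(-0.5, 0.5),
    theta = 0.8, geom = g
  )
  s <- 2
  tr <- transform_parameters(pars, s)
  expect_equal(tr$abilities, pars$abilities * 2)
  expect_equal(tr$theta, pars$theta * 4)
  expect_equal(tr$geom$length, g$length / 2)
  # identity at s = 1
  id <- transform_parameters(pars, 1)
  expect_equal(id$abilities, pars$abilities)
  # pointwise density identity: (1/s) f(x/s; transformed) = f(x; original)
  xs <- seq(g$lower + 0.01, g$upper - 0.01, length.out = 25)
  f_orig <- corsm_density(xs, pars$abilities[1], pars$difficulties[1],
    pars$theta, g)
  f_tr <- corsm_density(xs / s, tr$abilities[1], tr$difficulties[1],
    tr$theta, tr$geom) / s
  expect_equal(f_tr, f_orig, tolerance = 1e-10)
  expect_error(transform_parameters(pars, -1), "positive")
})

test_that("rescaling is affine, invertible and preserves missingness", {
  df <- data.frame(id = c("a", "b"), q1 = c(2.5, NA), q2 = c(0, 5))
  unit <- rescale_scores(df, c(0, 5), c(0, 1))
  expect_equal(unit$q1, c(0.5, NA))
  expect_equal(unit$q2, c(0, 1)) # endpoints map to endpoints
  # likert 3 on 1-5 maps to 0.5
  expect_equal(
    rescale_scores(data.frame(id = 1, q = 3), c(1, 5), c(0, 1))$q, 0.5
  )
  # round trip
  set.seed(5)
  wide <- data.frame(id = 1:4, a = runif(4, 0, 800), b = runif(4, 0, 800))
  back <- rescale_scores(
    rescale_scores(wide, c(0, 800), c(0, 1)), c(0, 1), c(0, 800)
  )
  expect_equal(back$a, wide$a, tolerance = 1e-12)
  # out-of-range value names the cell
  expect_error(
    rescale_scores(data.frame(id = "p9", q1 = 6), c(1, 5), c(0, 1)),
    "p9.*q1"
  )
})
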
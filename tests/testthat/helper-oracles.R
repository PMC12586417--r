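# Independent brute-force oracles used to check the closed-form and
# Newton-Raphson paths. These deliberately share no code with the package
# internals: plain numeric integration and grid search only.

# density via direct numeric evaluation: quadratic exponent over an
# adaptive-quadrature denominator
oracle_density <- function(x, beta, delta, theta, geom) {
  m <- geom$midpoint + (beta - delta) / (2 * theta)
  denom <- integrate(function(t) exp(-theta * (t - m)^2),
    geom$lower, geom$upper,
    rel.tol = 1e-12
  )$value
  exp(-theta * (x - m)^2) / denom
}

# normalising integral of the exponential-family form
oracle_gamma <- function(beta, delta, theta, geom) {
  integrate(
    function(t) exp(t * (beta - delta) + t * (2 * geom$midpoint - t) * theta),
    geom$lower, geom$upper,
    rel.tol = 1e-13
  )$value
}

# truncated-normal mean and variance by numeric integration
oracle_moments <- function(beta, delta, theta, geom) {
  f <- function(t) sapply(t, corsm_density, beta, delta, theta, geom)
  p <- integrate(function(t) t * f(t), geom$lower, geom$upper,
    rel.tol = 1e-12
  )$value
  v <- integrate(function(t) (t - p)^2 * f(t), geom$lower, geom$upper,
    rel.tol = 1e-12
  )$value
  c(mean = p, var = v)
}

# marginal density of one person's response vector, integrating the ability
# over the normal prior by adaptive quadrature
oracle_marginal <- function(x, delta, theta, geom, mu = 0, sigma = 1) {
  integrate(function(b) {
    sapply(b, function(bb) {
      prod(corsm_density(x, bb, delta, theta, geom)) * dnorm(bb, mu, sigma)
    })
  }, mu - 8 * sigma, mu + 8 * sigma, rel.tol = 1e-10)$value
}

oracle_marginal_ll <- function(xmat, delta, theta, geom, mu = 0, sigma = 1) {
  sum(apply(xmat, 1, function(r) {
    log(oracle_marginal(r, delta, theta, geom, mu, sigma))
  }))
}

# small model-true continuous dataset used across tests
sim_small <- function(n = 30, i = 3, theta = 0.5, geom = scale_geometry(5),
                      seed = 101) {
  set.seed(seed)
  ab <- rnorm(n)
  dif <- seq(-0.8, 0.8, length.out = i)
  list(
    ab = ab, dif = dif, theta = theta, geom = geom,
    data = simulate_corsm(ab, dif, theta, geom, seed = seed + 1)
  )
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b) / pmax(abs(b), 1e-12)), tol)
}
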
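# Stable truncated-normal primitives shared by the density, the moments and
# every estimation stage. All are internal and fully vectorised; shapes are
# preserved (vectors or matrices in, same shape out).

# log(exp(la) - exp(lb)) for la >= lb
.logspace_sub <- function(la, lb) {
  d <- lb - la
  d[d > 0] <- 0 # guard tiny FP overshoot
  la + log1p(-exp(d))
}

# log(pnorm(hi) - pnorm(lo)), stable in both tails; hi >= lo elementwise
.log_pnorm_diff <- function(lo, hi) {
  n <- max(length(lo), length(hi))
  lo2 <- rep_len(as.vector(lo), n)
  hi2 <- rep_len(as.vector(hi), n)
  out <- numeric(n)
  up <- lo2 > 0                      # both bounds in the upper tail
  dn <- hi2 < 0                      # both bounds in the lower tail
  mid <- !up & !dn
  if (any(up)) {
    out[up] <- .logspace_sub(
      stats::pnorm(lo2[up], lower.tail = FALSE, log.p = TRUE),
      stats::pnorm(hi2[up], lower.tail = FALSE, log.p = TRUE)
    )
  }
  if (any(dn)) {
    out[dn] <- .logspace_sub(
      stats::pnorm(hi2[dn], log.p = TRUE),
      stats::pnorm(lo2[dn], log.p = TRUE)
    )
  }
  if (any(mid)) out[mid] <- log(stats::pnorm(hi2[mid]) - stats::pnorm(lo2[mid]))
  if (is.matrix(lo) || is.matrix(hi)) {
    ref <- if (is.matrix(lo)) lo else hi
    dim(out) <- dim(ref)
  }
  out
}

# Moments of N(m, s^2) truncated to [a, b]. Returns logZ (log truncation
# mass), mean, var and raw moments up to order 4 (needed by the dispersion
# Newton step). Uses the standardised-moment recursion
#   mu_k = (k-1) mu_{k-2} + (alpha^{k-1} phi(alpha) - beta^{k-1} phi(beta)) / Z
# with the phi/Z ratios kept in log space so deep-tail truncations stay finite.
.tn_stats <- function(m, s, a, b) {
  # far beyond the support the distribution is numerically a point mass at
  # the nearer bound and the standardised-moment recursion loses all digits;
  # clamp the location where the saturated moments are already exact
  m <- pmin(pmax(m, a - 100 * s), b + 100 * s)
  alpha <- (a - m) / s
  beta <- (b - m) / s
  logZ <- .log_pnorm_diff(alpha, beta)
  ra <- exp(stats::dnorm(alpha, log = TRUE) - logZ)
  rb <- exp(stats::dnorm(beta, log = TRUE) - logZ)
  ta1 <- alpha * ra
  tb1 <- beta * rb
  ta2 <- alpha * ta1
  tb2 <- beta * tb1
  ta3 <- alpha * ta2
  tb3 <- beta * tb2
  mu1 <- ra - rb
  mu2 <- 1 + ta1 - tb1
  mu3 <- 2 * mu1 + ta2 - tb2
  mu4 <- 3 * mu2 + ta3 - tb3
  mean <- m + s * mu1
  var <- s^2 * (mu2 - mu1^2)
  ex2 <- m^2 + 2 * m * s * mu1 + s^2 * mu2
  ex3 <- m^3 + 3 * m^2 * s * mu1 + 3 * m * s^2 * mu2 + s^3 * mu3
  ex4 <- m^4 + 4 * m^3 * s * mu1 + 6 * m^2 * s^2 * mu2 +
    4 * m * s^3 * mu3 + s^4 * mu4
  list(logZ = logZ, mean = mean, var = var, ex2 = ex2, ex3 = ex3, ex4 = ex4)
}

# log of the Gaussian-kernel normaliser int_a^b exp(-theta (t - m)^2) dt,
# i.e. the denominator of the truncated-normal density form.
.log_kernel_norm <- function(m, theta, a, b) {
  s <- 1 / sqrt(2 * theta)
  log(s) + 0.5 * log(2 * pi) + .log_pnorm_diff((a - m) / s, (b - m) / s)
}
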
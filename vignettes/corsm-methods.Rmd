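---
title: "Estimating the continuous rating scale model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the continuous rating scale model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corsm)
library(dplyr)
```

## The model

Visual analogue scales (VAS) ask a respondent to mark a point anywhere on a
line of length $L$ with midpoint $c$; the mark $x_{ni}$ of person $n$ on item
$i$ may fall anywhere in the closed interval $[c - L/2,\; c + L/2]$,
endpoints included, so no boundary transformation of the raw scores is
needed. The continuous rating scale model (CoRSM) — a Rasch-family model for
such bounded continuous responses — gives $x_{ni}$ the density

$$
f(x \mid \beta_n, \delta_i, \theta) \;=\;
\frac{\exp\!\big[x(\beta_n - \delta_i) + x(2c - x)\,\theta\big]}{\gamma},
$$

with $\gamma$ the normalising integral of the numerator over the support.
Completing the square shows this is a doubly truncated normal with location
$c + (\beta_n - \delta_i)/(2\theta)$ and squared scale $1/(2\theta)$:

* $\beta_n$ — person location (ability) on the latent continuum;
* $\delta_i$ — item location (difficulty), identified by fixing
  $\bar\delta = 0$;
* $\theta > 0$ — dispersion: small $\theta$ spreads responses across the
  whole line (high discrimination), large $\theta$ concentrates them near
  the model location.

All internal computation re-centres the line at $c = 0$ (the model is
invariant to the choice of origin) and restores the user's midpoint at the
interface. The normaliser is evaluated as a Gaussian tail mass from
standard-normal CDF differences kept in log space, which stays accurate from
$\theta \approx 10^{-4}$ up to very large $\theta$; below that the location
term $(\beta-\delta)/(2\theta)$ of the quadratic form degrades numerically,
so the density switches to the exponential-family form with a log-space
numeric integral for its normaliser. A dedicated test sweeps
$\theta \in [0.05, 10]$ and checks the two forms agree to $10^{-10}$.

## The estimation algorithm

Three stages alternate until the largest parameter change in a full cycle
drops below `outer_tol` ($10^{-4}$ by default, at most 100 cycles):

1. **Items — marginal maximum likelihood.** Abilities are integrated out
   over a normal prior $N(\mu, \sigma^2)$ (default $N(0,1)$), approximated
   by a Gauss–Hermite grid transformed to the prior, 21 nodes by default
   with weights normalised to sum to one (a quadrature-refinement test
   confirms 21 vs 61 nodes changes the log-likelihood by under $10^{-6}$ on
   a small set). Newton–Raphson uses the full item-by-item Hessian of the
   marginal log-likelihood; starting values are
   $\hat\delta_i = -(\sum_n x_{ni}/N)/(2\theta)$, the mean difficulty is
   subtracted after every iteration, and the stage stops when the largest
   change is below $0.001$ or after 25 iterations. Standard errors come from
   the inverse negative Hessian.
2. **Persons — maximum a posteriori.** Each person's log posterior is
   maximised by a one-dimensional Newton step (vectorised across persons),
   starting from $\hat\beta_n = (\sum_i x_{ni}/I)/(2\theta)$. Because the
   exponential-family score is simply $x - E[X]$, the gradient and Hessian
   are the residual sum and the negative sum of model variances plus the
   prior terms. The proper prior keeps every estimate finite — including
   for respondents who mark an endpoint on every item, where plain maximum
   likelihood diverges. Posterior SDs are $(-1/H)^{1/2}$ at the mode.
3. **Dispersion — maximum likelihood.** With items and persons fixed, the
   joint log-likelihood is maximised over $\log\theta$ (guaranteeing
   $\theta > 0$) by damped Newton steps, halving the step while the
   log-likelihood would decrease. The score per cell is
   $E[T^2] - x^2$ and the curvature $-(E[T^4] - E[T^2]^2)$, with truncated
   normal moments from the standardised-moment recursion. All-constant
   response patterns push $\log\theta$ to the $\pm 10$ cap and are flagged
   degenerate rather than raised.

The shared-dispersion (`muller`) variant estimates one $\theta$; the
`verhelst` variant repeats stage 3 independently per item, giving item-level
dispersions $\theta_i$ alongside the difficulties.

Design choices that the method description leaves open, resolved here:
the alternation order is items → persons → dispersion (the order the stages
are derived in); the dispersion stage iterates to convergence within each
cycle rather than taking a single Newton step; person estimates do not feed
back into the item stage (under marginal ML they are not needed there);
the dispersion starts at $\theta = 1$, the midpoint of the simulated regime
on the log scale. Grid-search oracle tests (items on the mean-zero plane at
step 0.005, persons at step $10^{-4}$, dispersion on a 2000-point log grid)
confirm each Newton stage lands on the brute-force maximiser.

## Units, rescaling, and declared score ranges

Rescaling observed data changes the unit of the latent continuum: dividing
scores by $s$ multiplies abilities and difficulties by $s$ and the
dispersion by $s^2$, while the density transforms as an exact change of
variable. `fit_corsm()` therefore asks for the *declared* score range (say
0–800 pixels) and, if the data are stored on another range (say the unit
interval), maps them back before fitting — so estimates always come out in
the unit the scale was scored in, and fitting the same data at any storage
scale gives identical results up to the transformation
(`transform_parameters()`). Note the prior is part of the model and scales
with the latent unit.

## Likert-type data

A $K$-category item is treated as a discretisation of a continuous line: we
view the line as $K$ unit-width bins and score category $k$ as the bin
midpoint $k + 1/2$ on a line of length $K$, so the truncation bounds sit
half a bin beyond the extreme categories. Evaluating the continuous density
at equally spaced points gives adjacent-category log-odds that are *exactly*
a rating scale model (RSM) with equidistant thresholds
$\tau_k = \theta\,\Delta^2 (2k - 1 - m)$, $k = 1, \dots, m$, where
$m = K - 1$ and $\Delta$ is the support spacing — symmetric, zero-sum, and
in the ratio pattern $(-3, -1, 1, 3)$ for five categories. On the
bin-midpoint support the spacing is 1 and $2c/\Delta = K$, so the fitted
parameters are already in the adjacent-category metric and
$\tau_k = \hat\theta\,(2k - K)$.

The bin-midpoint convention was chosen over placing the extreme categories
on the line endpoints: on rating-scale-model test data the endpoint
convention compresses the recovered thresholds markedly (the fitted
continuous model must push density to the very ends of the line to reach the
extreme categories), while the midpoint convention recovers generating
thresholds with mean absolute error around 0.1 at $K = 5$, $I = 20$,
$N = 500$ — and a self-consistency test shows that data generated from
exactly equidistant thresholds refit to their generating dispersion within
0.1. Model fit statistics for discrete fits use the continuous
truncated-normal moments at the fitted parameters, not the discretised
category distribution; this reproduces the characteristic below-one outfit
values seen when the continuous variance is applied to discrete scores.

The calibration is deliberately an approximation when the generating
thresholds are *not* equidistant (the usual case for real Likert data): the
fitted equidistant thresholds are then the model's best one-parameter
summary of the category structure, and person/difficulty estimates absorb
some discretisation bias. The recovery harness quantifies this.

## Simulators and the recovery harness

`simulate_corsm()` draws responses by inverse-CDF sampling of the truncated
normal (exact and vectorised); `simulate_rsm()` inverts the cumulative
category probabilities against uniform draws (the smallest category whose
cumulative probability reaches the draw). Non-normal abilities come from
the Fleishman cubic $a + bx + cx^2 + dx^3$ of a standard normal; the
shipped preset $(-0.22, 0.78, 0.22, 0.06)$ produces a skewed, heavy-tailed
distribution with analytic mean $a + c = 0$ and variance
$b^2 + 2c^2 + 6bd + 15d^2 \approx 1.04$, and the generator is tested
against those closed forms rather than against printed summary statistics
(whose labels appear internally inconsistent in the source material for
this preset).

`run_recovery_study()` reproduces the continuous simulation protocol: per
replication, abilities from the declared distribution, difficulties equally
spaced on $[-2, 2]$ (an equally spaced grid keeps the mean-zero
identification exact for truth–estimate comparison), responses simulated on
the condition's line, rescaled to the unit interval, fitted with the
original range declared, and scored by MAD and RMSE per parameter class.
The default factorial is 200/500/1000 persons × 20/40/60 items ×
dispersion 0.5/2 × three geometry/distribution scenarios (unit-normal
abilities with $L = 1$ and $L = 5$, Fleishman abilities with $L = 5$), 100
replications each; every replication's seed derives deterministically from
`base_seed`, so a report is bit-reproducible. Non-converged replications
are excluded and counted rather than imputed. `run_discrete_recovery()`
does the same for the Likert path with the fixed threshold presets for
5/7/9 categories.

The generator emulates the idealised measurement model: independent
responses given the latent trait, a correctly specified response
distribution, no response styles, no missing data mechanism. Passing
recovery tests therefore demonstrate the estimation algorithm, not the
behaviour of real raters.

## Fit assessment

`outfit_mnsq()` computes the unweighted mean of squared standardised
residuals per item, $\text{MNSQ}_i = \sum_n z_{ni}^2 / N$, from the model's
expected score and score variance at the fitted parameters. Values near 1
indicate fit: the statistic is exactly calibrated ($E[z^2] = 1$, tested) when
the moments use the generating parameters, while at *estimated* parameters
the mean sits several percent below 1 (about 0.92 at $I = 20$, $N = 1000$)
because MAP-shrunken expected scores absorb part of each residual and the
dispersion estimate widens correspondingly — matching the slightly-below-one
mean outfits familiar from practice. Only values above 1.4 mark an item for
removal — low
values (overfit) are kept, as they still carry information. After removal,
refit on the retained set before reporting. `split_sample_stability()`
repeats random half-sample refits and flags items fitting in fewer than
seven of ten repeats as consistent misfits. Items whose model variance
collapses below $10^{-12}$ are flagged unreliable instead of producing
unstable ratios.

## Problem sizes and numerical tolerances

The bundled test suite runs the recovery experiments in a 20-replication
smoke mode with a $\pm 0.06$ acceptance band; `scripts/acceptance.R` runs
the full 100-replication protocol (a few minutes per condition on one
core). Analytic identities are tested tightly: density normalisation to
$10^{-8}$, equality of the two density forms to $10^{-10}$, moments against
adaptive quadrature to $10^{-8}$, fit scale-equivariance to $10^{-6}$, and
threshold equidistance/symmetry/zero-sum to $10^{-10}$.

## Known limitations

* Unidimensional only; multidimensional traits must be analysed one
  dimension at a time, ignoring their correlations.
* The normal-prior assumption of the marginal step is a working model;
  recovery under the Fleishman non-normal distribution is demonstrated to
  stay within 0.03 of the normal case at $L = 5$, but heavier departures
  are untested.
* For non-equidistant generating thresholds the discrete path is an
  approximation by construction (see above).
* Dispersion estimation treats item and person estimates as fixed (no
  joint information matrix), so its reported SE is conditional.
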
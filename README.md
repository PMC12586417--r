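# corsm

Item response theory for **bounded continuous ratings** — visual analogue
scale (VAS) marks, slider responses, pixel distances — and, through the same
model, Likert-type data.

Classical IRT treats responses as discrete categories. When a respondent
instead marks any point on a line of length *L* with midpoint *c*, the
continuous rating scale model (CoRSM, a Rasch-family model) gives the mark
*x* a doubly truncated normal density on the closed line,

```
f(x | β, δ, θ) ∝ exp[ x(β − δ) + x(2c − x)θ ],   x ∈ [c − L/2, c + L/2]
```

with location `c + (β − δ)/(2θ)` and squared scale `1/(2θ)`: person ability
β, item difficulty δ (mean fixed at 0 for identification), and dispersion θ
(small θ = responses spread across the line = high discrimination). Because
the model is a member of the Rasch family, fitted abilities and difficulties
are interval-level scores suitable for parametric statistics — provided the
data fit, which the package's outfit statistics check.

`corsm` provides, in a tidyverse-native interface (data frames in, tibbles
out, `tidy()` / `glance()` / `autoplot()` methods):

* **Estimation** (`fit_corsm()`): item difficulties by marginal maximum
  likelihood with Gauss–Hermite quadrature over a normal ability prior,
  person abilities by MAP (finite even for all-endpoint responders),
  dispersion by maximum likelihood on the log scale — alternated to joint
  convergence. One shared dispersion (`variant = "muller"`) or one per item
  (`variant = "verhelst"`).
* **Unit accommodation**: you declare the original score range (0–800
  pixels, 0–1, …); data stored on any other affine range are mapped back, so
  estimates are reported in the unit the scale was scored in
  (`transform_parameters()` gives the exact rescaling algebra).
* **Likert-type data** (`fit_corsm_discrete()`): a K-category item is the
  discretisation of a length-K line; the fit reports abilities,
  difficulties and the equidistant step difficulties
  `τ_k = θ(2k − K)` of the equivalent rating scale model.
* **Simulators** (`simulate_corsm()`, `simulate_rsm()`,
  `fleishman_abilities()`) and a **Monte-Carlo recovery harness**
  (`run_recovery_study()`, `run_discrete_recovery()`) with MAD/RMSE
  scoring.
* **Fit statistics** (`outfit_mnsq()`, `retention_filter()`,
  `split_sample_stability()`): outfit mean squares with the 0.6–1.4 band
  (only values above 1.4 remove an item) and a half-sample stability check.
* A **command line** (`inst/exec/corsa`, or `cli_main()`) with `fit`,
  `simulate`, `recover`, `fitstats` and `template` subcommands over wide
  CSV files.

## Worked example

Simulate 200 respondents on twenty items of a 0–5 line, rescale to the unit
interval (as platforms routinely store VAS data), and fit with the original
range declared:

```r
library(corsm)

set.seed(1)
abilities <- rnorm(200)
difficulties <- seq(-2, 2, length.out = 20)
geom <- scale_geometry(5, 2.5)

sim  <- simulate_corsm(abilities, difficulties, theta = 0.5, geom, seed = 2)
unit <- rescale_scores(sim, c(0, 5), c(0, 1))
fit  <- fit_corsm(unit, score_range = c(0, 5), stored_range = c(0, 1))

glance(fit)
#> # A tibble: 1 × 7
#>   n_persons n_items variant theta logLik converged cycles
#>       <int>   <int> <chr>   <dbl>  <dbl> <lgl>      <int>
#> 1       200      20 muller  0.487 -4764. TRUE          20
mad_rmse(fit$persons$ability, abilities)
#> # A tibble: 1 × 2
#>     mad  rmse
#>   <dbl> <dbl>
#> 1 0.215 0.273
mad_rmse(fit$items$difficulty, difficulties)
#> # A tibble: 1 × 2
#>      mad   rmse
#>    <dbl>  <dbl>
#> 1 0.0666 0.0871
```

Despite the storage rescaling, the dispersion comes back at 0.487 against a
generating value of 0.5, and abilities/difficulties are recovered in the
original 0–5 latent unit — the unit-accommodation property that
distinguishes this estimator from tools that rescale data without adjusting
the latent metric. `tidy(fit)` gives the item table with standard errors,
`tidy(fit, "persons")` the abilities with posterior SDs, and
`outfit_mnsq(fit)` the item fit table.

For Likert data:

```r
likert <- simulate_rsm(rnorm(500), seq(-2, 2, length.out = 20),
                       rsm_tau_preset(5), seed = 3)
dfit <- fit_corsm_discrete(likert, n_categories = 5)
dfit$steps      # equidistant step difficulties in the (-3, -1, 1, 3) ratio
```

See the methods vignette (`vignettes/corsm-methods.Rmd`) for the model, the
algorithm, and every numerical design decision.

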
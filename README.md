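# limcomp

Bayesian measurement of ipsative trait profiles from **compositional
forced-choice items** — items where a respondent distributes a fixed total
(e.g. 100 points) across *D* statements, one per latent dimension. The
package is for psychometricians and survey methodologists who work with
points-allocation tests (value surveys, organizational-culture instruments,
career-interest batteries) and need trait estimates with Rasch-style
measurement properties, convergence they can rely on, and honest model
checking.

## The model

Scores from such items are compositional, so the analysis happens on
additive log ratios against each item's reference slot,
`Y_kD = log(X_k / X_D)`. The **lognormal ipsative model (LIM)** decomposes
each ratio as

```
Y_kD = (θ_k + δ_k) − (θ_D + δ_D) + ε_kD,   ε_kD ~ N(0, σ²_ε)
```

with ipsatized person traits θ (Σ_d θ_d = 0 per person), one utility δ per
statement (per-dimension sum-zero over the test's item slots), and a single
noise variance. It is a one-parameter, Rasch-type model: differences
between persons' expected ratios are free of the item parameters, and
differences between items are free of the person parameters (specific
objectivity). Estimation is by a fully conjugate blocked Gibbs sampler over
θ, δ, σ²_ε and the population mean μ and covariance Σ of the free trait
block, with standard priors (δ ~ N(0,1), θ₋D ~ MVN(μ, Σ), μ_d ~ N(0,1),
Σ ~ InvWishart(I, D−1), σ² ~ InvGamma(1,1)).

Around the core model the package provides screening and multiplicative
zero imputation, Gelman–Rubin convergence diagnostics, Fisher
information / approximate standard errors and reliability, posterior
predictive model checking with a profile-differentiation discrepancy, a
two-parameter Thurstonian comparator (of which the LIM is the equal-slopes,
ipsatively constrained special case), and a seeded simulation harness for
parameter-recovery and convergence-rate studies. A 40-item, four-dimension
value-test linkage design ships as a fixture (`value_test_design()`).

## Worked example

```r
library(limcomp)

# a 250-person, 10-item, four-dimension compositional test
sim <- simulate_lim(n_persons = 250, n_items = 10, n_dims = 4,
                    correlation = 0.5, sigma2 = 0.087, seed = 42)
fit <- fit_lim(sim$data, sim$design, n_chains = 2,
               n_burnin = 1000, n_draws = 1500, seed = 1)
fit
#> <lim_fit:lim> 250 persons x 10 items x 4 dims; 2 chains x 1500 draws
#>   sigma2 = 0.0878; max PSR = 1.005; converged: TRUE
```

The fit recovers the generating noise variance (0.0878 against a true
0.087) and every monitored potential scale reduction factor is below 1.1,
so the two chains agree. Posterior summaries are tidyverse-friendly:

```r
head(tidy(fit, blocks = "delta"), 3)
#> # A tibble: 3 × 4
#>   block term          estimate std.error
#> 1 delta delta[s01_01]    0.278     0.481
#> 2 delta delta[s02_01]    0.564     0.470
#> 3 delta delta[s03_01]   -0.939     0.480

reliability(fit)
#> # A tibble: 4 × 4
#>   dimension trait_var error_var   rho
#> 1 dim1          0.335   0.00592 0.982
#> 2 dim2          0.371   0.00594 0.984
#> 3 dim3          0.341   0.00593 0.983
#> 4 dim4          0.444   0.00164 0.996
```

Reliability is the share of observed trait-estimate variance not due to
estimation error; here the short 10-item test already measures the
profiles precisely because the log-ratio noise is small. Model–data fit by
posterior predictive checking compares the observed sum of profile
differentiation (the range of each person's dimension totals on the raw
100-point scale) with its distribution over model replicates:

```r
ppmc(fit, sim$data, sim$design, n_rep = 500, seed = 1)
#> <lim_ppmc> observed total differentiation 76358.20 at the 37.6th percentile
#>   of 500 replicates; pr = 0.624 (acceptable fit)
```

`pr` between 0.025 and 0.975 means the observed differentiation is typical
of data the fitted model generates — as it should be here, since the data
came from the model. The estimated utilities correlate 0.9995 with the
generating ones on the identified scale.

A thin command-line front end (`inst/cli/limcomp.R`) exposes
`simulate | fit | ppmc | reliability | recover` for scripted pipelines;
every subcommand writes its artifacts plus a seed-carrying JSON manifest.

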
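---
title: "Measuring ipsative profiles from compositional forced-choice items"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ipsative profiles from compositional forced-choice items}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limcomp)
```

## The measurement problem

Compositional forced-choice items ask a respondent to distribute a fixed
total — typically `C = 100` points — across `D` statements, each written for
a different latent dimension (say, four value orientations). The resulting
scores are *ipsative*: they sum to `C` within every item, so they carry
information only about the within-person profile, never about a person's
absolute standing on a single trait. They are also *compositional*:
strictly positive parts of a fixed whole, which calls for log-ratio
analysis rather than raw-scale modelling.

`limcomp` implements a lognormal ipsative model (LIM) for such data. With
the last slot of each item as the reference part, the additive log-ratio
(ALR) transform maps each `D`-part allocation to `D - 1` ratios
`Y_k = log(X_k / X_D)`, and the model decomposes each ratio as

    Y_k = (theta_k + delta_k) - (theta_D + delta_D) + eps,
    eps ~ N(0, sigma2),

where `theta_d` are a person's ipsatized traits (summing to zero over
dimensions), `delta` is the utility — the general attractiveness — of the
statement occupying the slot, and the `D - 1` ratio errors of an item are
independent with one shared variance `sigma2`. The model is a Rasch-type,
one-parameter model: person contrasts are free of the statement utilities
and statement contrasts are free of the sample (specific objectivity), and
both identities are enforced in the test suite by perturbation.

A two-parameter Thurstonian comparator (TMC) with per-statement slopes and
pairwise locations is included. The LIM is its special case with all slopes
equal to one and the ipsative trait constraint switched on. With equally
keyed statements (all slopes effectively equal) the comparator's loading
structure is rank-deficient and its scale is only weakly identified; its
well-documented convergence failures in that regime are a *finding* the
package reports via the potential scale reduction factor, never an error it
tries to repair.

## Estimation

The joint posterior over `theta`, `delta`, `sigma2`, and the population
mean `mu` and covariance `Sigma` of the free trait block is sampled by a
blocked Gibbs sampler. The priors follow the model's standard Bayesian
setup: `delta ~ N(0, 1)`, the free traits `theta_{-D} ~ MVN(mu, Sigma)`,
`mu_d ~ N(0, 1)`, `Sigma ~ InvWishart(I, D - 1)`, and
`sigma2 ~ InvGamma(1, 1)`. Because the model is linear-Gaussian given the
log ratios, every full conditional is available in closed form:

* all persons' free trait rows share a single precision matrix, so the
  whole trait block is drawn with one Cholesky factorization per sweep;
* the utilities are drawn jointly from their multivariate normal
  conditional through the signed statement-incidence matrix, which also
  handles statements shared across items;
* `sigma2`, `mu` and `Sigma` use the usual inverse-gamma, normal and
  inverse-Wishart conjugate updates.

Exact conjugate draws need no proposal tuning, have unit acceptance, and
mix essentially as independent draws — which is why the desk-scale chain
lengths below suffice. The comparator uses the same machinery except for
its slopes, which have a lognormal(0, 0.5) prior and are updated by
per-statement adaptive random-walk Metropolis on the log scale (adaptation
targets 0.2–0.5 acceptance and freezes at the end of burn-in).

### Identification

Two constraints identify the LIM: each person's traits sum to zero (only
`D - 1` coordinates are sampled; the reference coordinate is minus their
sum), and each dimension's utilities sum to zero over the item slots of the
design, counting repetitions. The second constraint is enforced by
projection after every sweep. Subtracting a constant from one dimension's
utilities changes the likelihood, so the projection is paired with the
compensating shift of the free traits and `mu` that leaves every expected
log ratio unchanged; the chain therefore keeps targeting the posterior,
expressed on the identified manifold.

One consequence matters for simulation studies. Generated tests center
utilities *within items* (so each item's `D` slot utilities sum to zero),
while estimation identifies them by *per-dimension* slot sums. The two
parameterizations differ by a constant per dimension — roughly 0.1 in
magnitude for 10–40 item tests — which is not an estimation error and does
not shrink with the sample. The recovery harness therefore maps the
generating truth to its identified representative (the same
likelihood-invariant shift) before computing bias and RMSE. The grand mean
of the utility bias and all covariance comparisons are unaffected by this
choice; per-statement RMSE would otherwise be dominated by the offset.

The reference slot is fixed to the last dimension of every item. Because
the `D - 1` ratio errors are taken as independent, the likelihood is not
invariant to this choice; the convention is stated rather than hidden.

## Preprocessing

Zeros make the log ratios infinite, so they are repaired by multiplicative
imputation: each zero becomes `kappa` (default 0.5 points) and the nonzero
scores of the same item are scaled by `1 - m * kappa / C` (`m` zeros in the
row), preserving the total exactly and the rank order of the positive
scores. `kappa = 0.65` times the smallest possible response is exposed as
the common alternative. Imputation is only well supported while zeros are
rare; above a 10% zero share the function warns rather than fails, since
the right remedy (redesigning the test or respecting the zeros as
structural) is not the package's call to make. Screening removes two
nonsense patterns before fitting: respondents who give the full total to
the same slot position in every item (generalized from the "always the
first statement" case to any slot, since the printed rule is one instance
of the class), and — when response times are supplied — respondents below a
300-second floor.

## Diagnostics

The Fisher information for any trait is `I / sigma2` (test length `I`),
independent of traits and utilities, giving the constant approximate
standard error `sqrt(sigma2 / I)`. Reliability per dimension is the classic
ratio `(var(theta_hat) - SE^2) / var(theta_hat)`. The error variance that
should enter this ratio is genuinely ambiguous: the Fisher-based constant
does not reproduce published reliabilities for comparable data, so the
default uses each dimension's mean squared posterior SD (the Bayesian
measurement variance), with the Fisher variant behind `error = "fisher"`.
Neither variant is asserted against any published value.

Model–data fit uses posterior predictive checking with the sum over
persons of *profile differentiation* — the range of a person's dimension
score totals — as the discrepancy. The statistic is computed on RAW scores
(points, not proportions or log ratios): differentiation is defined on
observed allocations, and the raw scale is where test users read profiles.
Replicates are generated at the log-ratio level from evenly spaced,
seeded posterior draws and mapped back through the inverse ALR, matching
the model's noise structure. `pr` is the proportion of replicated
statistics at least as large as the observed one (ties count), with
misfit flagged outside (0.025, 0.975). Under the true model the check is
approximately uniform, which the suite verifies by simulation.

## The simulation harness

`simulate_lim()` reproduces the generative structure of the published
simulation design: utilities drawn U(−1.2, 1.2) and centered within items;
normative traits MVN with zero means, unit SDs and a common inter-trait
correlation from {0.8, 0.5, 0.2, 0, −0.2} or a published "real-world"
four-trait matrix; ipsatized truths obtained by subtracting each person's
mean; responses built from noisy log ratios and the inverse ALR. The
printed real-world matrix is sign-inconsistent in one pair, so it is
symmetrized from its lower triangle (the result is positive definite). The
generating noise variance is not stated in the source design; the default
0.087 adopts the empirical error-variance estimate from the 40-item value
test, and it is configurable.

What the generator deliberately does *not* emulate: discrete responding
(people type integers; the model generates continuous allocations),
response styles, zero inflation, attention lapses, or item-content
effects. Passing recovery tests therefore demonstrate correctness of the
estimator under the model's own assumptions, not robustness to real survey
behaviour.

`run_recovery()` scores bias and RMSE per parameter block and, for the
trait covariances, relative and relative-absolute bias. Covariance truths
are the *realized* sample covariances of each replication's generated
ipsatized traits rather than the population matrix: the estimator sees one
trait realization, and at `N = 250` the trait-sampling noise alone would
swamp the published tolerance band, which tracks estimation error given
the realization (it tightens with test length). The estimated
`(D-1) x (D-1)` covariance of the free block is extended to the full
`D x D` ipsatized covariance through the sum-zero map before scoring, and
entries with near-zero truth are excluded from relative metrics.
"Convergence" for a replication means every monitored PSR (all utilities,
`sigma2`, `mu`, the covariance entries, and 50 person-trait scalars) is
below 1.1 — the conventional threshold, configurable, since the source
analyses report PSR values without stating their cut.

## Problem sizes and numerical choices

The package's reference desk-scale study uses 2 chains of 1,000 burn-in
plus 1,500 retained sweeps over 10 seeded replications per condition —
sized so that a condition runs in about a minute while leaving PSR and the
recovery metrics stable; the full 3 × 3 × 6 grid at 100 replications and
10,000 + 10,000 sweeps remains available through the same interface.
Other conventions: chains are reproducible bit for bit from (seed, config,
data), with chain `c` seeded at `seed + c - 1`; degenerate PSR (zero
within-chain variance) is defined as 1 with a warning; compositions are
validated to their declared total at relative tolerance 1e-6 on input and
1e-9 after imputation; the ALR round trip is exact to 1e-10 relative
error; all arrays are 0-based internally only in the sense of R's native
indexing — reports and files are 1-based throughout.

## Limitations

The LIM yields ipsative scores only: between-person comparison is
meaningful for profiles and differentiation, not for single traits. The
independence of an item's `D - 1` log ratios is an assumption of
convenience inherited from the likelihood's form; a person-level error on
the reference statement would correlate them. Unidimensional tests are
outside the model (a single dimension carries no information under the
sum constraint), unfolding (ideal-point) response processes are not
modelled, and the comparator's identification under MCMC is scaffolding
for the convergence comparison, not a recommended analysis of real data.
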
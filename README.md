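# scalesel

Informed Bayesian selection of spatial extents for landscape covariates.

## The problem

Ecological responses measured at survey sites often depend on landscape
covariates (proportion forest, proportion developed land, …) summarised
within a circular buffer — but at an unknown radius, the *scale of
effect*. Covariates extracted at nested radii are extremely correlated
(adjacent extents often correlate above 0.95), and popular
latent-indicator methods for choosing the radius (SS-style scale
selection, BLISS) assume the covariate belongs in the model at *some*
scale. When it is unclear whether the covariate matters at all, that
assumption biases every probability they report.

`scalesel` treats the question as discrete model selection over `K + 1`
models — one intercept-only *no-association* model `M0` plus one model
per extent,

    M0: y = b0 + e        Mk: y = b0 + bk * x_k + e,   e ~ N(0, sigma^2)

with an informed prior `Pr(Mk)` over the model set (e.g. half the mass
on `M0`, the rest stair-stepped across extents). Posterior model
probabilities are `Pr(Mk | y) ∝ Pr(Mk) p(y | Mk)`, with the marginal
likelihood `p(y | Mk)` available in closed form for Gaussian coefficient
priors and known error variance. For settings without closed forms the
package provides a Gibbs-formulated reversible-jump sampler: every model
is sampled independently (parallelisable), inactive coefficients are
completed from moment-matched pseudo-priors, and probabilities are
estimated by Rao-Blackwell averaging of the model indicator's full
conditional, with an across-chain Monte Carlo error.

Also included: reconstructions of the SS and BLISS competitors,
synthetic generators for nested-extent proportion covariates (annulus
construction with an analytic correlation oracle, plus a compositional
eight-class variant and a raster-extraction path), a comparison-study
harness with exact truths, and a univariate screening workflow for many
covariates.

## Worked example

```r
library(scalesel)

covs  <- simulate_extent_covariates(100, seed = 42)   # 10 extents, 500-5000 m
y     <- simulate_response(covs, target_extent = 2500, beta0 = 1,
                           beta = 1.8, sigma = 1, seed = 43)
prior <- point_mass_prior(0.5, rep(1, 10), extents = covs$extents)

exact_posterior_model_probs(y, covs, prior, sigma2 = 1)
#> posterior model probabilities (exact)
#>  model   prob mc_error method
#>   null 0.0687        0  exact
#>    500 0.0539        0  exact
#>   1000 0.0875        0  exact
#>   1500 0.0742        0  exact
#>   2000 0.0715        0  exact
#>   2500 0.1065        0  exact
#>   3000 0.1214        0  exact
#>   3500 0.1243        0  exact
#>   4000 0.1120        0  exact
#>   4500 0.0920        0  exact
#>   5000 0.0880        0  exact
```

Reading the output: the no-association probability has dropped from its
prior 0.5 to 0.069 — the covariate clearly matters — but with
inter-extent correlations of 0.85–0.99 this effect size cannot pin one
radius down sharply, so the remaining mass spreads over neighbouring
mid-range extents (the true scale here is 2500 m). The sampling-based
estimator reproduces the same numbers to Monte Carlo accuracy:

```r
run_infr(y, covs, prior, sigma2 = 1, config = rj_config(seed = 7))
#> posterior model probabilities (infR)
#>  model   prob mc_error method
#>   null 0.0676 0.004140   infR
#>    500 0.0538 0.000292   infR
#>   1000 0.0868 0.000399   infR
#>   ...  (remaining extents match the exact values to ~0.001)
```

Screening several covariates (here the synthetic eight-class
composition, response driven by forest at 5 km):

```r
mc <- simulate_multiclass_covariates(100, seed = 1)
y8 <- simulate_response(mc$forest, 5000, beta0 = 1, beta = 8, sigma = 1,
                        seed = 2)
scr <- screen_variables(y8, mc,
                        stair_step_prior(10, 0.5,
                                         extents = mc$forest$extents),
                        sigma2 = 1)
scr$summary[scr$summary$variable == "forest", ]
#>  variable    null_prob top_extent_m top_extent_prob flagged
#>    forest 1.171493e-36         6000       0.3801963    TRUE
```

The truly active variable keeps essentially no mass on "no association"
and concentrates its extent mass at and adjacent to the true 5 km scale
(0.38 at 6 km, 0.36 at 5 km for this draw).

A thin command-line wrapper ships in `inst/scripts/scalesel`
(subcommands `prior`, `simulate`, `screen`), e.g.
`scalesel prior --stair-step 10 --null-mass 0.5`.

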
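# mixglm

Clusterwise regression — fitting a finite mixture of generalized linear
models — is a standard tool when a sample hides latent groups whose
response depends differently on the covariates: subpopulations of counties
with different epidemic growth profiles, market segments with different
price sensitivity, patient strata with different dose response.  Fitting
such a mixture is well served by existing software; *assessing* the fit is
not.  The classical deviance R² of a single GLM says nothing about how a
mixture splits the data, and sum-of-squares decompositions ignore that
clusters can have very different dispersions.

`mixglm` fits mixtures of Gaussian, Poisson and binomial regressions by a
weighted-EM algorithm, and then decomposes the model's deviance over the
fitted *soft* partition — the posterior membership probabilities
ẑᵢⱼ — to answer three questions at once: how separated are the clusters
along the response, how much do the covariates explain within clusters,
and how much remains unexplained.

## The measures

With soft sizes n̂ⱼ = Σᵢ ẑᵢⱼ, soft cluster means ȳⱼ = Σᵢ ẑᵢⱼ yᵢ / n̂ⱼ, the
grand mean ȳ, fitted means μ̂ᵢⱼ and fitted dispersions ϕ̂ⱼ, every measure
is twice a difference of ẑ-weighted log-likelihoods:

* **Local deviances**, per cluster j: the local null deviance
  **Dⱼ** (saturated vs. the cluster's intercept-only model ȳⱼ), the local
  residual deviance **RDⱼ** (saturated vs. fitted), and the local
  explained deviance **EDⱼ** (fitted vs. intercept-only), with
  Dⱼ = EDⱼ + RDⱼ.
* **Totals**: within deviance WD = Σⱼ Dⱼ, explained-within EWD = Σⱼ EDⱼ,
  residual-within RWD = Σⱼ RDⱼ, between deviance BD = Σⱼ BDⱼ (the
  discrepancy between ȳⱼ and ȳ), and the total deviance
  **TD = BD + EWD + RWD**.
* **Normalized shares** NBD + NEWD + NRWD = 1: cluster separation along
  the response, covariate contribution, and unexplained remainder; the
  explained share is NED = 1 − NRWD.
* **Deviance R²**: locally R²ⱼ = EDⱼ/Dⱼ, and overall
  **R² = EWD/WD = Σⱼ (Dⱼ/WD) R²ⱼ**, a weighted average of the local
  values.  Degree-of-freedom-adjusted variants are computed but flagged
  *descriptive-only*: the soft partition changes whenever the model does,
  so adjusted values must never drive model selection.

For Gaussian components these reduce to standardized (Pearson) weighted
sums of squares with the cluster variances σ̂ⱼ² in the denominator; for
Poisson and binomial they reduce to the familiar count-scale deviance
formulas with the 0·ln 0 = 0 convention.

## Worked example

Two Gaussian regression clusters with opposite slopes and unequal
variances (the "large separation, good fit" benchmark condition,
n = 1000):

```r
library(mixglm)

dat <- generate_mixture_data(simulation_condition("gaussian", 8), seed = 1)
fit <- mixglm(dat, y ~ x, family = "gaussian", k = 2,
              labels = "class", init = "true_labels")
fit
#> Mixture of 2 gaussian regressions (n = 1000, d = 1)
#> log-likelihood -889.8096 after 5 EM iterations (converged)
#> pi:   0.5174  0.4826
#> coefficients:
#>         [,1]    [,2]
#> [1,] -1.2045 -0.3828
#> [2,]  1.1985  0.4050
#> sigma: 0.4198  0.2103
#> BIC 1827.973   ICL 1868.038

dec <- deviance_decomposition(fit)
glance(dec)
#> # A tibble: 1 × 11
#>      WD     BD   EWD   RWD     TD   NBD  NEWD   NRWD   NED    R2 R2bar
#>   <dbl>  <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl> <dbl>
#> 1 3406. 20468. 2406. 1000. 23873. 0.857 0.101 0.0419 0.958 0.706 0.706
```

Reading the output: the generating intercepts ±1.2, slopes ∓0.4 and
standard deviations (0.4, 0.2) are recovered; NBD = 0.857 says the two
clusters are strongly separated along y; NEWD = 0.101 is the share the
covariate explains within clusters; only NRWD = 4.2% of the total
deviance is left unexplained.  The overall deviance R² = 0.706 is the
Dⱼ/WD-weighted average of the local values (`tidy(dec)` shows
R²₁ = 0.464, R²₂ = 0.802 — the second cluster's smaller variance makes
its regression fit tighter).

`tidy(fit)` returns the component coefficients with approximate standard
errors, `augment(fit)` the per-observation posteriors and MAP labels,
`autoplot(fit)` and `autoplot(dec)` the standard diagnostic figures.
`run_condition()` runs the seeded Monte Carlo harness over the built-in
benchmark conditions, and `fit_report()` / `simulate_report()` (plus the
thin CLI in `inst/cli/mixglm.R`) write JSON/CSV reports for batch use —
including the Poisson-with-population-offset rate model used for
epidemiological counts.

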
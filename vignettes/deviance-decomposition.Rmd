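---
title: "Deviance decompositions for mixtures of GLMs: model, measures, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deviance decompositions for mixtures of GLMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixglm)
```

## The model

`mixglm` fits the clusterwise regression model

$$f(y_i \mid x_i; \psi) \;=\; \sum_{j=1}^{k} \pi_j\, f(y_i; \mu_{ij}, \phi_j),
\qquad g(\mu_{ij}) = \beta_j' x_i^{*},$$

a finite mixture of $k$ generalized linear regressions with canonical
links: identity (Gaussian), log (Poisson), logit (binomial with a fixed
number of trials $m$, responses kept on the count scale $y_i \in \{0,
\dots, m\}$).  Each component has its own coefficient vector $\beta_j$
and, in the Gaussian case, its own variance $\sigma_j^2$; $x_i^{*}$
includes an intercept.  The model assumes observations are independent
given the covariates, that every component follows the *same*
exponential-family member, and that mixing weights do not depend on the
covariates.

Estimation is by EM.  The E-step computes posterior membership
probabilities $\hat z_{ij} \propto \pi_j f(y_i; \mu_{ij}, \phi_j)$ in log
space with max-subtraction; the M-step updates $\hat\pi_j = \hat n_j/n$
(where $\hat n_j = \sum_i \hat z_{ij}$ is the soft size) and solves one
weighted GLM per component, with the posterior column as prior weights —
weighted least squares for Gaussian components, weighted IRLS otherwise.
The observed-data log-likelihood is monotone along the iterations, which
the code asserts on every run.

## The deviance measures

All assessment happens *after* fitting, at the fitted soft partition
$\hat z_{ij}$ and the fitted dispersions $\hat\phi_j$.  Freezing both is
deliberate: the measures are meant to isolate the contribution of the
regressors, not of changes in the partition or the dispersion.  Every
measure is twice a difference of $\hat z$-weighted log-likelihoods
between two nested mean specifications:

| measure | compares | meaning |
|---|---|---|
| $D_j$ | saturated vs. local intercept-only ($\bar y_j$) | local spread |
| $RD_j$ | saturated vs. fitted $\hat\mu_{ij}$ | local lack of fit |
| $ED_j$ | fitted vs. local intercept-only | local covariate effect |
| $BD_j$ | local intercept-only vs. grand mean $\bar y$ | separation contribution |

with $\bar y_j = \sum_i \hat z_{ij} y_i / \hat n_j$ the soft weighted
response mean and $\bar y$ the unweighted sample mean.  Sums over
clusters give the within deviance $WD$, its split $WD = EWD + RWD$, the
between deviance $BD$, and the total deviance $TD$, computed
independently from the grand-mean null model and checked against the
identity $TD = BD + EWD + RWD$ at every call (tolerance $10^{-8}$
relative).  Dividing by $TD$ gives the normalized shares
$NBD + NEWD + NRWD = 1$; the local and overall deviance R² are
$R^2_j = ED_j / D_j$ and $R^2 = EWD / WD = \sum_j (D_j/WD)\, R^2_j$.

For each family the generic log-likelihood differences collapse to closed
forms, which is what `local_deviances(method = "closed")` evaluates:
standardized weighted sums of squares $\sum_i \hat z_{ij}(y_i - \cdot)^2 /
\hat\sigma_j^2$ for Gaussian (so clusters with different variances are
comparable — these are soft Pearson residuals, which coincide with
deviance residuals here), and the usual count-scale formulas for Poisson
and binomial under the $0 \ln 0 = 0$ convention.  The slower
`method = "loglik"` route evaluates the defining log-likelihood
differences with exact densities; the test suite asserts the two routes
agree to $10^{-8}$ relative on random instances of all three families.

Two structural facts worth knowing:

* For one-parameter families ($a(\phi)$ constant across components) the
  total deviance is partition-free — the $\hat z_{ij}$ sum out — so $TD$
  is identical across different fits of the same data.  For Gaussian
  mixtures each bracket of $TD$ is scaled by its component's
  $\hat\sigma_j^2$ under the fitted model, so $TD$ does depend on the
  fit.
* At a converged fit all of $D_j, RD_j, ED_j, BD_j \ge 0$ and both R²
  measures lie in $[0, 1]$, because the fitted weighted GLM nests the
  local intercept-only model and $\bar y_j$ is that null model's exact
  weighted MLE under a canonical link.

### Adjusted variants are descriptive only

The degree-of-freedom-adjusted values
$\bar R^2_j = 1 - \frac{RD_j/(\hat n_j - (d+1))}{D_j/(\hat n_j - 1)}$ and
$\bar R^2 = 1 - \frac{RWD/(n - k(d+1))}{WD/(n - k)}$ are computed and
reported, but flagged `descriptive_only` and accompanied by a warning in
`adjusted_r2()`.  The reason is structural, not cosmetic: refitting with
a different covariate set or a different $k$ changes the soft partition,
hence $WD$ — the benchmark denominator itself moves.  Comparing adjusted
values across models is therefore meaningless, and the package never uses
them for selection; BIC and ICL (reported by `glance()`) are the
selection tools.

### Undefined ratios

If $TD = 0$ (a constant response) the normalized shares are undefined and
returned as `NA` with `flags$td_zero` set; likewise $R^2_j$ when
$D_j = 0$.  Nothing is silently coerced to 0 or 1.  A Poisson or binomial
cluster whose soft mean sits on the domain boundary (all-zero cluster)
raises an error naming the cluster.

## Initialization strategies

`initial_partition()` implements the strategies compared in the Monte
Carlo study: `true_labels` (simulation benchmarking), `true_dgp_map`
(MAP under the generating parameters), `short_em` (best of `S` random
restarts run for `H = 5` iterations each), `kmeans` (best of 10 starts by
within-cluster sum of squares), `pam` (k-medoids, Euclidean), and
`gmm_full` (unconstrained "VVV" Gaussian mixture via **mclust**, with its
default agglomerative hierarchical seeding — the reference
implementation of that strategy, which we prefer over re-seeding it with
k-means).  The joint clustering space for the partitional strategies is
the raw, unstandardized $(X, y)$ matrix.  Random short-EM starts are
i.i.d. uniform multinomial hard assignments, resampled if a class falls
below the viability threshold.  Every strategy is deterministic given
`(data, seed)`; a partition with an empty cluster is retried once with a
shifted seed and then fails loudly.

## The synthetic-data generator

`simulation_condition()` encodes a $2^3$ benchmark design for each family
— class separation (small/large) × regression fit (poor/good) × sample
size (100/1000) — as a balanced two-component mixture on a single
standard-normal covariate, with fixed coefficient tables per family
(Gaussian components additionally differ in variance, $\sigma_1 >
\sigma_2$; binomial uses $m = 10$ trials).  These defaults *are* the
study conditions: they are not tuning knobs, and `run_condition()`
reproduces the corresponding summary tables (means and standard
deviations of ARI, NBD, local/overall R², deviance weights over 250
replicates, true-label initialization, per-replicate seeds
`base_seed + r`).

What the generator deliberately does not emulate: covariate-dependent
mixing weights, more than one covariate, unbalanced or tiny components,
overdispersion/zero inflation in the count families, or offsets.
Passing the Monte Carlo checks therefore demonstrates correctness of the
estimator and the measures under a well-specified mixture, not
robustness to misspecification on real data.

Per-cluster metrics are reported after aligning estimated components to
the reference labels with the agreement-maximizing permutation
(exhaustive for $k \le 6$, greedy beyond — no replicate in the shipped
harness exceeds $k = 2$).  In the initialization comparison
(`run_init_comparison()`) the same replicate data are reused across
strategies, so differences are paired rather than confounded with
sampling noise.

## Numerical choices

* EM convergence: relative change of the observed-data log-likelihood
  below `tol = 1e-8`, at most 500 iterations; non-convergence returns the
  last iterate with `converged = FALSE`.
* Inner IRLS: `glm.fit` with `epsilon = 1e-10`, at most 100 iterations
  (with its built-in step-halving); Gaussian components use exact
  weighted least squares.  Solutions satisfy the weighted score equations
  to $10^{-8}$ relative.
* Gaussian variance floor `1e-10`, flagged when hit, to keep degenerate
  spikes from collapsing the likelihood.
* A component whose soft size drops below $d + 2$ aborts the fit with a
  degenerate-component error naming the component, rather than limping on
  with an unidentifiable piece.
* MAP ties break toward the lowest component index — reproducibility over
  randomization.
* ICL is computed as $BIC + 2\,\mathrm{ent}(\hat z)$ with entropy
  $-\sum_{ij} \hat z_{ij} \ln \hat z_{ij}$ ($0 \ln 0 = 0$), so a hard
  partition gives $ICL = BIC$.
* Offsets (log exposure) are accepted for the Poisson family only — the
  rate-model use case — and rejected elsewhere instead of being silently
  ignored.  With an offset, the local null keeps the mean-based
  definition $\bar y_j$ by default; an offset-aware null (weighted
  intercept-only GLM including the offset) is available behind
  `offset_null = TRUE` for users who want the null on the rate scale.
* Coefficient standard errors in `tidy()` come from the per-component
  observed weighted Fisher information at convergence; they ignore
  membership uncertainty and are labelled approximate.

## Problem sizes

The shipped checks use the design's own sizes: 250 Monte Carlo replicates
per condition ($n$ = 100 or 1000), 50 replicates for parameter recovery,
and batches of ~100 small random fits for the algebraic-identity and
oracle-equivalence properties.  A full run of the test suite and the
reproduction script completes in a few minutes on a single core.

## Known limitations

Only canonical links and the three shipped families; no
quasi-likelihood, gamma or inverse-Gaussian members (the family object is
the extension point).  No stochastic or classification EM (hard 0/1
memberships can be supplied and frozen via `m_step()`, which reproduces
independent per-subset fits).  Mixing weights are covariate-free.
Standard errors do not propagate partition uncertainty.  The adjusted R²
values, by design, refuse to be model-selection tools.
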
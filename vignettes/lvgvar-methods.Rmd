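---
title: "Latent-variable graphical VAR models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent-variable graphical VAR models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvgvar)
```

## The model

lvgvar estimates networks between *latent* variables from two very
different designs: intensive time series of a single subject, and panel
data in which many subjects are measured on a few (at least three) waves.
Both combine a linear factor measurement model

$$y_t = \tau + \Lambda\,\eta_t + \varepsilon_t$$

with a lag-1 graphical vector autoregression (GVAR) between the latent
variables,

$$\eta_t = B\,\eta_{t-1} + \zeta_t, \qquad
  \Sigma^{(\zeta)} = \Delta (I - \Omega)^{-1} \Delta .$$

The matrix $B$ is the **temporal network** (entry $b_{ij}$: the effect of
variable $j$ at the previous occasion on variable $i$ now). The innovation
covariance is parameterized as a Gaussian graphical model (GGM): $\Omega$
holds partial correlations — the **contemporaneous network** — and
$\Delta$ is a diagonal scaling on the standard-deviation scale. This
parameterization is equivalent to inverting the covariance, standardizing,
and flipping the sign of the off-diagonal, but it lets single edges be
fixed to zero while the scale stays free. For panel data a third GGM, the
**between-subjects network** $\Omega^{(\eta)}_{between}$, models the
covariance of the stable subject means, and the measurement model
(loadings and intercepts) is constrained equal across the within- and
between-subject levels: without that invariance it is doubtful the same
construct is measured at both levels.

Stationarity does the heavy lifting. The stationary latent covariance
solves the discrete Lyapunov equation
$\mathrm{vec}(\Sigma_0) = (I \otimes I - B \otimes B)^{-1}
\mathrm{vec}(\Sigma^{(\zeta)})$, lag-$k$ covariances follow the recursion
$\Sigma_k = B\,\Sigma_{k-1}$, and every observed moment block derives from
these plus the measurement model.

### Estimation device: (block-)Toeplitz moment structures

For a single subject the data are augmented: each occasion contributes a
row holding the previous occasion's values next to the current values,
with missing lead values at the first occasion of every block (e.g. a
day), so overnight pairs never enter. The covariance of this paired vector
is a $2 \times 2$-block Toeplitz matrix whose lead block would equal the
lag-0 block under the model. Because the augmentation duplicates data,
that lead block (and its mean) is kept **saturated with its own
parameters**; otherwise the degrees of freedom would be wrong. The model
is then estimated with full-information maximum likelihood (FIML) over
missingness-pattern groups. Two caveats are inherited from this device:
the Toeplitz likelihood is not the exact joint likelihood of the series
(the exact single-observation likelihood is out of scope here), and model
fit does not check stationarity itself.

For panel data the stacked vector holds all indicators at wave 1, wave 2,
… and its covariance is block Toeplitz: block $(s, t)$ equals the
between-subject covariance $\Lambda \Sigma^{(\eta)}_{b} \Lambda^\top +
\Theta_b$ plus the within lag-$|s-t|$ covariance (plus within residual
variances when $s = t$). Indicators absent at a wave are cut from the
stacked mean and covariance.

The sample covariance uses divisor $n$ and the chi-square multiplier is
$n$ (not $n-1$); with these conventions the RMSEA back-calculations from
published fits reproduce exactly. For the time-series setting $n$ is the
number of rows of the augmented matrix.

## Parameters, identification, defaults

* Identification (default `loadings`): the first loading of every factor
  is fixed to its pattern value and the latent scalings $\Delta$ are free;
  alternatively (`scaling`) all loadings are free and the scalings are
  fixed to one. Latent means are fixed to zero in both settings (the
  intercepts absorb the panel stationary means; they are not separately
  identified).
* Residual variances (default `chol`) are parameterized on the
  standard-deviation scale and squared, so they cannot go negative; a
  direct variance parameterization (positive via log) is available.
  Residuals are uncorrelated by default (variances only, no residual
  covariances). A between-level residual that hits the zero boundary can
  be fixed to zero and the model refit (`fix_between_residual`),
  mirroring standard practice.
* Temporal coefficients are displayed on their raw regression scale or
  standardized to partial directed correlations. Several PDC conventions
  circulate; this package uses
  $\mathrm{PDC}_{ij} = b_{ij} / \sqrt{\sigma_{ii}\,\kappa_{jj} + b_{ij}^2}$
  with $\sigma$ the innovation covariance and $\kappa$ its inverse (after
  Wild et al.'s standardization of VAR coefficients): it is bounded in
  $(-1, 1)$, preserves signs and zeros of $B$, and is monotone in
  $|b_{ij}|$ at fixed innovation structure. Only the display changes;
  estimation and search operate on $B$ itself.
* Optimization runs on an unconstrained scale: partial correlations
  through $\tanh$, scalings and Cholesky diagonals through $\log$,
  loadings, intercepts and temporal coefficients untransformed. A BFGS
  quasi-Newton minimizes the fit value to a relative tolerance of 1e-9;
  stationarity (spectral radius below $1 - 10^{-6}$) and positive
  definiteness are enforced by penalty, and positive-definiteness checks
  use a Cholesky factorization with relative pivot tolerance 1e-10.
  Failures surface as typed conditions or as `converged = FALSE` fits —
  never silently.
* Starting values: free loadings 1, empty networks, $B = 0.1 I$,
  intercepts and the saturated lead block from the (EM) saturated moments,
  scalings and residuals from an even split of the observed variances.
  Warm starts reuse a previous solution; if a structural change makes the
  warm start infeasible the fit falls back to the default start.
* Gradients are computed analytically in $(\mu, \Sigma)$ space and chained
  through a Jacobian of the structure map; that Jacobian uses closed forms
  for intercepts, saturated-block Cholesky entries and residual
  deviations, and finite differences (step $10^{-6}$, forward differences
  inside the optimizer) for parameters that enter nonlinearly. Standard
  errors and modification indices come from the expected (Fisher)
  information, as in mainstream SEM practice.

## Fit assessment

$\chi^2 = n(\hat F_{model} - \hat F_{saturated})$, with the saturated
value from the sample moments (complete data) or an
expectation-maximization fit of the unstructured moments (missing data).
RMSEA is $\sqrt{\max(0, \chi^2 - df) / (df\,n)}$ with its interval from
noncentral chi-square root finding at the 5% and 95% quantiles.
Incremental indices (NFI, PNFI, TLI/NNFI, RFI, IFI, RNI, CFI) use an
independence baseline with free means and variances and zero covariances —
published analyses rarely state their baseline, so these indices are
reported for guidance and not treated as reproduction targets; only the
$\chi^2$/df/RMSEA arithmetic is. AIC ($-2\ln L + 2k$) and BIC
($-2\ln L + k \ln n$, with $n$ the number of cases — augmented rows in
the time-series setting) include the full normal constant; comparisons
are unaffected by it.

## Model search

The staged pipeline mirrors common practice: (1) fit the fully connected
model; (2) fix to zero all network edges not significant at $\alpha$
(optionally Bonferroni, Holm or Benjamini–Hochberg adjusted — the family
is one network matrix, so temporal, contemporaneous and between edges are
adjusted separately, mirroring how the networks are reported) and refit;
(3) either stop (`prune`), add edges step-up by the strongest significant
modification index while BIC improves (`stepup`), or run the full
`modelsearch`: per iteration, candidates are all additions with
significant modification indices and all removals of non-significant free
edges; each candidate is refit and the single change with the largest BIC
improvement is accepted until no candidate improves BIC. Previously
pruned edges re-enter the candidate set (the neighborhood is symmetric).
Ties prefer removal over addition, then lexicographic parameter order.

Two numerical choices keep the search affordable without changing its
decisions in practice: candidates are evaluated in order of their
score-test-predicted BIC change and evaluation stops once no remaining
candidate's prediction (with a factor-2 safety margin) can beat the best
measured improvement; and candidate refits use a slightly looser
convergence tolerance (1e-8) than final fits. Modification indices are
full score tests — squared objective gradient over the effective curvature
with the free parameters partialed out.

## Case-drop bootstrap

Structure stability is assessed by re-running the entire pipeline
(including pruning) on subsamples with a fixed proportion (default 25%)
of cases removed: a uniformly chosen subject subset for panel data, and a
contiguous block of occasions for time series, preserving temporal
dependence. The dropped block starts at a random occasion and wraps
around the series end by default (the non-wrapping truncation is
available); wrapping keeps the dropped count exact. Replicate seeds are
derived deterministically from the master seed, so summaries are exactly
reproducible; failed replicates are counted, never imputed. Reported are
signed per-edge inclusion counts and a co-inclusion matrix (so mutually
exclusive edges — each included, never together — are visible).

## Synthetic data and the simulation harness

`simulate_ts()` draws the latent series from the stationary distribution,
runs the VAR recursion with GGM-structured innovations (default burn-in
100 occasions), and passes it through the measurement model with
independent residuals. `simulate_panel()` draws subject means from the
between-level model, the first wave of within deviations exactly from the
stationary distribution (no burn-in needed), and subsequent waves from
the recursion. Simulated data are complete; real experience-sampling data
additionally feature missingness, floor effects, and discreteness of
rating scales, none of which the generator emulates — passing tests
therefore support the estimation machinery, not robustness to those
features.

The bundled generating models match the dimensions of the two empirical
settings the package is aimed at: a 5-factor / 14-indicator time-series
model and a 6-factor / 22-indicator / 3-wave panel model. Their network
entries hold published point estimates where available; quantities never
printed (loadings, scalings, residual variances, intercepts) are fixed
documented stand-ins (loadings cycling 1/0.9/0.8/0.85/0.75, residual
variances 0.4 within the ts model and 0.25 at both panel levels, within
scalings 0.5 and between scalings 0.6 in the panel model, intercepts 4 as
a 7-point-scale stand-in). These values are part of the package and are
not tuned.

`run_study()` crosses sample sizes with estimator variants (3 strategies
× 4 adjustments × 2 α levels = 24), shares each dataset's saturated fit
and a refit cache across variants, reports mean sensitivity, specificity
and weight correlation over successful replicates plus the success rate,
and caches per-cell results so interrupted studies resume.

## Problem sizes used in the test suite

The suite exercises full-scale arithmetic (e.g. the 66-variable panel
moment structure and its 2118 degrees of freedom, and one saturated fit
of that model to moments at n = 2998) but scales Monte-Carlo components
to what a routine check needs: chi-square calibration uses 150 replicates
of a 1-factor / 3-indicator series at n = 5000; the 24-variant
conservativeness sweep uses 4 replicates of the bundled time-series model
at n = 50 and 2 replicates of the bundled panel model at n = 500 (the
per-dataset sweep shares one saturated fit and one refit cache across all
24 variants); the sensitivity-growth check uses a 2-variable observed
GVAR over n ∈ {75, 250, 800} with 6 replicates per cell. These sizes are
the package's own choices for a default run; the harness scales to larger
studies unchanged.

## Known limitations

* Lag-1 dynamics only; higher lags appear only as derived quantities.
* Contemporaneous structure is undirected (GGM); structural/directed
  contemporaneous models are out of scope.
* The ts likelihood is the Toeplitz approximation discussed above.
* No regularized estimation, no random effects on network parameters, no
  multi-group or measurement-invariance testing.
* Normality is assumed throughout; bootstrap stability checks are the
  recommended complement on real data.
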
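# lvgvar

Psychological constructs such as mood states, symptoms or attitudes are
measured with error, through multiple indicators. Networks estimated
directly between observed items therefore conflate measurement noise with
the dynamics of interest, and cross-sectional networks cannot separate
within-person from between-person structure. **lvgvar** estimates
graphical vector-autoregression models *between latent variables* — from
intensive time series of a single subject (*ts-lvgvar*) or from panel
data with at least three waves (*panel-lvgvar*) — for methodologists and
applied researchers in network psychometrics and dynamic SEM.

## The model

A linear factor model links indicators to latent variables,

    y_t = tau + Lambda eta_t + eps_t,

and the latent variables follow a lag-1 graphical VAR,

    eta_t = B eta_{t-1} + zeta_t,     Sigma_zeta = Delta (I - Omega)^-1 Delta,

giving a **temporal network** `B` (lagged, directed effects) and a
**contemporaneous network** `Omega` (partial correlations between
same-occasion innovations). Panel models add a **between-subjects
network** on the covariance of stable subject means, with the measurement
model invariant across levels. Estimation is (FI)ML on a lag-1 Toeplitz
moment structure (single subject; paired-occasion augmented data with a
saturated lead block so degrees of freedom stay honest) or a
block-Toeplitz structure over waves (panel; within/between variance
decomposition). On top of the estimator sit chi-square fit assessment
with RMSEA and incremental indices, significance pruning with
Bonferroni/Holm/FDR adjustments, modification-index step-up search, a
BIC-optimizing stepwise model search, a case-drop bootstrap for structure
stability, and generative simulators for both settings.

## Worked example

Simulate a morning-to-evening style experience-sampling series from the
bundled 5-factor / 14-indicator generating model (400 occasions in 40
daily blocks; pairs never cross a block boundary), then run the standard
pipeline — saturated fit, pruning at alpha = 0.01, BIC model search:

```r
library(lvgvar)

gen <- bundled_ts_model()
dat <- simulate_ts(gen, 400, seed = 42, n_blocks = 40)
fit <- search_pipeline(saturate_networks(gen), dat, alpha = 0.01,
                       adjustment = "none", strategy = "modelsearch")
print(fit)
#> lvgvar model fit (ts_lvgvar_spec, fiml)
#>   free parameters: 170   df: 264   n: 400
#>   chi-square(264) = 269.07, p = 0.402
#>   RMSEA = 0.007 (0.000 - 0.021)   CFI = 0.999   TLI = 0.999
#>   AIC = 29027.71   BIC = 29706.26
```

The model is not rejected (chi-square close to its degrees of freedom,
RMSEA 0.007), as it should be on data simulated from the fitted
structure. The estimated networks recover the generating ones:

```r
round(fit$spec$beta$value, 2)        # temporal network (rows = target)
#>      F1   F2   F3  F4   F5
#> F1 0.34 0.00 0.00 0.0 0.00
#> F2 0.00 0.45 0.00 0.0 0.00
#> F3 0.00 0.00 0.27 0.0 0.00
#> F4 0.00 0.00 0.00 0.3 0.00
#> F5 0.00 0.00 0.00 0.0 0.23

round(fit$spec$omega_zeta$value, 2)  # contemporaneous partial correlations
#>       F1    F2    F3    F4    F5
#> F1  0.00 -0.41 -0.55 -0.36 -0.27
#> F2 -0.41  0.00  0.00  0.00  0.00
#> F3 -0.55  0.00  0.00  0.00  0.00
#> F4 -0.36  0.00  0.00  0.00  0.00
#> F5 -0.27  0.00  0.00  0.00  0.00
```

Every factor keeps its autoregression (inertia), and the contemporaneous
network recovers the star structure in which high F1 (positive
activation) relates negatively to the four other factors. Temporal
standardization to partial directed correlations
(`standardize_temporal()`), stability bootstraps (`bootstrap_search()`),
panel models from wide CSVs or deposited summary moments
(`read_panel()`, `read_moments()`), and full simulation studies
(`run_study()`) follow the same pattern; a command-line wrapper lives at
`system.file("cli", "lvgvar.R", package = "lvgvar")` with subcommands
`fit-ts`, `fit-panel`, `search`, `bootstrap`, `simulate` and `study`.

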
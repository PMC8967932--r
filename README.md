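# dlmm: one-shot distributed linear mixed models from aggregated data

Multi-site clinical studies routinely need a linear mixed model (LMM) —
common fixed effects with site-level random deviations — but privacy rules
keep the individual patient data (IPD) inside each site. `dlmm` fits the
LMM **without pooling any records**: every site shares, once, four
aggregated objects

- the cross-product matrix `S^X = X'X` (p × p),
- the cross-product vector `S^Xy = X'y` (length p),
- the outcome sum of squares `s^y = y'y`, and
- the sample size `n`,

and the coordinator reconstructs the *exact* pooled maximum-likelihood /
restricted maximum-likelihood objective from them. The fit is **lossless**:
estimates, standard errors, likelihood values, variance-component tests and
per-site predictions are numerically identical to the analysis that stacks
all records.

## The model and the reconstruction

For patient *j* at site *i* (*i* = 1, …, K):

    y_ij = x_ij' β + z_ij' u_i + ε_ij,    u_i ~ N(0, V),  ε_ij ~ N(0, σ²),

with `V = diag(σ₁², …, σ_q²)` and the random-effect covariates `z` a subset
of the fixed-effect covariates `x` (possibly only the constant 1, a random
intercept). Writing `Θ = V/σ²` and `Γ_i = Z_i Θ Z_i' + I`, the profiled
objective needs only `X_i'Γ_i⁻¹X_i`, `X_i'Γ_i⁻¹y_i`, `y_i'Γ_i⁻¹y_i` and
`log|Γ_i|`. The Woodbury identity and the matrix determinant lemma turn
each of these into an expression in the shared aggregates alone:

    A'Γ⁻¹B = A'B − (A'Z) Θ(I_q + Z'Z Θ)⁻¹ (Z'B),
    |Γ_i|  = |I_q + Z_i'Z_i Θ|,

where `Z'Z`, `A'Z`, `Z'B` are sub-blocks of `S^X` and `S^Xy`. Everything
downstream — profiled `β̃(Θ)` and `σ̃²(Θ)`, the ML/REML profile
likelihood, model-based and cluster-robust (sandwich) covariances of `β̂`,
the boundary likelihood-ratio test for each variance component (null:
`½χ²₀ + ½χ²₁`), forward selection of random effects, and the per-site
BLUPs `û_i = Θ̂ Z_i'Γ_i⁻¹(y_i − X_iβ̂)` with conditional and
prediction covariances — is assembled from the same four objects.

## Worked example

```r
library(dlmm)

# a 6-site consortium with a random intercept and a random x1 slope
sim <- simulate_sites(n_sites = 6, n_per_site = 40,
                      beta = c(1, 0.5, -0.3),
                      re_columns = c(1, 2), re_variances = c(0.5, 0.25),
                      sigma2 = 1, seed = 42)

# each site reduces its records to shareable aggregates...
ads <- aggregate_sites(sim$data)

# ...and the coordinator fits the model from the aggregates alone
fit <- dlmm(ads, re = c("(Intercept)", "x1"), method = "reml")
fit
#> Distributed linear mixed model fit (REML, joint variant)
#>   sites: 6  observations: 240
#>   log-likelihood: -368.51682
#>
#> Fixed effects:
#> (Intercept)          x1          x2
#>     1.03300     0.62121    -0.26682
#>
#> Random-effect variances (diagonal V):
#> (Intercept)          x1
#>     0.29444     0.24877
#>
#> Residual variance: 1.1063
```

The fixed-effect table reads: site-average outcome 1.03 at covariate zero,
a +0.62 common slope in `x1`, and −0.27 in `x2`; the slopes vary across
sites with variances 0.29 (intercept) and 0.25 (`x1` slope) around those
common values. The lossless property is directly checkable against the
pooled-records reference implementation:

```r
pooled <- fit_pooled(sim$data, re = c("(Intercept)", "x1"))
max(abs(fit$beta - pooled$beta))          # 1.1e-15
fit$loglik - pooled$loglik                # 0
```

Inference, selection and prediction all run off the same aggregates:

```r
tidy(fit)                                   # Wald table, model-based SEs
tidy(fit, estimator = "sandwich")           # cluster-robust SEs
forward_select(ads, c("x1", "x2"))          # boundary-LRT selection
tidy(dlmm_blup(fit))                        # per-site effects + 95% PIs
autoplot(fit)                               # forest plot
```

Before sharing aggregates, a site can audit them for sparse inferable
cells (`privacy_audit(ad, binary_columns = ...)`); counts of 0/1
characteristics below 5 are flagged. A command-line interface covering
simulate → aggregate → fit → select → blup ships in `inst/cli/dlmm`.

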
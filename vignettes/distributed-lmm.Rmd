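---
title: "Distributed linear mixed models from one-shot aggregated data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed linear mixed models from one-shot aggregated data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlmm)
```

## The problem

A consortium of $K$ sites (hospitals, registries, claims databases) wants a
linear mixed model for a continuous outcome, but individual patient data
(IPD) cannot leave any site. Classical federated approaches iterate:
gradients or summary updates travel back and forth until convergence. This
package implements a *one-shot* alternative: each site communicates, once,
the cross-products $S^X_i = X_i'X_i$, $S^{Xy}_i = X_i'y_i$, the outcome sum
of squares $s^y_i = y_i'y_i$, and $n_i$ — and the coordinator reproduces the
pooled analysis exactly.

## Model

$$y_{ij} = x_{ij}'\beta + z_{ij}'u_i + \epsilon_{ij}, \qquad
u_i \sim N(0, V), \quad \epsilon_{ij} \sim N(0, \sigma^2),$$

for patient $j = 1,\dots,n_i$ at site $i = 1,\dots,K$. The random-effect
covariates $z_{ij}$ are a subset of $x_{ij}$ (the intercept column gives a
random intercept), and the components of $u_i$ are assumed independent:
$V = \mathrm{diag}(\sigma_1^2,\dots,\sigma_q^2)$. This diagonal structure
is what makes the boundary likelihood-ratio machinery tractable (the null
distribution for an unstructured $V$ depends on $V$ itself and is out of
scope here). That $z \subseteq x$ is a *structural requirement*, not a
convenience: it is exactly what makes $Z_i'Z_i$, $X_i'Z_i$ and $Z_i'y_i$
sub-blocks of the shared aggregates.

## Exact reconstruction of the profile likelihood

Let $\Theta = V/\sigma^2$ and $\Gamma_i(\Theta) = Z_i\Theta Z_i' + I_{n_i}$.
Profiling $\beta$ and $\sigma^2$ out of the Gaussian likelihood leaves

$$\tilde\beta(\Theta) = \Big(\sum_i X_i'\Gamma_i^{-1}X_i\Big)^{-1}
  \sum_i X_i'\Gamma_i^{-1}y_i, \qquad
  \tilde\sigma^2(\Theta) = \frac{1}{c}\sum_i
  (y_i - X_i\tilde\beta)'\Gamma_i^{-1}(y_i - X_i\tilde\beta),$$

with $c = N$ (ML) or $N - p$ (REML; see below), and the profile
log-likelihood
$L_p(\Theta) = -\tfrac12\{N\log 2\pi + c\log\tilde\sigma^2 +
\sum_i \log|\Gamma_i|\} - \tfrac{c}{2}$, where we use the identity that the
profiled quadratic form equals $c\,\tilde\sigma^2$. Every term involving
$\Gamma_i^{-1}$ is an $n_i \times n_i$ object in disguise only: by the
Woodbury identity and the matrix determinant lemma,

$$A'\Gamma_i^{-1}B = A'B - (A'Z_i)\,M_i\,(Z_i'B), \qquad
  |\Gamma_i| = |I_q + Z_i'Z_i\Theta|,$$

for any $A, B$ among $\{X_i, Z_i, y_i\}$. The textbook form of the middle
factor, $M_i = (\Theta^{-1} + Z_i'Z_i)^{-1}$, is undefined when a
component of $\Theta$ is zero — which is routine here, because boundary
values arise under the likelihood-ratio test. We therefore evaluate the
algebraically identical push-through form

$$M_i = \Theta^{1/2}\big(I_q + \Theta^{1/2} Z_i'Z_i\,
  \Theta^{1/2}\big)^{-1}\Theta^{1/2},$$

which is symmetric, positive semi-definite, and exact at $\theta_k = 0$.
All $q \times q$ and $p \times p$ solves use Cholesky factorizations; no
$n_i \times n_i$ matrix is ever formed on the aggregated-data path.

## Two restricted-likelihood conventions

The restricted profile likelihood is implemented in two variants:

* `reml_variant = "joint"` (default): subtracts
  $\tfrac12\log\big|\sum_i X_i'\Gamma_i^{-1}X_i\big|$ and divides the
  profiled quadratic form by $N - p$. This is the convention of standard
  mixed-model software, and it is what an independent pooled REML fit
  (e.g. `lme4::lmer`) computes — agreement with such a fit is part of the
  test suite.
* `reml_variant = "per_site"`: evaluates the literal per-site form
  $L_p - \tfrac12\sum_i\{\log|X_i'\Gamma_i^{-1}X_i| -
  n_i\log\tilde\sigma^2\}$ with divisor $N$. Note the added
  $+\tfrac12 N \log\tilde\sigma^2$ cancels the $\log\tilde\sigma^2$ term of
  $L_p$, so this objective weights the variance quite differently; it is
  provided for comparability with analyses that define REML this way, and
  both variants remain exactly reconstructible from the aggregates.

The divisor and determinant choices matter only for REML; ML is unique.

## Optimization over the variance ratios

The objective is maximized over $\theta \ge 0$ (elementwise) by L-BFGS-B on
$\eta = \log(\theta + 10^{-10})$, default start $\theta = 0.1\cdot 1_q$,
with restarts from $\{0.01, 1, 10\}\cdot 1_q$ taken only when a start fails
to converge. The gradient is analytic, via the envelope theorem: with
$s_{ik} = (Z_i'\Gamma_i^{-1}r_i)_k$ and $r_i = y_i - X_i\tilde\beta$,

$$\frac{\partial L}{\partial\theta_k} = -\frac12\Big\{
  -\frac{c\sum_i s_{ik}^2}{\mathrm{RSS}}
  + \sum_i (Z_i'\Gamma_i^{-1}Z_i)_{kk}
  - \sum_i g_{ik}'\Big(\sum_j X_j'\Gamma_j^{-1}X_j\Big)^{-1} g_{ik}
  \Big\},$$

the last term for joint REML only, $g_{ik}$ the $k$-th row of
$Z_i'\Gamma_i^{-1}X_i$.

Boundary handling needs care: on the $\eta$ scale the parameterization
flattens near $\theta = 0$ ($d\theta/d\eta \to 0$), so quasi-Newton
iterates can stall at small positive values that belong on the boundary —
or, conversely, at zero when a small interior optimum exists. After the
quasi-Newton stage the fitter therefore adjudicates every component below
$10^{-4}$ by the first-order condition at $\theta_k = 0$: if the objective
increases into the interior the component is set to exactly zero,
otherwise a bounded Brent search relocates the interior optimum. Surviving
components are polished by cyclic Brent sweeps alternating with a
quasi-Newton restart (coordinate sweeps alone can stall off the joint
optimum when $q > 2$). Components below $10^{-8}$ are reported as exactly
zero, and a final damped Newton step roots the analytic gradient itself:
objective-difference searches bottom out at an argument error of order
$\sqrt{\text{noise}/\text{curvature}}$, which is visibly imprecise when
the likelihood is flat (few sites), whereas the gradient root is
conditioned as noise/curvature. This pipeline is what makes the lossless
comparisons tight at machine precision and the likelihood-ratio
statistic's point mass at zero numerically clean: in side-by-side runs the zero/non-zero
classification of every replicate matches an independent mixed-model
fitter.

For $q \in \{1, 2\}$ the per-site $q\times q$ inversions have closed forms
that vectorize across sites; the generic Cholesky path handles larger $q$.
Both paths are verified against dense $\Gamma_i^{-1}$ linear algebra.

## Inference

The covariance of $\hat\beta$ is either the model-based
$\hat\sigma^2(\sum_i X_i'\Gamma_i^{-1}X_i)^{-1}$ or the cluster-robust
sandwich with per-site score outer products; both are assembled from the
aggregates. Wald intervals use the conventional $\pm 1.96$ multiplier
exactly.

Testing $H_0: \sigma_k^2 = 0$ places the parameter on the boundary, so the
likelihood-ratio statistic follows the 50:50 mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$ under $H_0$ (random intercept
retained throughout). The p-value is 1 at $LR = 0$ and
$\tfrac12 P(\chi^2_1 \ge LR)$ otherwise. The test uses ML likelihoods by
default — the hypotheses share the fixed-effect structure and the statistic
is defined through the full likelihood — with REML available behind an
explicit argument. Forward selection starts from the random intercept,
admits the smallest mixture p-value below `alpha` at each step (ties break
on larger LR, then lower column index), and applies no multiplicity
correction; the trace reports every test so users can adjust. The mixture
is an asymptotic ($K \to \infty$) result: at moderate $K$ the finite-sample
mass at zero sits slightly above one half because the score statistic is a
right-skewed sum over sites, a deviation that shrinks as sites are added
and that the package's calibration simulations make visible rather than
hide.

## Prediction

The per-site BLUP $\hat u_i = \hat\Theta Z_i'\Gamma_i^{-1}
(y_i - X_i\hat\beta)$ is reported with two covariances: the variance of
the predictor, $\mathrm{Var}(\hat u_i \mid X_i)$, and the prediction-error
covariance $\mathrm{Var}(\hat u_i - u_i) = \hat V -
\mathrm{Var}(\hat u_i \mid X_i)$. Intervals use the latter — the target is
the realised $u_i$, not the estimator — which is also why they are labelled
prediction intervals. In the one-way model the BLUP is the classical
shrinkage $\tfrac{n_i\hat\theta}{1 + n_i\hat\theta}\,\bar r_i$ of the site
mean residual; shrinkage strengthens with $n_i$, and a component with
$\hat V_k = 0$ yields zero predictions and zero covariance rows. Site
effects are reported as fixed effect plus BLUP for the random-effect
columns only. BLUPs identify sites by construction: the command-line
interface refuses to write them without an explicit `--report-blups`
acknowledgement.

## The synthetic-data generator

`simulate_sites()` draws directly from the model above: covariates are
standard normal (or Bernoulli for tagged binary columns), random effects
are independent across components and sites, errors are homoscedastic
Gaussian. One global seed streams a sub-seed per site, so enlarging the
consortium leaves earlier sites' draws untouched. The generator emulates
exactly the assumptions the estimator makes — what it deliberately does
*not* emulate is real multi-site messiness: missing data, non-Gaussian or
heteroscedastic errors, covariate-distribution shift across sites,
correlated random effects, or nested/longitudinal structure. Passing tests
therefore certify the *algebra and algorithms* (lossless reconstruction,
calibration under the stated model), not robustness to misspecification.

## Verification design

The dense reference implementation (`fit_pooled()`,
`brute_force_blup()`) exists to make the lossless claim falsifiable: it
evaluates every $\Gamma_i$ quantity by explicit $n_i \times n_i$ inversion
on the stacked records and shares none of the Woodbury reconstruction, so
the two routes can only agree if the reconstruction is exact. It shares
the optimizer deliberately, so any discrepancy isolates the likelihood
evaluation rather than the search path. The BLUP oracle conditions the
joint Gaussian of $(u_i, y_i)$ by brute force. Problem sizes in the test
suite (up to $K = 100$ sites, $n_i \le 100$, $p \le 10$, $q \le 4$; 1000
replicates for the null-calibration simulation, 200 for parameter
recovery) were chosen so that Monte-Carlo bands are tight enough to be
informative at desk scale.

## Degenerate and adversarial inputs

Exact-fit data (profiled residual variance zero) raise an explicit
degenerate-data error rather than returning an infinite likelihood.
Rank-deficient pooled designs are reported with the near-collinear columns
named (smallest-eigenvalue heuristic). Aggregates are validated on read:
symmetry to $10^{-10}$, positive semi-definiteness, non-negative implied
residual sum of squares, and a schema check; sites' column sets must agree
and are aligned by name to the first site's order, because silent
positional mismatch is the dominant failure mode of multi-site exchanges.
Tiny negative likelihood-ratio values (optimizer noise) are clamped to
zero, with a warning above $10^{-6}$.

## Privacy posture

The aggregates avoid row-level transfer but are not formally private: for
0/1 columns, marginal and pairwise counts are exactly recoverable from
$S^X$. `privacy_audit()` flags any such inferable count below a threshold
(default 5) so contributors can review before sharing; it is advisory by
design (the CLI's `--strict` mode turns it into a refusal). Counts of
three or more characteristics jointly are not recoverable from $S^X$ and
are outside the audit's reach. No differential-privacy or encryption
guarantees are made.
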
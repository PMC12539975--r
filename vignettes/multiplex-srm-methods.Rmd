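---
title: "Methods: the multiplex social relations model in srmnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the multiplex social relations model in srmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`srmnet` implements a Bayesian social relations model (SRM) for multiplex
directed networks: M layers of ties observed on one common set of N nodes,
stored as an N x N x M array G with G[i, j, m] the flow from sender i to
receiver j in layer m. Each layer may be Bernoulli (binary ties), Binomial
with a per-dyad exposure count E[i, j, m] (e.g. the number of observation
scans in which a tie could have been recorded), Poisson (raw counts), or
Gaussian; all layers of one network must share a family. Self-ties are
undefined: diagonal cells are stored but never modelled.

On the link scale (logit by default for binary/binomial data; probit,
log, and identity are available where compatible), the linear predictor for
an ordered pair is

```
theta[i,j,m] = eta[m] + alpha[i,m] + beta[j,m] + delta[i,j,m]
             + Lambda(i,j,m)
             + focal_slopes[m,] . x_i + target_slopes[m,] . x_j
             + dyad_slopes[m,] . x_ij
```

with `eta` a per-layer intercept, `alpha` and `beta` sender and receiver
random effects, `delta` a dyad-by-direction random effect, and `Lambda` the
sum over block variables of an offset indexed by the (sender block, receiver
block) pair — the assortativity part of the model.

The multiplex structure lives in the random-effect correlations.
Each node's 2M-vector (alpha over layers, then beta over layers) is
multivariate normal with SDs `sigma` and an unconstrained 2M x 2M
correlation matrix `rho` — its entries are the *generalized reciprocity*
parameters, within and between layers. Each unordered dyad {i, j}
contributes a 2M-vector (i-to-j effects over layers, then j-to-i effects)
with SDs tied between the two directions (`tie_dyadic_sigmas`) and a
2M x 2M correlation matrix `varrho` — *dyadic reciprocity*. Because the
labels i and j within a dyad are arbitrary, `varrho` must have the
exchangeable block form `[C B; B C]` with C a correlation matrix and B
symmetric.

Both correlation matrices are parameterized through Cholesky factors in a
non-centred scheme (effects = scale * (factor x iid standard normals)),
which is what makes the posterior geometry tractable for Hamiltonian
sampling. The block form of `varrho` is enforced softly: Normal(0, epsilon)
penalties on the entrywise deviations `varrho[m+M, n+M] - varrho[m, n]` and
`varrho[m, n+M] - varrho[n, m+M]` for all layer pairs m < n. As epsilon
tends to zero the posterior concentrates on exactly block-structured
matrices; the default epsilon = 0.01 keeps the constraint tight (posterior
deviations are typically well below 5 * epsilon) without degrading sampler
adaptation. We interpret the penalized norm of each constrained pair as the
absolute value of a scalar difference, since each constraint binds a single
matrix entry. An alternative exact construction (tracking feasible bounds
within the Cholesky factor) exists in the literature; this package
implements the penalty method only.

## Priors

Defaults, all exposed through `prior_settings()`:

| parameter | prior | default |
|---|---|---|
| sender/receiver SDs `sigma`, dyadic SDs | Exponential(rate) | rate = 2.5 |
| correlation Cholesky factors (both) | LKJ Cholesky(shape) | shape = 2.5 |
| intercepts, slopes, block offsets | Normal(0, sd) | sd = 1 |
| Gaussian residual SD `psi` | Exponential(rate) | rate = 1.0 |
| block-structure penalty scale | Normal(0, epsilon) on deviations | epsilon = 0.01 |

The unit-normal priors on slopes are weakly regularizing, which is why
`build_designs(standardize = TRUE)` (the default) centres and scales numeric
covariates: it puts all slopes on a comparable prior scale. Whether the
penalty's scale parameter acts as an SD or a variance is a genuine
ambiguity in the penalty formulation; this package uses it as the SD of the
deviation, and the constraint-satisfaction tests are calibrated against that
choice. The LKJ prior is applied to the dyadic factor *in addition to* the
structure penalty, so the prior over the constrained space remains proper
and weakly informative.

## Inference

No gradient-based MCMC backend with a custom-density interface is part of
the package's dependency footprint, so `srmnet` ships its own engine: a
multinomial No-U-Turn sampler with dual-averaging step-size adaptation and
windowed diagonal mass-matrix estimation, run on an analytically
differentiated joint log density (`srm_density()` exposes both the value and
the gradient; the test suite verifies the gradient against central finite
differences to below 1e-5 relative error for all four outcome families).
Defaults are 2 chains, 1000 warmup and 1000 sampling iterations, target
acceptance 0.9, and maximum tree depth 10 — conservative settings chosen
because hierarchical SRM posteriors with tens of thousands of latent
effects need careful adaptation. Chains initialize from small uniform
jitter around zero on the unconstrained scale, which keeps the initial
density finite in every outcome family. All randomness derives from the
configuration seed, so identical data + configuration + seed reproduce a
fit bit for bit.

Model size scales as M * N^2 (the dyadic raw effects dominate:
M * N * (N - 1) scalars), so a four-layer network with 250 nodes already
has more than a quarter-million free parameters (`count_free_parameters()`).
Practical fits are best kept below a few hundred nodes.

`check_diagnostics()` reports split-R-hat and effective sample sizes for all
reported (non-random-effect) parameters; per-draw random effects are
retained for posterior network metrics and can be thinned
(`thin_random_effects`) to bound memory.

## Post-processing

* `summarize_fit()` — posterior medians and highest-posterior-density
  intervals (the narrowest interval with the stated mass; default 0.90).
  Block offsets are shown re-centred within each variable and layer because
  the raw offsets are only identified up to a shared shift; contrasts
  (`block_contrast()`) always use raw offsets, where the shift cancels.
* `variance_partition()` — per-draw, per-layer proportions of latent-scale
  variance attributable to focal, target, dyadic, and residual components.
  The residual variance on the link scale is pi^2/3 (logit), 1 (probit), or
  psi^2 (gaussian). For Poisson layers no standard latent residual
  convention exists; partitions are reported on the latent log scale with a
  zero residual term, so Poisson VPCs describe the latent intensity, not
  observed counts. The three-way partition merges dyadic and residual
  components, which is the better-identified summary when dyadic
  reciprocity is weak.
* `adjusted_dyadic_correlation()` — multiplies a latent dyadic correlation
  by `sigma^2 / (sigma^2 + 1)`, mapping it onto the observation-level scale
  that residual-correlation formulations of the SRM estimate (with unit
  noise, an observed-scale analysis understates the latent correlation by
  exactly this factor).
* `reciprocity_matrices()` — entrywise medians/intervals of `rho` or
  `varrho` with "(out)/(in)" and "(i to j)/(j to i)" labelling, flagging
  entries whose interval excludes zero.
* `posterior_network_metric()` — applies any user metric to the latent
  tie-probability (or rate/mean) matrix reconstructed from each retained
  draw, propagating full posterior uncertainty into the metric.

## The simulator and what the tests do (and do not) show

`simulate_multiplex_network()` is a first-class module: it draws the
correlated random effects, assembles the same linear predictor the model
uses, and samples outcomes under the requested family, returning the full
ground truth alongside a validated data object. Self-contained covariate
generators (standard-normal numeric covariates and dyadic matrices, uniform
block memberships) allow fixtures without external data. Means of the
random effects default to zero, matching standard practice. Gaussian
outcomes are supported in the simulator as well, for symmetry with the
model, and simulator slopes are applied to covariates exactly as supplied
(standardization is a fitting-time choice).

The validation harness (`recovery_sweep()`, `prior_norm_baseline()`,
`frobenius_divergence()`) operationalizes recovery as: the posterior
distribution of `Tr((rho_true - rho_draw)' (rho_true - rho_draw))` — the
summed squared entry differences; note this is the *squared* Frobenius norm,
which is the form used throughout — should sit far below the same
divergence computed against 500 draws from the prior. The prior baseline
for the dyadic matrix is sampled from the penalized prior by a short NUTS
run on the prior-only density, since the constrained prior has no
closed-form sampler.

Study conditions used by the packaged checks (chosen once as realistic for
field data of this kind): two layers, moderate reciprocities (within-layer
generalized 0.4, dyadic 0.6; cross-layer 0.15-0.3), random-effect SDs
0.7-0.8, intercepts around -1 to -1.5 on the logit scale, binomial exposure
10. The automated suite runs one constraint-satisfaction fit at N = 40 and
one recovery fit at N = 100 with a reduced draw budget (450 + 450, single
chain), and the recovery sweep defaults to a small smoke grid; the
full-scale protocol (dozens of datasets, N up to ~145, layer counts 2-8,
three-layer dense/dense/sparse designs with full covariate sets) runs
through the same functions with a larger grid and the default sampler
settings. Passing these tests demonstrates that the implementation recovers
its own generative process — it does not by itself validate the model
against measurement processes real data may have (reporting error,
censoring, missing dyads), none of which the generator emulates.

## Numerical choices and limitations

* Positive definiteness of assembled correlation matrices is accepted when
  the smallest eigenvalue exceeds 1e-8, tolerating benign floating-point
  asymmetry.
* Non-finite density or gradient values during leapfrog integration are
  treated as divergent transitions (reported per chain), not errors.
* Poisson rates are clamped at exp(300) inside the likelihood so that
  extreme proposals reject gracefully rather than overflow.
* Categorical covariates use reference coding with the reference level
  chosen as the first level in sorted order (recorded in the design
  object); formulas support additive main effects only.
* Missing values anywhere in outcomes (off-diagonal) or covariates are hard
  errors; imputation is out of scope.
* Undirected or mixed directed/undirected layers, double-sampled
  observation structures, longitudinal extensions, and residual-correlation
  (latent bivariate probit) formulations are out of scope; dyadic effects
  are always parameterized explicitly.
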
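---
title: "A Bayesian spatially varying coefficient index model for areal outlet counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian spatially varying coefficient index model for areal outlet counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcindex)
```

## The model

`svcindex` fits a hierarchical Bayesian regression for counts of K outcome
types (e.g. tobacco-only, alcohol-only, and combined retail outlets)
observed on n areal units such as census block groups. For unit $i$ and
outcome $k$,

$$y_{ik} \sim \text{Poisson}(\theta_{ik} E_{ik}), \qquad
  E_{ik} = r_k\, p_i, \qquad
  \log \theta_{ik} = \alpha_k + \beta_{ik} \sum_{j=1}^{C} w_j q_{ij},$$

where $p_i$ is the unit population, $r_k = \sum_i y_{ik} / \sum_i p_i$ is
the overall per-capita rate (internal standardization, so
$\sum_i E_{ik} = \sum_i y_{ik}$ exactly), and $q_{ij} \in \{1,\dots,10\}$
are decile scores of C sociodemographic variables. The inner sum is a
neighborhood disadvantage index (NDI): a weighted combination of decile
scores whose weights $w_j$ are estimated **inside** the outcome model, so
the data decide each variable's contribution to "disadvantage". The
coefficient $\beta_{ik}$ is unit-specific — the association between
disadvantage and outlet rates is allowed to vary over space
(nonstationarity) — and $\exp(\beta_{ik})$ is the relative risk per one
decile-unit increase of the index.

Priors complete the specification:

* $\alpha_k$: improper flat priors;
* $\beta_{\cdot k}$: a multivariate **intrinsic conditional autoregressive**
  (MVCAR) field across the adjacency graph, coupling the K outcome types
  through a shared $K \times K$ precision $\Omega$. The kernel is the
  pairwise-difference form
  $|\Omega|^{(n-1)/2} \exp\{-\tfrac12 \sum_{i \sim j}
  (\beta_i - \beta_j)^\top \Omega\, (\beta_i - \beta_j)\}$,
  improper under constant column shifts; the exponent $(n-1)$ is the rank of
  the Laplacian of a connected graph (disconnected inputs are rejected at
  load time rather than handled);
* $\Omega \sim \text{Wishart}(R, K)$ in the *rate-matrix* convention
  $f(\Omega) \propto |\Omega|^{(\nu-K-1)/2} e^{-\operatorname{tr}(R\Omega)/2}$
  with $R = 0.2\,I_K$ and $\nu = K$ by default (prior mean $K R^{-1}$).
  The convention matters — base R's `rWishart()` uses the scale-matrix
  convention — and the package translates internally
  (`scale = solve(rate)`);
* $w \sim \text{Dirichlet}(\alpha_1,\dots,\alpha_C)$, default all 1, which
  keeps every $w_j \in (0,1)$ with $\sum_j w_j = 1$ and gives each variable
  a priori equal weight $1/C$.

$\Sigma = \Omega^{-1}$ is the between-outcome covariance of the coefficient
fields; its correlations $\rho_{kl} = \Sigma_{kl} / \sqrt{\Sigma_{kk}\Sigma_{ll}}$
("conditional correlations") measure how similarly two outlet types respond
to disadvantage over space.

## Preprocessing

Covariates are first **oriented** so that larger values always mean greater
disadvantage: per capita income defaults to the inverse orientation
$x \mapsto \max(x) - x$; every other variable is direct. Orientation is
declared per variable in configuration — the package never infers signs
automatically, keeping preprocessing deterministic. Oriented variables are
then **decile-scored** with cutpoints at the empirical quantiles
$0.1, \dots, 0.9$ using the median-unbiased definition (`type = 8` in
`quantile()`); ties share the lowest admissible decile, and a constant
column collapses to decile 1 with a warning. Decile coding puts variables
with different scales on a common 1–10 footing and damps outliers and
survey noise; since only ranks enter the model, the marginal distributions
of the raw covariates are irrelevant downstream.

Units with zero population or missing covariates are dropped before
anything else, and cutpoints are computed on the analysis set (whether to
decile before or after exclusions is a genuine choice; after is used and
documented here). The drop counts are reported and the subgraph must remain
connected.

## The sampler

`run_mcmc()` is a Metropolis-within-Gibbs sampler. Per iteration:

1. **Coefficient field**: single-site Metropolis sweeps (three per
   iteration; compiled in C++) with multivariate Gaussian steps shaped by
   the Cholesky factor of $\Omega^{-1}$, so proposals respect the current
   cross-outcome correlation. Acceptance combines the Poisson likelihood
   change with the MVCAR kernel change over the site's neighbors.
2. **Intercepts**: exact Gibbs — under the flat prior,
   $e^{\alpha_k}\,|\,\cdot \sim
   \Gamma(\sum_i y_{ik},\, \sum_i E_{ik} e^{\beta_{ik}\text{NDI}_i})$.
3. **Precision**: conjugate Wishart draw with degrees of freedom
   $\nu + n - 1$ and rate $R + S$,
   $S = \sum_{i\sim j} (\beta_i-\beta_j)(\beta_i-\beta_j)^\top$.
4. **Weights**: Metropolis on the additive-log-ratio scale
   $z_j = \log(w_j / w_C)$ — component-wise moves, a global shift (the only
   direction that moves the reference weight in one step), antithetic pair
   moves that transfer mass between two variables, and an
   adaptive-covariance move shaped by the estimated posterior covariance of
   $z$. The target includes the Dirichlet prior and the ALR Jacobian
   $\sum_j \log w_j$; proposals reaching $w_j \le 10^{-12}$ are rejected
   outright (open-simplex support). Proposal scales mix mostly local steps
   with occasional 4x jumps so chains can hop between near-equivalent
   allocations of weight among correlated decile columns.

Two further moves address the model's two weakly identified directions,
which ordinary blockwise updates traverse very slowly:

* a **likelihood-preserving weight/field swap**: propose new log-ratios and
  rescale the field as $\beta_{ik}' = \beta_{ik}\,\text{NDI}_i /
  \text{NDI}_i'$, leaving every Poisson mean exactly unchanged; acceptance
  rests on the MVCAR kernel, the Dirichlet prior, and the Jacobian
  $K \sum_i \log(\text{NDI}_i/\text{NDI}_i')$. Without it, a flexible field
  can lock in a wrong weight allocation for the length of a desk-scale run.
* a **likelihood-invariant intercept/field trade**: $\alpha_k + c$ together
  with $\beta_{ik} - c/\text{NDI}_i$ keeps every linear predictor fixed, so
  the move explores the direction in which the intercept is pinned down
  only by the field's smoothness prior.

Identifiability of the field level is handled in the default
`"centered"` mode by a ridge-compensated column-shift move (shift
$\beta_{\cdot k}$ by $c$ and $\alpha_k$ by $-c \cdot \overline{\text{NDI}}$);
the mean slope per outcome is the column mean of the stored field. An
`"unconstrained"` mode omits the shift move for sensitivity analysis — both
modes target the same posterior because the intrinsic kernel is
shift-invariant and the intercept prior flat.

Proposal scales adapt by Robbins–Monro toward 0.44 (scalar moves) or 0.234
(multivariate) during burn-in only and are frozen afterwards, so retained
draws come from a fixed kernel. All randomness flows through R's RNG from
per-chain seeds; identical configurations reproduce draws bit-identically.

Initialization is moment-matched and deterministic:
$\alpha_k = \log(\sum_i y_{ik} / \sum_i E_{ik})$, $\beta = 0$, $w = 1/C$,
$\Omega = K R^{-1}$.

## Diagnostics and summaries

* **Convergence**: classical Gelman–Rubin $\hat R$ with
  $W$ = mean within-chain variance, $B = T \cdot \text{var}$(chain means),
  $\hat V = \frac{T-1}{T} W + \frac{B}{T}$, $\hat R = \sqrt{\hat V / W}$;
  threshold 1.2. Monitored scalars: every $\alpha_k$ and $w_j$, the unique
  elements of $\Omega$, and an evenly spaced (hence reproducible) subsample
  of 100 field entries — monitoring all $nK$ entries at realistic problem
  sizes is wasteful.
* **Effects**: pooled-chain equal-tailed 95% credible intervals of
  $\exp(\beta_{ik})$ (empirical quantiles, linear interpolation; whether
  intervals should be equal-tailed or highest-density is not determined by
  convention alone — equal-tailed is used and documented). A unit is
  flagged *significant* when the lower bound exceeds 1.
* **Correlations**: each stored $\Omega$ draw is inverted and converted to
  correlations; medians and 95% intervals per outcome pair.
* **Weights**: ranked table of raw medians (not renormalized) with
  intervals; **NDI**: per-unit posterior median of
  $\sum_j w_j q_{ij}$, necessarily in $[1, 10]$.
* **Group comparisons**: for each outcome, units split by the significance
  flag and compared — on the posterior-median NDI and on each decile
  column — with Welch's unequal-variance t-test
  (Welch–Satterthwaite df, two-sided p, no multiplicity correction, raw
  p-values reported).

## The synthetic-data generator

No public dataset accompanies the model, so the package generates areal
data with exactly the structure the model assumes, with known truth, and
every downstream stage is exercised against it. `simulation_config()`
defaults describe a realistic operating point:

* a 20x20 rook-contiguity lattice (~400 units) standing in for block-group
  adjacency; queen contiguity available;
* nine right-skewed covariates as exponentiated equicorrelated Gaussians
  (latent correlation 0.3), the last column inverse-oriented to play per
  capita income. Only ranks matter downstream, so the marginal family is a
  free choice; spatial autocorrelation of covariates is deliberately not
  modeled (ranks again);
* unit populations uniform on 500–3000, the block-group range;
* true weights: the estimated profile
  (0.26, 0.18, 0.16, 0.14, 0.12, 0.04, 0.04, 0.03, 0.03) of the motivating
  study reused as a realistic truth;
* true field: mean slopes (0.20, 0.17, 0.15) plus a sum-to-zero MVCAR
  deviation with kernel scale 0.17 and cross-outcome correlations
  $\rho_{12} = 0.9$, $\rho_{13} = \rho_{23} = 0$. On the default lattice the
  marginal field spread is about $0.89 \times 0.17 \approx 0.15$, so the
  strongest unit relative risks per index unit approach 1.8 — the upper end
  of the scale such studies report. The constrained (sum-to-zero) draw is
  used because the intrinsic density is improper, matching the sampler's
  identifiability convention;
* per-capita baseline rates (7.0, 4.6, 4.4) x 1e-4 — a few outlets per
  thousand residents, as in the motivating data.

What passing tests on these data do **not** show: robustness to spatially
autocorrelated covariates, to non-planar adjacency, to overdispersion or
zero inflation beyond the Poisson, or to real-world geocoding noise.

## Validation operating point and problem sizes

Recovery experiments (`recovery_experiment()`) rescale the base rates so
the mean events per unit hit a target (default 10; the validation runs use
40) and, via `strong_signal_config()`, raise the mean slopes to $\log 2$
and the field kernel scale to 0.3. These values follow from a power
argument rather than realism: separating the 0.02 gaps in the target weight
profile requires a weight posterior standard deviation below about 0.02,
and centering the $\rho_{12}$ posterior within a credible halfwidth of the
generating 0.9 requires the field increments to stand well above Poisson
noise. At the realistic defaults the weight ranking and an extreme
correlation are genuinely not resolvable from one desk-scale dataset — the
posterior shrinks toward the Dirichlet and Wishart priors; this is a
property of the model at that information level, not a defect of the
sampler, and is worth remembering when interpreting real-data fits of
comparable size.

Desk-scale MCMC for tests and experiments is 5000 burn-in / 5000 retained
draws on two chains (`mcmc_config_test()`); the full-scale protocol
(50,000 / 10,000, thinning 1, two chains) remains the `mcmc_config()`
default. The test suite also runs a 50-replicate calibration study (8x8
lattice, K = 1, C = 3, truth weights drawn from the prior) checking that
95% weight intervals cover at their nominal rate, and a joint-posterior
oracle on a 4-unit path lattice where sampler means are compared with dense
grid quadrature (intercept integrated analytically) to 0.02. That oracle
instance uses strongly heterogeneous index values and a stiff fixed CAR
precision: the intercept/field trade direction is exactly flat in the
likelihood, and with a loose field prior its posterior spread is several
units, which no quadrature box or finite chain pins down to 0.02.

## Known limitations

* The intrinsic MVCAR requires a connected graph; islands must be bridged
  or dropped by the user.
* Poisson only: no negative-binomial or zero-inflated variants, and no
  covariate effects outside the index.
* Desk-scale runs shrink extreme cross-outcome correlations toward zero
  (see above); paper-scale data and chains sharpen this.
* The per-draw storage of the relative-risk surface is memory-hungry at
  thousands of units; disable with `store_theta = FALSE`.
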
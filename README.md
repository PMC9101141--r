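# svcindex

Bayesian spatially varying coefficient (SVC) index regression for
multi-outcome areal count data.

## The problem

Public-health studies of the retail environment ask how neighborhood
disadvantage relates to the density of tobacco and alcohol outlets across
small areal units (census block groups), and whether that relationship is
the same everywhere and for every outlet type. Fixed composite deprivation
indices prejudge each variable's importance; constant-coefficient models
prejudge spatial stationarity. `svcindex` implements a model that does
neither: the disadvantage index weights are estimated inside the outcome
model, and the index effect is allowed to vary over space and to be
correlated across outlet types. It is aimed at spatial epidemiologists and
biostatisticians working with areal counts and a battery of candidate
deprivation variables.

## The model

For unit *i* = 1..n and outcome type *k* = 1..K:

    y_ik ~ Poisson(theta_ik * E_ik),     E_ik = r_k * p_i
    log(theta_ik) = alpha_k + beta_ik * sum_j w_j q_ij

* `E_ik` — expected count: overall per-capita rate `r_k = sum(y_k)/sum(p)`
  times unit population (internal standardization, so expected and observed
  totals agree exactly);
* `q_ij` in 1..10 — decile scores of C oriented sociodemographic variables
  (per capita income is inverse-oriented with `max(x) - x`);
* `w` — index weights on the open simplex, Dirichlet prior (default
  uniform: a priori equal weight 1/C);
* `beta_ik` — unit- and outcome-specific index effect with a multivariate
  intrinsic CAR (MVCAR) prior over the adjacency graph; the K fields share
  a Wishart-prior precision `Omega` (BUGS rate convention, `R = 0.2 I`,
  `df = K`), and `Sigma = Omega^-1` yields the conditional correlations
  between outlet types;
* `alpha_k` — flat-prior intercepts.

Estimation is Metropolis-within-Gibbs (exact Gibbs for intercepts and
precision; Metropolis for the field and the weights, plus
likelihood-invariant moves along the model's weakly identified directions);
`exp(beta_ik)` is reported as the relative risk per index decile with
equal-tailed 95% credible intervals, a unit being flagged significant when
the lower bound exceeds 1. Convergence is assessed with the Gelman–Rubin
statistic (threshold 1.2). See the methods vignette
(`vignettes/svc-index-model.Rmd`) for the full account.

## Worked example

The package is organised as an analysis workflow over synthetic lattice
data with known ground truth (no public dataset accompanies the model);
the numbered drivers under `analysis/` run it end to end:

```sh
Rscript analysis/01_simulate.R   # dataset bundle -> results/run/
Rscript analysis/02_fit.R        # decile design, expected counts, MCMC draws
Rscript analysis/03_diagnose.R   # Rhat, effects, weights, correlations, Welch tests
Rscript analysis/04_recovery.R   # parameter-recovery experiment -> results/recovery.json
```

`analysis/04_recovery.R` generates data from the strong-signal validation
configuration — truth weights (0.26, 0.18, 0.16, 0.14, 0.12, 0.04, 0.04,
0.03, 0.03), conditional correlation 0.9 between outcomes 1 and 2, zero
elsewhere — refits the model at desk scale (5k burn-in / 5k retained, two
chains), and prints:

```
recovery_report: 8/9 weight CrIs cover truth; top-3 rank recovered; max Rhat 1.127 (all converged)
  variable truth median   lower  upper abs_error covered
1      w_1  0.26 0.2468 0.21265 0.2792   0.01315    TRUE
2      w_2  0.18 0.1978 0.16716 0.2302   0.01779    TRUE
3      w_3  0.16 0.1927 0.15764 0.2316   0.03269    TRUE
...
  pair k l  median  lower  upper truth covered
1  1-2 1 2  0.8762  0.832 0.9097   0.9    TRUE
2  1-3 1 3  0.0246 -0.121 0.1644   0.0    TRUE
```

Reading: eight of nine 95% credible intervals cover the generating weights
and the three dominant variables are ranked correctly; every monitored
scalar has Gelman–Rubin below the 1.2 threshold; and the posterior for the
cross-outcome conditional correlation separates the correlated pair
(median 0.88, interval covering the generating 0.9) from the uncorrelated
ones.

Equivalent programmatic entry points: `run_pipeline()` (simulate → prep →
fit → diagnose into a run directory with a checksummed manifest) and
`recovery_experiment()`.

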
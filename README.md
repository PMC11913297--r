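# cicapprox

Approximate a probability density that you can only evaluate **up to an
unknown normalizing constant**, and estimate that constant, using as few
evaluations as possible.

The setting is ubiquitous in computational statistics. You can compute a
nonnegative function `r(x)` on `R^p`, but the density you actually care
about is

```
q*(x) = r(x) / rho,      rho = ∫ r(x) dx   (unknown)
```

and each evaluation of `r` is expensive — a simulator run, a full-data
likelihood, a finite-element limit-state check. Typical instances:

* **Bayesian inference** — `r = prior × likelihood`; `q*` is the posterior
  and `rho` the model evidence.
* **Rare-event / importance sampling** — `r(x) = 1{failure}(x) p(x)`; `q*`
  is the optimal importance-sampling density and `rho` the failure
  probability.

`cicapprox` approximates `q*` within the family of Gaussian mixtures by
adaptive importance sampling. What distinguishes it from fixed-family
cross-entropy methods is that the *number of mixture components* `k` is
chosen automatically, per iteration, by an information criterion built for
weighted samples.

## The method

Let `q_theta` be a `k`-component Gaussian mixture with free-parameter
dimension `d = (k−1) + k(p + p(p+1)/2)`. Minimizing `KL(Q* || Q_theta)` is
equivalent to minimizing the cross-entropy `C(theta) = −∫ r log q_theta dx`,
which is estimated from points `X_i ~ q_eta` by the importance-weighted
average (the *approximate cross-entropy*, ACE)

```
ACE(theta) = −(1/n) Σ_i w_i log q_theta(X_i),   w_i = r(X_i) / q_eta(X_i).
```

Its minimizer (the *minimum cross-entropy estimator*, MCE) is found by a
weighted EM algorithm. Evaluating the ACE at its own minimizer is biased
downward by `rho·d/n` asymptotically — the weighted-sample analogue of the
optimism that the AIC corrects. The *cross-entropy information criterion*

```
CIC(k) = ACE(theta_hat_k) + rho_hat · d_k / n
```

removes that bias, so minimizing `CIC` over `k` selects the component count
best supported by the evaluations collected so far. When sampling happens
directly from `q*`, the weights are constant and `CIC = rho × AIC`.

The driver iterates: sample from the current mixture → evaluate `r` once
per point → refit every candidate `k` on all accumulated (stage-weighted)
samples → keep the CIC-minimizing mixture as the next proposal. The
normalizing constant is estimated as the mean importance weight, pooled
over all stages after the initial one (`rho_hat` is exactly `rho` with zero
variance when the proposal reaches `q*`).

## Worked example

Estimate the tail probability `rho = Φ(−1.5) ≈ 0.0668` of a half-space
under a bivariate standard normal, starting from an overdispersed `N(0, 9 I)`
proposal — a miniature structural-reliability problem where `r(x)` is zero
except beyond the limit state:

```r
library(cicapprox)
cli_main(c("demo", "--fixture", "indicator", "--seed", "1"))
```

```
Iteration 1: selected k = 3, rho_hat = 0.0881008 (ESS 55.6)
 k  d       ace       cic
 1  5 0.1532416 0.1536821
 2 11 0.1152032 0.1161723
 3 17 0.1102750 0.1117727
...
Iteration 5: selected k = 3, rho_hat = 0.0676732 (ESS 885.0)
 k  d       ace       cic
 1  5 0.1349445 0.1350122
 2 11 0.1188848 0.1190336
 3 17 0.1152359 0.1154660
selected k: 3
rho_hat: 0.0673921 (se 0.000559)
```

Reading the output: each iteration reports, per candidate component count
`k`, its dimension `d`, the cumulative ACE of the fitted mixture and its
CIC; the selected `k` minimizes the CIC. The effective sample size (ESS)
shows the proposal adapting — from 56 useful points out of 1000 under the
initial proposal to ~885 once the mixture has bent itself along the
truncated-Gaussian target. The final estimate `0.0674 ± 0.0006` brackets
the true `0.0668`. The same machinery is available programmatically:

```r
target <- make_indicator_target(c(1, 0), b = 1.5)
config <- run_config(gmm_params(1, c(0, 0), list(diag(9, 2))),
                     tau = 5, k_grid = 1:3, seed = 1)
fit <- cic_approximate(target, config)
fit$rho            # 0.0673921
fit$selected_k     # per-iteration selections
```

User-supplied problems plug in through `unnorm_target(p, fun)` — any
vectorized nonnegative evaluator — or through a YAML/JSON configuration
file and the `cicapprox approximate` command (see `?parse_config`,
`?cli_main`).

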
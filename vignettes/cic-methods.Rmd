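---
title: "Cross-entropy information criterion: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-entropy information criterion: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicapprox)
```

## The problem

We want to approximate a density $q^*(x) = r(x)/\rho$ on $\mathbb{R}^p$
when only the unnormalized, nonnegative function $r$ can be evaluated,
$\rho = \int r\,d\mu$ is unknown, and each evaluation of $r$ is expensive
enough that none should be wasted. The two quantities of interest are a
parametric approximation of $q^*$ and an estimate of $\rho$ — the model
evidence in Bayesian problems, the failure probability in rare-event
problems.

## Estimators

**ACE.** With points $X_i \sim q_\eta$ and importance weights
$w_i = r(X_i)/q_\eta(X_i)$, the cross-entropy
$C(\theta) = -\int r \log q_\theta\,d\mu$ is estimated unbiasedly by the
approximate cross-entropy
$\bar C_\eta(\theta) = -\tfrac1n \sum_i w_i \log q_\theta(X_i)$.
Minimizing it over $\theta$ gives the minimum cross-entropy estimator
(MCE); when the proposal equals $q^*$ the weights are constant and the MCE
is the maximum likelihood estimator.

**Cumulative forms.** Over iterations $s = 0,\dots,t-1$ with proposals
$q_{\hat\theta^{(s)}}$ and stage sizes $n_s$, every archived observation
enters the cumulative ACE with equal weight,
$\bar C^{(t-1)}(\theta) = -\left(\sum_s n_s\right)^{-1}
\sum_s \sum_i w_i^{(s)} \log q_\theta(X_i^{(s)})$.
No stage reweighting is applied; alternatives that favour newer stages are
deliberately out of scope.

**CIC.** Evaluating the ACE at its own minimizer is optimistic; its
asymptotic bias is $-\rho d/n$, with $d$ the free-parameter dimension.
The criterion used for choosing the mixture size is therefore
$\mathrm{CIC}(d) = \bar C(\hat\theta) + \hat\rho\, d/n$, and the selected
$k$ minimizes it. The test suite checks the bias constant empirically: for
a single 1-D Gaussian family ($d = 2$) the Monte-Carlo mean of
$n[\bar C_{\hat\theta^{(1)}}(\hat\theta^{(2)}) - C(\hat\theta^{(2)})]/\rho$
over 1000 replicates at $n = 400$ falls within $\pm 0.8$ of $-2$.

**$\hat\rho$.** The mean importance weight. At the first iteration it uses
the initial stage; from the second iteration onward the initial stage is
excluded, because weights drawn under a poorly chosen initial proposal can
dominate the pooled variance. Model selection cannot influence $\hat\rho$
within an iteration (it does not depend on $k$), so it is computed once
per iteration, before the component-count loop. The reported standard
error treats the pooled weights as i.i.d.; that is exact within a stage
and an approximation across stages.

## Weighted EM

For fixed $k$, the MCE is found by EM on the weighted sample:
responsibilities $\gamma_{ij} \propto \pi_j N(x_i;\mu_j,\Sigma_j)$, then
masses $m_{ij} = w_i\gamma_{ij}$ drive standard mean/covariance updates.
Each step does not increase the ACE; the suite asserts every trajectory is
non-increasing to within $10^{-9}$.

Numerical choices, all validated by the closed-form $k=1$ solution and the
constant-weight reduction to an independent unweighted EM (`mclust`):

* **Covariance floor.** Rare-event weights concentrate on few points, so
  M-step covariances can degenerate. Eigenvalues are clipped at
  $10^{-6}$ times the average marginal variance of the weighted sample.
* **Initialization.** Weighted k-means++-style seeding over the positively
  weighted points; $k = 1$ uses the exact weighted mean/covariance.
* **Collapse handling.** A component whose mass vanishes (or that sits on
  the covariance floor) for three consecutive iterations is re-seeded at
  the point the current mixture explains worst, weight-adjusted; after two
  rescues the restart aborts. If all restarts abort, that $k$ is excluded
  from selection rather than failing the run.
* **Stopping.** Relative ACE change below $10^{-6}$, at most 500
  iterations, 4 restarts, ties broken by restart order. These are the
  package's own tolerances; the method itself only requires the EM cost to
  stay below the cost of evaluating $r$.
* **Support guard.** A fit is refused when $d$ reaches half the effective
  sample size $(\sum w)^2/\sum w^2$ of the pooled weights — with fewer
  effective observations than half the parameter count, the M-step is
  ill-posed and the criterion comparison meaningless.

## The driver

Each iteration samples from the current mixture, evaluates $r$ exactly once
per point (weights are stored, never recomputed from fresh evaluations),
refits every candidate $k$ on the full archive, and selects by CIC. Two
behaviours are worth calling out:

* Every $k$ is refit from scratch at every iteration, which matches the
  cumulative estimator's definition and avoids path dependence. A
  `warm_start` option additionally seeds EM with the previous iteration's
  fit of the same $k$ — extra starts only, so it can only lower the ACE.
* Selection is performed from the first iteration on, even though the bias
  result formally applies from the second; early selections are already
  useful for steering the proposal and carry the documented caveat.
* The grid search is exhaustive by default; an `early_stop` option ends it
  after two consecutive CIC increases, reflecting the typical
  decrease-then-increase shape of the criterion in $k$.
* If the freshly selected mixture assigns an effective sample size below 5
  to its own stage, a warning is issued but the run continues; there is no
  principled abort rule, and later stages usually recover.

After the last iteration a final sample is drawn from the output mixture
purely to sharpen $\hat\rho$, which is then pooled over all post-initial
stages. Total evaluations of $r$ are exactly
$\sum_{t=0}^{\tau} n_t$.

The non-cumulative variant (`cumulative = FALSE`, single fixed $k$) is the
classical iteration that refits on the newest stage only; it exists for
the fixed-family setting and for the bias experiment above.

## Synthetic targets and what they do (and do not) show

All validation targets are generated in code with known $\rho$:

* **In-family mixture** ($r = \rho\, q_\theta$, default: equal-weight
  components at $\pm 3$, unit variances, $\rho = 3$) — the well-specified
  case; used for recovery of $k$ and of component locations.
* **Half-space indicator** ($r(x) = 1\{u^\top x > b\}\varphi_p(x)$,
  default $b = 1.5$, $p = 2$, so $\rho = \Phi(-1.5)$) — reproduces the
  weight sparsity of structural-reliability problems with a limit state
  linear in the standardized inputs, while keeping $\rho$ in closed form.
* **Conjugate normal posterior** ($r = \text{prior} \times
  \text{likelihood}$, evidence in closed form) — the Bayesian use case.

Oracles compute $C(\theta)$ and $\rho$ independently of the estimators:
adaptive quadrature on a $\pm 12$-standard-deviation window with absolute
tolerance $10^{-9}$ for $p = 1$, Monte Carlo from the known $q^*$ with
reported standard errors for $p \ge 2$; stochastic comparisons use
4-standard-error bands.

These fixtures exercise weighting, fitting, selection and
normalizing-constant estimation, but they are low-dimensional, unimodal or
mildly multimodal, and have Gaussian-compatible tails. Passing them does
not certify behaviour on heavy-tailed targets, strongly curved limit
states, high dimensions (where mixture covariances have $O(p^2)$
parameters and the ESS guard will bind quickly), or evaluators with
stochastic noise — all outside this package's scope.

## Problem sizes used in validation

The suite's end-to-end checks run at desk scale, chosen as the smallest
sizes at which the statistical claims are comfortably testable: stage
sizes 500–1000, up to 5 iterations, component grids up to $k = 5$, 20
seeds for selection-rate checks, 50 seeds for the variance-trend check,
and 500–1000 replicates for unbiasedness and bias-constant checks. The
acceptance script uses the same scales and finishes in well under a minute
of CPU time per fixture.

## Known limitations

* Mixture components are full-covariance Gaussians only; the interfaces
  would admit other exponential-family components, but none are built.
* The i.i.d.-pooled standard error for $\hat\rho$ ignores between-stage
  dependence introduced by proposal adaptation; treat it as a guide, not
  an exact confidence width.
* Self-normalized and defensive (mixture-proposal) weighting schemes are
  not implemented.
* The ESS warning threshold (5) and the $d < \tfrac12\,\mathrm{ESS}$ guard
  are pragmatic defaults, not theory-derived constants.
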
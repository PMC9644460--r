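---
title: "Methods: a stock-and-flow model of psychological distress prevalence"
author: "distressdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stock-and-flow model of psychological distress prevalence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distressdyn)
```

## The model and its assumptions

`distressdyn` fits a one-stock system-dynamics model of the number of adults
currently experiencing high to very high psychological distress (K10 score
of 22 or more), denoted $M(t)$:

$$\frac{dM}{dt} = i(t)\,\bigl(P(t) - M\bigr) \;-\; \gamma\,k(t)\,M \;-\; s\,M
\;-\; r(t)\,C(t).$$

People with low/moderate distress develop high/very-high distress at
per-capita rate $i(t)$; they leave the stock through mortality (hazard ratio
$\gamma \ge 1$ over the background per-capita rate $k$), natural recovery at
rate $s$, and treated recovery $r(t)\,C(t)$, where $C(t)$ patients are
treated per year and a fraction $r(t)$ of them recover.

Structural assumptions inherited from the study design:

* **Exogenous, capacity-driven treatment volume.** $C(t)$ does not depend on
  $M$: services operate at or near capacity, so provision is set by
  availability, not demand. Consequently the treated-recovery flow
  $r\,C$ is state-independent (see the numerical guard below).
* **Linear exogenous drivers.** $P(t) = P_0 + g\,t$, $D(t) = D_0 + h\,t$,
  $C(t) = C_0 + u\,t$. The levels and slopes carry priors estimated as
  linear-regression quantities, which is why the drivers are linear in time
  rather than exponential.
* **Exponential behavioural trends.** $i(t) = i_0 e^{\delta_i t}$ and
  $r(t) = r_0 e^{\delta_r t}$ change at constant *fractional* rates; the two
  trend parameters $\delta_i$ and $\delta_r$ are the scientific targets
  (rising individual-level risk vs. changing treatment effectiveness).
* **Mortality closure.** Only total deaths $D(t)$ are observed, so the
  background rate is recovered from the identity
  $D = k\,(P - M) + \gamma k M$, i.e. $k = D / (P + (\gamma - 1) M)$,
  re-evaluated from the instantaneous state inside the derivative. The
  identity therefore holds exactly at every stored time, which the tests
  assert to $10^{-8}$ relative tolerance.
* **No migration into the stock**; new entrants to the population arrive
  with low/moderate distress.
* Time is measured in years since the start of 2008; the fitted horizon is
  $t \in [0, 12]$ (2008–2019).

## Observation model

Each record of one of the four streams — `distress` ($\to M$), `population`
($\to P$), `mortality` ($\to D$), `services` ($\to C$) — is evaluated at
mid-year, $t = \text{year} - 2008 + 0.5$: the population series is a 30-June
snapshot, and under locally linear trends a yearly flow total is best
matched by the mid-year instantaneous rate. Counts are negative-binomial in
the gamma–Poisson (inverse-scale) parameterisation: mean $m$, shape
$\beta m$, so $\mathrm{Var} = m(1 + 1/\beta)$ and $\beta \to \infty$ is the
Poisson limit. Deviations are independent across records, so the total
log-likelihood is the sum over records. The log-pmf is evaluated through
`stats::dnbinom`, whose saddle-point algorithm remains accurate where the
naive `lgamma` difference cancels catastrophically (shape $\beta m$ can
reach $10^{12}$ and beyond during sampling).

## Priors

`default_priors()` ships the documented prior set: truncated normals for the
initial prevalence (mean 0.1464, the midpoint of the 2007/2009 survey
estimates) and for the driver levels/slopes (sd = 20% of the mean, from
linear regressions of the published series); a shifted lognormal on
$\gamma - 1$ with mode 0.37 ($\gamma = 1.37$) and 95th percentile 1
($\gamma = 2$); a lognormal on $s$ with mode 0.31 and 95th percentile 0.45;
non-informative half-normal/normal (sd 0.5) on $i_0$ and $\delta_i$; a
truncated normal on $r_0$ with mean $0.45 \times 0.41 = 0.1845$ (sustained
response rate × proportion receiving minimally adequate care); and
normal(0, 0.0125) on $\delta_r$, bounding $|\delta_r|$ below about
3.75%/yr at 3 sd. Truncated-normal normalising constants are included.

The dispersion priors are the package's own choice (the observation-noise
scales are not published): normal(1, 1) on $\log_{10}\beta$ per stream,
spanning near-Poisson to strongly overdispersed counts. With the default
generator's near-deterministic administrative streams, $\beta$ is
unidentifiable above the Poisson limit — the likelihood is flat in $\beta$
once $1/\beta$ is small against the relative residuals — so its posterior is
prior-dominated by design; $\beta$ is accordingly not part of the
parameter-recovery coverage checks, which target the 13 dynamic parameters.

## Numerical integration

The ODE is one-dimensional and non-stiff at all plausible parameters, so the
integrator is an embedded Cash–Karp Runge–Kutta 4(5) with adaptive step
control (`rtol` $10^{-8}$, `atol` $10^{-4}$ persons), implemented in C++
because a fit evaluates the likelihood — and hence the ODE — some $10^5$
times. Tests verify agreement with a $dt = 10^{-4}$ yr Euler oracle
(relative error $< 10^{-4}$), with `deSolve::lsoda` at tight tolerances, and
with the constant-coefficient closed form
$M(t) = M^* + (M_0 - M^*)e^{-(i + \gamma k + s)t}$,
$M^* = iP/(i + \gamma k + s)$ (relative error $< 10^{-6}$).

Two guards handle regimes the fitted posterior never visits but prior-tail
draws can reach:

* $r(t)$ is a proportion and is clipped at 1, with a flag
  (`attr(traj, "r_clipped")`).
* The state-independent flow $r\,C$ can formally overdraw the stock. The
  outflow is capped by a continuous ramp within $\max(1, rC/1000)$ persons
  of an empty stock and flagged (`recovery_capped`). A ramp rather than a
  hard per-step cap keeps the derivative continuous — a discontinuity at
  $M = 0$ stalls adaptive step control — and the ramp width keeps the
  boundary-layer relaxation rate explicitly integrable while remaining a
  negligible fraction of the population.
* The solver caps its step budget at $10^5$; parameter draws needing more
  (explosive incidence trends with relaxation times below $10^{-4}$ yr) are
  treated as zero-likelihood by the sampler. Their exact log-likelihoods are
  on the order of $-10^6$, so this changes nothing statistically and removes
  a severe computational tail.

## Sampling

The posterior over the 13 dynamic parameters plus the 4 dispersions is
sampled on an unconstrained scale — log for positive parameters, logit for
proportions, $\log(\gamma - 1)$ for the hazard ratio, identity for the
unbounded slopes and trends — with the usual Jacobian corrections, and the
coordinates are standardised by each prior's median and central 95% interval
so all directions are $O(1)$.

The kernel is gradient-free (no ODE sensitivities are needed at this scale):

1. **Initialisation.** Prior draws are screened (re-drawn while the
   posterior is $-\infty$); the five best seed a multi-start Nelder–Mead
   search followed by a BFGS polish, and the inverse Hessian at the best
   mode gives a Laplace covariance. Multi-start matters: the posterior has a
   rare spurious basin (very large $i_0$ offset by a strongly negative
   $\delta_i$) that a single start can fall into. Nelder–Mead precedes BFGS
   because numerical gradients explode across the support boundary.
2. **Metropolis-within-Gibbs sweep.** Each iteration updates along every
   eigen-direction of the covariance with a 1-D random-walk step,
   Robbins–Monro-adapted towards 44% acceptance during warmup; the sweep
   directions are refreshed from the accumulated empirical covariance.
3. **Independence moves.** With probability 0.2 an independence Metropolis
   proposal from $N(\text{mode}, 2\times$Laplace$)$ offers $O(1)$ jumps that
   decorrelate directions the sweep traverses slowly.

All adaptation is confined to the discarded warmup half, so the post-warmup
chain is a fixed, valid MH kernel. A plain joint random-walk Metropolis was
tried first and mixed an order of magnitude worse (bulk ESS ~5–40 at
4 × 1000 on 17 dimensions), which miscalibrated credible intervals; the
sweep kernel reaches ESS ~30–350 at the same budget. Defaults follow the
study configuration (4 chains × 4000 iterations, first half warmup, 8000
retained draws); one master seed derives the per-chain seeds, making runs
exactly reproducible. Convergence is summarised by rank-normalised
split-$\hat R$ and bulk ESS (Geyer initial monotone sequence); $\hat R >
1.01$ raises a flag on the fit, not an error.

Constrained variants pin parameters (`pinned = c(delta_i = 0)` or
`c(delta_r = 0)`): pinned parameters are removed from the sampled vector and
fixed verbatim in every draw.

## Posterior post-processing

* `trajectory_bands()` simulates 1000 randomly selected draws (the figure
  convention) and reports pointwise 2.5/25/50/75/97.5 percentiles.
* `counterfactual_prevalence()` re-simulates each draw with $\delta_i := 0$.
  The headline difference is *counterfactual prevalence at the start of 2008
  minus at the end of 2019* ($t = 0$ vs $t = 12$), following the reading
  that prevalence "would have decreased by" that amount over the period; the
  alternative contrast (factual minus counterfactual at end-2019) is
  computed alongside as `difference_vs_factual`. Persons averted multiply
  the difference by that draw's 2019 population; the relative reduction
  divides by that draw's 2008 prevalence. The "2019" evaluation time is
  end-of-year so the contrast spans the full study period; this is a
  configurable choice (`reference_years`).
* `posterior_predictive_check()` uses the $\chi^2$ discrepancy
  $T(y) = \sum_t (y_t - m_t)^2 / \mathrm{Var}_t$ with the negative-binomial
  variance $m(1 + 1/\beta)$ by default (Pearson $m$ selectable), comparing
  observed with replicated data; the Bayesian p-value is
  $\Pr\{T(y^{rep}) \ge T(y)\}$.
* `stream_mean_loglik()` provides the constrained-model comparison: the
  posterior-mean log-likelihood of one stream under each fit.

## The synthetic-data generator

`generate_observations()` reproduces exactly the statistical structure the
likelihood assumes — trajectory under a known truth, mid-year means,
independent negative-binomial noise per record — at the study's design: 6
biennial survey points (2009–2019) and 12 yearly points (2008–2019) per
administrative stream. `default_truth()` sets the drivers and recovery
parameters to the prior central values and chooses $i_0 = 0.06$/yr,
$\delta_i = 0.02$/yr so that prevalence stays near 0.146 while rising
incidence is partly offset by growing treatment volume — the regime the
method exists to disentangle. Dispersions are $\beta = 400$ for the survey
stream and $10^5$ for the administrative streams (near-deterministic
administrative series, visible relative noise only in the survey stream).

What the generator deliberately does **not** emulate: survey design effects
(weights, attrition, clustering), reporting-sensitivity drift in the K10
instrument, autocorrelated measurement error, and any model misspecification
(the generator *is* the fitted model). Passing the recovery and calibration
tests therefore demonstrates that the pipeline is correct and
well-calibrated *under the model's own assumptions*; it cannot certify
behaviour on real survey data, where the observation model is at best an
approximation.

## Problem sizes used in the tests

The test suite and the acceptance script run reduced-size studies chosen as
the smallest configurations that still exercise every claim: recovery and
calibration studies use 20 replications at 4 chains × 1000 iterations
(the full 4 × 4000 configuration is used for the single fit in the
acceptance script), predictive checks use 400–1000 posterior draws, and the
counterfactual uses its draw-count convention of 1000. On the coverage
criterion, note the statistic is a minimum over 13 components of a
Binomial(20, 0.95) count — stringent even for perfectly calibrated
intervals — so coverage summaries near 0.9 are the expected behaviour, not
evidence of miscalibration.

## Known limitations

* The sampler is tuned for this 17-parameter posterior; it is not a
  general-purpose MCMC engine, and heavily multimodal posteriors beyond the
  documented spurious basin would require re-examining the multi-start
  initialisation.
* With near-deterministic administrative streams the dispersions of those
  streams are one-sided-identified only (a lower bound), and their
  posteriors track the prior above the Poisson limit.
* Yearly flow totals are matched by mid-year instantaneous rates; for
  strongly curved trajectories within a year this approximation would bias
  the mortality/services means, though at the fitted trends the curvature is
  negligible.
* The model aggregates all severities above the K10 ≥ 22 threshold into one
  stock; severity structure, capacity-dependent provision and migration
  flows are out of scope.
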
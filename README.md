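# distressdyn

Bayesian system-dynamics modelling of psychological distress prevalence.

## The problem

Across several high-income countries, the prevalence of common mental
disorders has stayed flat or risen despite large increases in treatment
provision. Two competing explanations are (1) the individual-level risk of
developing a disorder has been rising, masking a real treatment benefit, and
(2) treatment effectiveness has been falling as services are stretched.
`distressdyn` implements a dynamic-modelling analysis that separates these
explanations using four routinely collected yearly count series: adults with
high/very-high psychological distress (K10 score ≥ 22) at survey years,
mid-year adult population, total adult deaths, and adults with high/very-high
distress receiving subsidised mental-health care.

The package is for epidemiologists and health-services researchers who want
a tested, reusable version of this analysis — runnable end to end on
synthetic data with the same statistical structure, or on their own CSV of
the four streams.

## The model

A single stock *M(t)* counts people currently in high/very-high distress:

```
dM/dt = i(t) (P(t) − M) − γ k(t) M − s M − r(t) C(t)
```

* inflow: incidence `i(t) (P − M)`, with per-capita incidence
  `i(t) = i₀ exp(δᵢ t)`;
* outflows: mortality `γ k M` (hazard ratio γ over the background rate
  `k(t)`, recovered from the total-mortality identity
  `D = k (P − M) + γ k M`), natural recovery `s M`, and treated recovery
  `r(t) C(t)`, with effectiveness `r(t) = r₀ exp(δ_r t)`;
* exogenous drivers: population `P(t) = P₀ + g t`, total mortality
  `D(t) = D₀ + h t`, patients treated per year `C(t) = C₀ + u t`.

Time is measured in years since the start of 2008. Each observed count is
negative-binomial around its model mean `m` with per-stream inverse scale β
(variance `m (1 + 1/β)`). All 13 dynamic parameters and the four β's are
sampled by MCMC (adaptive Metropolis-within-Gibbs on an unconstrained scale;
default 4 chains × 4000 iterations, first half warmup) under the documented
priors (`default_priors()`), including a truncated-normal initial prevalence
prior centred at 0.1464 and a shifted-lognormal hazard-ratio prior with mode
1.37.

The two headline quantities are the posterior probability that δᵢ > 0
(rising individual-level risk) and the counterfactual prevalence change
obtained by re-simulating every posterior draw with δᵢ = 0 (incidence held
at its 2008 level).

## Worked example

Generate a synthetic data set with the study's design (6 biennial survey
points 2009–2019; 12 yearly points per administrative stream) from the
documented ground truth (`default_truth()`: rising incidence δᵢ = 0.02/yr,
constant effectiveness trend δ_r = 0), fit, and post-process:

```r
library(distressdyn)

obs <- generate_observations(seed = 1)
fit <- fit_distress_model(obs, chains = 4, iterations = 2000, seed = 2)
fit
#> Distress dynamics model fit (adaptive Metropolis-within-Gibbs)
#>   4 chains x 2000 iterations (warmup fraction 0.50), seed 2
#>   4000 retained draws; mean acceptance 0.45
#>   max split-R-hat 1.114, min bulk ESS 31

summary(fit)   # medians, 95% CrIs, split-R-hat, bulk ESS per parameter
#>  parameter   median      lower    upper
#>  i0         0.06275    0.05211  0.07598
#>  delta_i    0.01924    0.01678  0.02186
#>  s          0.32596    0.26632  0.40211
#>  r0         0.18758    0.12607  0.24348
#>  delta_r   -0.00323   -0.02531  0.01675
#>  ...

posterior_probability(fit, function(d) d$delta_i > 0)
#> [1] 1
```

The incidence trend is recovered (true δᵢ = 0.02 inside the 95% CrI) and its
sign is established with posterior probability 1, while δ_r stays centred at
0 — the data contain no signal of changing effectiveness, matching how they
were generated.

The counterfactual re-simulates each draw with δᵢ := 0:

```r
counterfactual_prevalence(fit, n_draws = 1000, seed = 3)
#> Counterfactual (constant incidence, delta_i = 0), 2008-2019, 1000 draws
#>   prevalence difference: 0.0121 (95% CrI 0.0086-0.0162)
#>   persons averted:       239860 (95% CrI 171267-321146)
#>   relative reduction:    8.23% (95% CrI 5.87%-10.99%)
```

Had incidence stayed at its 2008 level, prevalence would have fallen by 1.2
percentage points over 2008–2019 under this synthetic regime — about 240,000
fewer people in distress in 2019 — because treatment volume keeps growing.
A posterior predictive χ² check on the survey stream shows no misfit:

```r
posterior_predictive_check(fit, stream = "distress", n_draws = 500, seed = 4)$p_value
#> [1] 0.674
```

`run_full_analysis(obs, outdir)` chains all of the above (unconstrained fit,
counterfactual, both constrained fits with a per-stream fit-comparison
table, predictive checks, plain-text report) and writes CSV/JSON outputs
that round-trip through the package's readers. Real data are supplied as a
CSV with header `stream,year,value` via `read_observations()`; priors can be
edited as YAML (`write_priors()` / `read_priors()`).

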
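# gmaic

Anchored population-adjusted indirect treatment comparisons for binary
outcomes, built for the common health-technology-assessment situation
where individual participant data (IPD) are available for one trial
(A vs C) but only published aggregate-level data (ALD) — covariate
means/SDs, arm sizes and event counts — for the comparator trial
(B vs C).

The package implements, behind one uniform interface:

* **Bucher's method** — the unadjusted anchored contrast
  d̂(AB) = d̂(AC) − d̂(BC), biased when effect modifiers are distributed
  differently across the two trial populations;
* **MAIC** (matching-adjusted indirect comparison) — weights
  w_i = exp(αᵀx_i) solved from the mean-balancing moment condition
  Σᵢ w̃_i x_i = x̄(ALD), used in a weighted marginal regression, with
  non-parametric bootstrap SE;
* **Bayesian parametric G-computation** — a Bayesian logistic outcome
  model logit P(y=1|t,x) = β₀ + β_t t + xᵀβ₁ + t·xᵀβ₂ fitted on the
  IPD and marginalised over a parametric population simulated to match
  the ALD moments (multivariate normal, or Gaussian-copula multivariate
  Gamma as a deliberately mis-specified variant);
* **G-MAIC** — the same outcome regression marginalised over a
  *Bayesian-bootstrap* approximation of the ALD population: the
  normalised MAIC weights act as pseudo-frequencies, giving a Dirichlet
  posterior π ~ Dirichlet(n·w̃) over the observed covariate profiles;
  each posterior draw of the outcome model is paired with a fresh
  Dirichlet draw, so the reported variance propagates both sources of
  uncertainty without parametrising the covariate distribution.

All four target the **marginal** A-vs-B log odds ratio in the ALD trial
population (odds ratios are non-collapsible, so this differs from the
conditional coefficient). A synthetic data-generating module and an
ADEMP-style simulation harness (bias, empirical SE, model-average SE,
coverage, with Monte Carlo standard errors) reproduce the two-trial
benchmark design the estimators are evaluated on: five covariates that
are simultaneously prognostic and effect-modifying, three population
overlap levels calibrated by effective-sample-size reduction, and
normal vs non-normal (skewed + binary, non-linearly dependent)
covariate structures.

## Worked example

```r
library(gmaic)
set.seed(2026)

# a two-trial anchored network from the built-in DGP
cfg <- scenario_config(n_ipd = 200, overlap = "moderate", structure = "normal")
ipd <- simulate_trial(cfg, "AC")            # IPD trial: A vs C
ald <- aggregate_ipd(simulate_trial(cfg, "BC"))  # published summaries: B vs C

# moment-matching weights against the published covariate means
w <- estimate_weights(ipd$X, ald$cov_means)
w
#> MAIC weights: n = 200, ESS = 80.5 (59.8% reduction), max |balance residual| = 3.6e-10

# Bayesian outcome regression, then G-MAIC marginalisation
post <- fit_outcome_model(ipd, L = 1000, method = "mcmc")
fit <- gmaic(post, ipd, w, ald)
fit
#> G-MAIC (Bayesian-bootstrap marginalization)
#>   A vs B log-OR: -0.5038 (SE 0.4302), 95% CI [-1.3470, 0.3395]
#>   ESS: 80.5 (59.8% reduction)

maic(ipd, ald, n_boot = 1000)
#> MAIC (moment-matching weights, bootstrap SE)
#>   A vs B log-OR: -0.2979 (SE 0.4590), 95% CI [-1.1975, 0.6017]
#>   ESS: 80.5 (59.8% reduction)

bucher(ipd_log_or(ipd), ald)
#> Bucher (unadjusted anchored contrast)
#>   A vs B log-OR: -0.6821 (SE 0.3521), 95% CI [-1.3723, 0.0080]

gcomp_parametric(post, ald, "mvn", cor(ipd$X))
#> Bayesian parametric G-computation
#>   A vs B log-OR: -0.5734 (SE 0.4051), 95% CI [-1.3673, 0.2205]
```

The printed estimate is the anchored marginal A-vs-B log odds ratio in
the BC trial population (here the design truth is 0: both active
treatments share the same conditional effect and effect modifiers).
The ESS line is the Kish effective sample size of the weights — a 59.8%
reduction means the reweighted IPD carries the information of roughly
80 of the 200 participants, the operative measure of population
overlap. `coef()`, `confint()`, `summary()` and `plot()` (posterior
contrast histogram) work on every estimate object.

Simulation benchmark:

```r
st <- run_study(make_scenarios(), n_sim = 500,
                methods = c("bucher", "maic", "gcomp", "gcomp_misspec", "gmaic"),
                seed = 1, out_dir = "simstudy-out")
plot_performance(st$performance, "bias")
```

A command-line front end lives at `inst/cli/gmaic-cli.R`
(`maic`, `gcomp`, `gmaic`, `bucher`, `simstudy` subcommands over IPD
CSV + ALD YAML files, JSON output).

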
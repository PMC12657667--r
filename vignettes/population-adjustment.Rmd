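---
title: "Population-adjusted anchored indirect comparisons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-adjusted anchored indirect comparisons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmaic)
```

## The problem

Two randomised trials form an anchored network: an *AC* trial comparing
the new treatment A against a common comparator C, for which we hold
individual participant data (IPD), and a *BC* trial comparing the
competitor B against the same comparator, for which only published
aggregate data (ALD) are available — covariate means and SDs, arm sizes
and event counts. The estimand is the **marginal A-vs-B log odds ratio
in the BC trial population**. Because some covariates modify the
relative treatment effect and are distributed differently in the two
trial populations, the naive anchored contrast
$\hat d_{AB} = \hat d_{AC} - \hat d_{BC}$ (Bucher's method) is biased;
and because the odds ratio is non-collapsible, conditional regression
coefficients do not answer the marginal question even when the model is
right.

## Estimators

**MAIC.** Weights $w_i = \exp(\alpha^\top x_i)$ on the IPD are the trial
assignment odds of a log-linear model that cannot be fitted directly
(no IPD for the BC trial), but $\alpha$ is identified by the
mean-balancing condition
$\sum_i \tilde w_i x_i = \bar x_{\mathrm{ALD}}$. `estimate_weights()`
minimises the convex dual
$Q(\alpha)=\sum_i \exp\{\alpha^\top (x_i - \bar x_{\mathrm{ALD}})\}$,
whose gradient is exactly the balance residual, so the first-order
condition *is* the moment constraint. The weighted marginal regression
of outcome on treatment (equivalently the weighted 2×2 log odds ratio)
gives $\hat d_{AC}$ in the reweighted population; the SE comes from a
non-parametric bootstrap that re-estimates the weights in every
resample. Matching is on means only by default; `match_sds = TRUE`
additionally balances second moments of continuous covariates.

**Parametric G-computation.** A Bayesian logistic outcome model
$\operatorname{logit} P(y=1\mid t,x) = \beta_0 + \beta_t t +
x^\top\beta_1 + t\,x^\top\beta_2$ is fitted on the IPD; a single
pseudo-population $\hat x_0$ of $n^\*$ profiles is simulated from a
parametric family moment-matched to the ALD (multivariate normal, or a
Gaussian copula with Gamma marginals); for each posterior draw $l$ the
average predicted probability under each treatment condition is formed
over $\hat x_0$ and contrasted on the logit scale,
$\Delta^{(l)} = \operatorname{logit}\mu_1^{(l)} -
\operatorname{logit}\mu_0^{(l)}$.

**G-MAIC.** Instead of parametrising the BC covariate distribution,
the reweighted IPD stands in for it. Treating the normalised MAIC
weights as pseudo-frequencies, Dirichlet–multinomial conjugacy with the
improper $\mathrm{Dirichlet}(0,\dots,0)$ prior gives the
Bayesian-bootstrap posterior
$\pi \sim \mathrm{Dirichlet}(n\tilde w_1,\dots,n\tilde w_n)$ over the
observed profiles. Each posterior draw of the outcome model is paired
with a fresh Dirichlet draw and
$\mu_t^{(l)} = \sum_i \pi_i^{(l)} p_i^{(l)}(t)$; the spread of
$\Delta^{(l)}$ therefore propagates both outcome-model and
population-approximation uncertainty. With uniform weights the scheme
reduces to Rubin's Bayesian bootstrap, which motivates the
concentration scale $a_i = n\tilde w_i$ (total concentration $n$); the
source method description does not print this formula, so that
reduction is the package's normalisation argument.

**Anchoring and intervals.** All methods report
$\hat d_{AB} = \hat d_{AC,\text{adj}} - \hat d_{BC}$ with
$\hat d_{BC}$ the 2×2 log odds ratio from the ALD event counts (0.5
continuity correction on all cells iff any cell is zero). For the
Bayesian methods the point estimate is the posterior mean of
$\Delta^{(l)}$ minus the anchor and the SE combines the posterior SD
with the anchor's sampling variance by summing variances — the ALD's
sampling error must enter somewhere, and a sum of variances is the
conservative, transparent choice. Intervals are Wald with multiplier
1.96. Posterior-quantile intervals were considered and rejected to
keep one interval construction across all five estimators.

## Failure handling

These methods fail in recognisable ways and the package records rather
than hides that:

* weight estimation that does not converge (e.g. ALD means outside the
  convex hull of the IPD covariates) returns `converged = FALSE`,
  never an error; `maic()` then flags the whole estimate invalid;
* bootstrap replicates whose weight estimation fails or whose weighted
  table is separated are dropped and counted (`boot_failures`); if more
  than half fail the SE is additionally flagged unreliable;
* marginalisation draws whose average probability is exactly 0 or 1
  (infinite after the logit) are dropped and counted;
* the simulation harness treats all invalid estimates as missing,
  reporting `failure_count` and `infinite_count` per method
  (complete-case within method).

## The synthetic data-generating process

`simulate_trial()` emulates a two-trial anchored network with five
covariates that are all simultaneously prognostic and
effect-modifying:

* outcome model: $\beta_t = \log 0.25$ for both active treatments
  (treatment effects equal by design, so the true marginal A-vs-B
  contrast is exactly 0 — verified by `true_marginal_effect()`),
  $\beta_1 = 0.5$ and $\beta_2 = 1.0$ per covariate (strong effect
  modification: the sign of the individual treatment effect flips
  across the covariate range);
* the intercept is calibrated by root-finding so the comparator-arm
  event rate in the BC population equals 0.35 (a mid-range default that
  avoids boundary degeneracy; configurable);
* BC population: five covariates centred at 0.6; under the **normal**
  structure, SD 0.2 with exchangeable correlation 0.2; under the
  **nonnormal** structure, three continuous covariates with Gamma
  marginals (shape 2, scale set by the mean, hence SD
  $= \text{mean}/\sqrt 2$ — with a fixed shape one cannot match both
  moments, and the mean is what MAIC balances) joined by a Gaussian
  copula, plus two binary covariates obtained by thresholding a noisy
  quadratic of the first covariate. The quadratic dependence is
  deliberately non-monotone: it leaves the linear correlation with
  $x_1$ near zero while creating strong non-linear dependence, which a
  log-linear trial-assignment model cannot represent — the mechanism
  that biases MAIC in the non-normal scenarios. Thresholds are solved
  by one-dimensional quadrature so the binary marginal probabilities
  (0.5 in the BC population) are exact;
* AC population: the same family with all means (and binary
  probabilities) shifted *down* by a per-overlap offset. The offsets
  are not free parameters: they were calibrated once by stochastic
  root-finding (200 trials of n = 600) so that the average MAIC ESS
  reduction hits the design targets — 31 / 55 / 82.7 % (high /
  moderate / poor overlap) under the normal structure and 32.7 / 55 /
  81 % under the nonnormal one — and then frozen in the package
  (normal: 0.0723, 0.1079, 0.1671; nonnormal: 0.1296, 0.1767, 0.2439).
  ESS reduction is the operative definition of overlap here;
* randomisation is exact 1:1 block assignment (arm-size noise would
  only blur the comparisons); the BC trial is fixed at 600
  participants, a typical phase-III size; IPD sizes 100 / 200 / 600.

The 3 × 3 × 2 factorial of size, overlap and structure gives the
18-scenario grid of `make_scenarios()`.

What the generator does *not* emulate: measurement error, missing
data, non-shared effect modifiers, covariate reporting differences
between trials, survival or continuous outcomes, and trial populations
whose *shapes* (not just locations) differ arbitrarily. Passing the
simulation benchmark therefore shows correct behaviour under a
controlled, favourable laboratory — not robustness on arbitrary real
submissions.

## Posterior computation

The outcome model has independent Normal(0, 10²) priors on every
coefficient — weakly informative on the log-odds scale and enough to
keep separated small samples proper. Two engines:

* `method = "mcmc"` (default): independence Metropolis–Hastings with a
  multivariate-t proposal (df 7) centred at the posterior mode with the
  inverse negative Hessian as scale, 2 chains, 250 burn-in draws each;
  the mode and Hessian come from a penalized Newton–Raphson with step
  halving. Split-chain $\hat R$ is computed for every parameter; if any
  exceeds 1.05 the sampler retries once with a heavier-tailed, wider
  proposal (df 4, scale ×1.6) and aborts loudly if still
  non-convergent. For a smooth 12-parameter logistic posterior an
  independence sampler at the Laplace approximation mixes rapidly
  (acceptance typically 0.5–0.9) and is asymptotically exact.
* `method = "laplace"`: draws from the multivariate normal Laplace
  approximation at the mode. This is an approximation, used for
  simulation runs needing thousands of fits; a test checks its
  agreement with the exact sampler at moderate n.

Covariates are deliberately *not* centred or scaled inside the fit:
the coefficients must stay on the data scale for marginalisation.
L = 1000 retained draws by default.

## Numerical choices

* Weight optimisation: BFGS on $\log Q$ with analytic gradient,
  start $\alpha = 0$, relative function tolerance $10^{-14}$;
  covariates centred at the target and standardised internally;
  convergence requires every standardised balance residual
  $< 10^{-6}$. Constant columns already matching their target are
  dropped with a warning; constant columns that do not match make the
  problem infeasible and are flagged, not thrown.
* Log-sum-exp stabilisation keeps the objective finite for extreme
  $\alpha$; weights are stored in the shift-invariant parameterisation
  $\exp\{\alpha^\top(x_i - \bar x_{\mathrm{ALD}})\}$.
* The simulated G-computation population is drawn **once** and shared
  across posterior draws; its correlation is borrowed from the IPD
  sample correlation, since the ALD reports none (an explicit
  assumption).
* Dirichlet draws use the gamma construction; one fresh draw per
  posterior draw, shared across the two treatment conditions of that
  draw.
* Tempering (`temper` < 1) raises normalised weights to a power below
  one before forming the concentration. It provably increases the ESS
  of the concentration vector; its variance-inflation effect on the
  contrasts is a property of the Bayesian-bootstrap component, so the
  package's test isolates it at a fixed outcome-model draw — with the
  full posterior the comparison is confounded, because tempering also
  moves the target population toward the unweighted IPD and thereby
  shifts the posterior contrast spread.

## Simulation harness

Performance measures follow the standard simulation-study forms: bias
$= \bar{\hat d} - d$; empirical SE $=$ SD of the estimates; model
average SE $=$ mean of reported SEs (root-mean-variance behind
`mod_se_type = "rms"`); coverage of 95 % Wald intervals; with MCSEs
$\mathrm{EmpSE}/\sqrt n$, $\mathrm{EmpSE}/\sqrt{2(n-1)}$ and
$\sqrt{c(1-c)/n}$. The true effect is taken as exactly 0 (design
implied and verified numerically), not re-estimated per scenario.
Replicates run on independent L'Ecuyer-CMRG sub-streams keyed by
replicate index, so results are reproducible and independent of
execution order.

Problem sizes used by the package's own checks: the coverage benchmark
runs 500 replicates of the n = 600 / high-overlap / normal scenario
with the Laplace posterior flag (L = 1000, $n^\*$ = 1000); the
instability benchmark runs 500 replicates of the n = 100 / poor /
nonnormal scenario with 250 bootstrap replicates per dataset —
bootstrap resolution affects only the SE resolution, not the point
estimates the bias comparison uses. The default for a single analysis
remains 1000 bootstrap replicates and 2000 replications for a full
study.

## Interface conventions

ALD covariate summaries are taken as pooled across arms (one mean per
covariate), matching how published baseline tables are most often
reported; SD entries for binary covariates are ignored by every
consumer. Per-draw contrast vectors are stored unanchored (the anchor
is a deterministic shift), so
`estimate$point + ald_log_or(ald)$estimate` always reconstructs the
adjusted A-vs-C contrast exactly.

## Known limitations

* G-MAIC never extrapolates beyond the IPD covariate support, so under
  very poor overlap its Dirichlet approximation of the ALD population
  becomes overly homogeneous and the variance is underestimated
  (under-coverage with small ESS); parametric G-computation is the
  better tool there, if one trusts its covariate family.
* The bootstrapped MAIC SE can explode or fail entirely in exactly the
  settings where adjustment matters most; failures are counted, not
  repaired.
* Only two-arm trials, binary outcomes and anchored comparisons are
  supported; no conditional-estimand (STC-style) output; no
  doubly-robust weighting; outcome models are linear-logistic only.
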
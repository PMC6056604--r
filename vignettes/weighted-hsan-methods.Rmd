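---
title: "Weighted hospital service area networks: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted hospital service area networks: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Population variation in hospitalization rates — for example rates of
*preventable* (ambulatory-care-sensitive) hospitalization, a standard
primary-care performance indicator — is often attributed to discrete
geographic catchments: each small area is assigned to the hospital receiving
the plurality of its admissions, and the areas per hospital form hospital
service areas (HSAs). Patient loyalty to the assigned hospital is typically
only 50–80 percent, so a discrete partition throws away a substantial share
of the information in observed patient flows, attenuates the apparent
between-hospital variation, and leaves hospitals that never win a plurality
invisible to the analysis.

`hsanet` implements the alternative: keep the full flow distribution. Every
person is attached *fractionally* to all hospitals used by residents of
their area, with weights proportional to the area's admission shares (a
*weighted hospital service area network*), and between-hospital variation is
estimated with a multiple-membership multilevel Poisson model.

# The model

For person $i$ with preventable-admission count $Y_i$, follow-up $t_i$,
person-level covariates $x_i$ and area flow weights $w_{ij}$ over hospitals
$j = 1,\dots,J$:

$$Y_i \sim \text{Poisson}(\mu_i), \qquad
\log \mu_i = \log t_i + x_i'\beta
  + \textstyle\sum_q \beta_q \big(\sum_j w_{ij} x_{qj}\big)
  + \sum_j w_{ij} u_j, \qquad u_j \sim N(0, \sigma^2_u),$$

with $0 \le w_{ij} \le 1$ and $\sum_j w_{ij} = 1$. Hospital-level covariates
$x_{qj}$ (e.g. bed occupancy) enter as weighted network averages,
group-mean-centred and rescaled (one model unit = 10 percentage points by
default). Where every weight row is a unit vector the model collapses to the
ordinary two-level random-intercept model, so the discrete-HSA analysis is
the degenerate special case. Additional random classifications (for example
a secondary geography) can be added, each single- or multiple-membership,
giving cross-classified models. There is no person-level Gaussian residual:
counts are the lowest level of the hierarchy, and no overdispersion term is
fitted (a known limitation of the Poisson formulation; zero-inflated and
negative-binomial variants are out of scope).

Between-hospital variation is summarised as:

* $\sigma^2_u$, the random-intercept variance on the log-rate scale;
* the **median rate ratio**, $\mathrm{MRR} =
  \exp\{\sqrt{2\sigma^2_u}\,\Phi^{-1}(0.75)\}$ — the median rate increase
  when moving from one hospital network to another with a higher rate. The
  coefficient is evaluated numerically
  ($\sqrt{2}\,\Phi^{-1}(0.75) \approx 0.954$), not as a rounded constant.
  The point estimate applies the transformation to the posterior mean of
  $\sigma^2_u$; the credible interval transforms the chain per draw (the
  transformation is monotone, so interval endpoints are transformed
  quantiles);
* the **proportional change in variance**,
  $(\sigma^2_{\text{before}} - \sigma^2_{\text{after}})/\sigma^2_{\text{before}}$,
  after adding covariates;
* the **DIC**, $\bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$, where the
  plug-in deviance is evaluated at the posterior means of the *parameters*
  ($\beta$, $u$), not of the linear predictor;
* posterior hospital rankings: per-hospital posterior medians, 95 percent
  credible intervals, ranks, and a flag where the interval excludes zero.
  No multiplicity adjustment is applied to these flags.

# Catchment construction

`computeAreaWeights()` builds the area × hospital weight matrix from
episode-merged, all-cause admissions: the weight of hospital $j$ in area $a$
is the fraction of $a$'s admissions admitted to $j$. Design choices, each
configurable where a genuine alternative exists:

* **Episode merging.** Transfers between hospitals (rows sharing an episode
  identifier) are one episode of care, attributed to the *first* hospital —
  where the admission decision was made. `attributeTo = "last"` switches the
  policy.
* **Plurality ties** are broken by the lexicographically smallest hospital
  id, making `assignHsa()` deterministic and invariant to row order. (Exact
  50/50 splits occur in real systems.)
* **Areas with no admissions** yield no weight profile; their residents are
  excluded from model datasets with an explicit exclusions report, never
  silently. This mirrors the cohort-accounting style of linked-data studies.
* **No minimum admission count per area**: an area with a single admission
  has a valid (degenerate) profile. Weights from one admission are of course
  noisy; this is a property of the method, not of the implementation.
* Weights are computed from **all-cause** admissions while the outcome
  counts only flagged preventable episodes, keeping the weighting structure
  and the outcome distinct.

# The sampler

The Poisson likelihood is not conjugate for $\beta$ or $u$, so the fitter
uses adaptive Metropolis-within-Gibbs, the standard engine for
multiple-membership Poisson models in dedicated multilevel software:

* each $\beta_p$ and each $u_j$ has a univariate random-walk Metropolis
  update; per-parameter step sizes adapt in batches of 50 toward ~44 percent
  acceptance *during burn-in only* and are frozen afterwards;
* each $\sigma^2_c$ has an exact conjugate Gibbs draw,
  $\sigma^2 \mid u \sim \text{IG}(a + J/2,\; b + \sum_j u_j^2/2)$;
* priors: $\beta_p \sim N(0, 10^6)$ iid,
  $\sigma^2 \sim \text{IG}(0.001, 0.001)$ — the conventional diffuse
  defaults of MCMC multilevel software; both configurable via `mmPriors()`.
  With variances this weakly identified, the inverse-gamma prior's spike at
  zero makes small-$J$ posteriors right-skewed; sensitivity to the prior
  should be checked on real analyses (e.g. `mmPriors(igShape = 0.5,
  igRate = 0.01)` as an alternative);
* default chain settings are 5,000 burn-in and 20,000 stored samples
  (`mcmcControl()`); the package's own tests scale down to 1,000/4,000,
  which the diagnostics show is adequate at the test problem sizes;
* weight matrices are stored sparse; updating $u_j$ touches only the persons
  with nonzero weight on hospital $j$, and $\eta$ and $e^\eta$ are
  maintained incrementally, so per-iteration cost is linear in the number of
  nonzero weights. The update loop is compiled (Rcpp), drawing from R's RNG
  so `set.seed()` governs the whole fit.

Numerical and initialization choices that matter:

* **Initialization.** $u$ starts at crude smoothed per-unit log-rate
  deviations and $\sigma^2$ at their variance. Starting at $u = 0$ is not
  innocuous: the first Gibbs draw of $\sigma^2$ then collapses to
  $\approx b/(a + J/2)$, prior-locking all $u_j$ near zero — a
  quasi-absorbing region of the Gibbs/Metropolis chain ("funnel" behaviour).
* **Determinism.** One seeded RNG stream drives the whole chain. Per-person
  RNG substreams were considered and rejected: they would complicate the
  sampler without changing the posterior, and exchangeability under person
  permutation is instead verified statistically in the test suite.
* The deviance trace stores $-2\sum_i [Y_i \log \mu_i - \mu_i - \log Y_i!]$
  at every kept state and is exactly recomputable from the stored
  parameters.
* Acceptance rates outside $[0.1, 0.8]$ after burn-in produce a diagnostics
  warning, not a failure; effective sample sizes and Geweke $z$ scores come
  from `coda`, and degenerate (constant) chains are flagged with ESS 0.

# The synthetic generator

Real linked admission cohorts are confidential, so `generateSystem()`
produces systems with known ground truth. The generator is a *gravity flow
model*: hospitals (with log-normal sizes) and areas are placed uniformly on
the unit square, and the probability a resident of area $a$ is admitted to
hospital $j$ is $p_{aj} \propto s_j \exp(-d_{aj}/\phi)$. A gravity model is
the simplest mechanism producing the observed spectrum of patient loyalty
(areas dominated by one hospital through areas splitting across many); real
flow weighting is empirical, so any generator matching the loyalty profile
is admissible.

Default parameters are chosen once to emulate the statistical shape of a
large population-based linked admission cohort, scaled to desk size (60 areas, 15 hospitals,
~6,000 persons, scaled down from 593 areas / 79 hospitals / ~267,000
persons so a full closed loop runs in minutes):

| parameter | default | rationale |
|---|---|---|
| `flowConcentration` ($\phi$) | 0.055 | calibrated once so mean top-1 hospital share ≈ 67% (observed band 60–75; second share lands ~19%, band 10–25) |
| `admissionRate` | 0.27 /person-year | ~1 all-cause admission per person over mean follow-up |
| `preventableRate` | 0.027 /person-year | ~0.10 preventable admissions per person over follow-up; the baseline log-rate $\beta_0$ is calibrated numerically per dataset to hit this marginal rate |
| `followupRange` | 1.4–6.0 y (uniform) | mean 3.7 years of follow-up |
| `sigma2U` | 0.13 | reference between-hospital variance on the log-rate scale |
| `beta` | age 0.25, sex −0.1, health 0.35 | plausible person-level gradients; three synthetic covariates stand in for a fuller survey battery |

Preventable outcomes $Y_i$ are drawn from the multiple-membership Poisson
model at the *true* flow probabilities and also emitted as flagged admission
rows, so the outcome can be re-counted from the admission table exactly.
The optional secondary geography groups areas by a coarse spatial grid
(areas are nested in these units — a simplification; real secondary
boundaries can cut across areas) with its own variance `sigma2Sla`.

What the generator does *not* emulate: real geography and road-network
travel, private/public hospital sorting, overdispersion beyond the Poisson,
informative censoring, and correlation between covariates and flows. Tests
passing on this generator therefore demonstrate the *statistical machinery*
(weight construction, sampler correctness, variance attribution), not
robustness to all features of real admission data.

# What the closed loop shows

At the default conditions the package's test suite verifies, among others:

* hand-checked toy systems for weights, plurality assignment (including the
  tie-break), market share indices and catchment summaries;
* exact conjugate behaviour of the $\sigma^2$ Gibbs step against the
  closed-form inverse-gamma conditional (Kolmogorov–Smirnov);
* agreement of the multiple-membership sampler with an independently coded
  two-level sampler (JAGS) when every weight row is a unit vector;
* parameter recovery: across 20 replicates at the default conditions, the
  95% credible interval covers the generating $\sigma^2_u = 0.13$ in ≥17
  replicates with small mean bias;
* attenuation: clustering on discrete HSAs yields a smaller fitted
  between-hospital variance than the weighted network in ≥8 of 10
  replicates — the qualitative headline of the weighted-network approach.

One known identification limit: with no true hospital effects
($\sigma^2_u = 0$) and only ~2,000 persons at the default event rate
(~200 events spread over 15 hospitals, further diluted by fractional
weights), the $\sigma^2$ posterior cannot concentrate below ~0.05–0.5; the
package's sampler agrees with the independent JAGS oracle on such data, so
this is a property of the design size, not of the implementation. Null
variance components are well separated from zero only when the data carry
tens of events per hospital *after* weight dilution.

# Problem sizes and runtime

Test and example fits use 1,000 burn-in / 4,000 stored samples at ~6,000
persons and 15 hospitals (a few seconds per fit); replicate studies (20
recovery replicates, 10 attenuation pairs) complete in a few minutes. Full
analyses should use the default 5,000 / 20,000 chains and check the
diagnostics (`mmDiagnostics()`, `tracePlot()`).
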
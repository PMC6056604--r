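# hsanet — weighted hospital service area networks and multiple-membership multilevel models

Health-services researchers and policy makers attribute population variation
in hospitalization rates — e.g. rates of *preventable*
(ambulatory-care-sensitive) hospitalization — to hospitals by assigning each
small area to the hospital receiving the plurality of its admissions
(hospital service areas, HSAs). Patient loyalty to the assigned hospital is
typically only 50–80%, so the discrete partition discards most of the
observed flow structure, attenuates between-hospital variance, and hides
hospitals that never win a plurality.

`hsanet` keeps the flows. Every person is attached fractionally to *all*
hospitals used by residents of their area, with weights proportional to the
area's admission shares (a **weighted hospital service area network**), and
between-hospital variation is estimated with a **multiple-membership
multilevel Poisson model** fitted by MCMC:

```
Y_i ~ Poisson(mu_i)
log mu_i = log t_i + x_i' beta + sum_q beta_q (sum_j w_ij x_qj) + sum_j w_ij u_j
u_j ~ N(0, sigma2_u),   0 <= w_ij <= 1,   sum_j w_ij = 1
```

with follow-up offset `t_i`, person covariates `x_i`, weighted hospital
covariates (e.g. bed occupancy, group-mean-centred, one unit = 10
percentage points), and hospital random effects `u_j`. Unit-vector weight
rows recover the ordinary two-level model, so the discrete-HSA analysis is
the degenerate special case. Variation is summarised as `sigma2_u`, the
Larsen–Merlo **median rate ratio** `MRR = exp(sqrt(2 sigma2) * qnorm(0.75))`,
the **proportional change in variance** after adding covariates, the **DIC**,
and posterior **hospital rankings** with 95% credible intervals.

The package covers the full workflow: episode merging and flow-weight /
HSA construction from admission records (`mergeEpisodes`,
`computeAreaWeights`, `assignHsa`, `personWeightMatrix`,
`catchmentSummary`), the MCMC fitter for single-membership,
multiple-membership and cross-classified Poisson models (`buildMmDataset`,
`fitMmPoisson`, `mmDiagnostics`), posterior metrics (`mrr`, `pcv`, `dic`,
`rankHospitals`, `compareRankings`), a gravity-model synthetic-flow
generator with known ground truth (`simConfig`, `generateSystem`,
`loyaltyProfile`), CSV/JSON/YAML I/O, and a one-call pipeline
(`runPipeline`). A thin command-line front end lives in
`inst/cli/hsanet.R` (subcommands `simulate`, `build-catchments`, `fit`,
`report`, `run-all`).

See the methods vignette (`vignettes/weighted-hsan-methods.Rmd`) for the
model, sampler, generator calibration and design decisions.

## Worked example

Simulate a desk-scale system (60 areas, 15 hospitals, ~6,000 persons,
true `sigma2_u = 0.13`), build catchments, fit the weighted-network and
discrete-HSA models, and compare:

```r
library(hsanet)
sys <- generateSystem(simConfig(), seed = 1)
loyaltyProfile(sys$admissions)
#> LoyaltyProfile over 60 areas (% of admissions):
#>        mean  q25  q75  min  max
#> share1 63.7 47.9 78.8 27.3 97.4
#> share2 20.6 11.1 30.6  1.3 41.8
#> share3  9.2  4.6 12.9  0.0 23.7

res <- runPipeline(sys$admissions, sys$persons, sys$hospitals,
                   hospitalCovariates = "occupancy_pct",
                   control = mcmcControl(burnin = 1000, samples = 4000),
                   seed = 1)
#> episodes: 6644 admission rows -> 6644 episodes
#> catchments: 60 areas, 15 hospitals, 14 non-empty HSAs
#> fitting multiple-membership model: 5962 persons, 15 hospitals
#> fitting HSA-clustered model: 14 HSAs

round(res$report$variance, 3)   # posterior mean and SE of sigma2_u
#>  mean    se
#> 0.268 0.169
round(res$report$mrr, 3)        # median rate ratio with 95% credible interval
#> estimate    lower    upper
#>    1.638    1.300    2.219
round(res$report$comparison$variances, 3)
#>  varianceMm varianceRef       ratio       mrrMm      mrrRef
#>       0.268       0.133       2.018       1.638       1.415
res$report$comparison$rankings$onlyInFirst
#> [1] "H13"
```

Reading: each area's most common hospital takes ~64% of its admissions, in
line with the loyalty the generator is calibrated to. The weighted-network
model attributes about twice the residual between-hospital variance
(`ratio = 2.018`) of the discrete-HSA model — the discrete partition blends
hospitals within catchments and attenuates their differences — and a person
moving to a higher-rate network faces a median 64% rate increase
(`MRR = 1.638`; this seed's realised variance sits above the generating
0.13, which the wide 95% interval reflects). Hospital H13 never wins a
plurality, so it is ranked only by the weighted-network model: exactly the
kind of facility a discrete-HSA analysis cannot see. `res$report$ranking`
holds the per-hospital posterior medians, intervals, ranks and flags
(caterpillar plot via `caterpillarPlot()`).

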
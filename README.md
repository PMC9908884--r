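# calfnet

Social proximity networks for group-housed dairy calves, from raw
indoor-positioning streams to statistical inference. The package is aimed
at behavioural ecologists and precision-livestock researchers who track
calves (or comparable penned animals) with high-frequency location sensors
and want the standard association-network analysis chain as tested,
reusable code.

## What it computes

Positions sampled at 1 Hz in a 6 m × 10 m pen are cleaned (move-in day,
human-visit intervals and out-of-pen fixes censored), smoothed with a 10-s
moving average, and converted to dyadic states over consecutive 3-min
windows: a pair of calves is associated in a window when both are
sufficiently observed and at least 90% of their co-timestamped fixes are
within 1 m. Windows aggregate into 4-day periods, and each dyad gets the
simple-ratio association index

    E_AB = X / (X + Y_AB + Y_A + Y_B)

where `X` counts windows together, `Y_AB` both seen but apart, and
`Y_A`/`Y_B` only one seen — the missing-data-aware fraction of sampling
units spent in association, with standard error `SE = a * sqrt((1 - a)/x)`.

On the resulting weighted networks the package provides:

* **node measures** per animal-period: strength (weighted degree), total
  social time (3 min × associated windows), eigenvector centrality,
  closeness on reciprocal-weight shortest paths, and the CV of a calf's
  association indices;
* **network stability**: Mantel correlations between period matrices with
  QAP node-permutation nulls, summarised by period lag;
* **social differentiation**: the CV of dyadic indices against a
  data-stream permutation null (swaps of individuals between within-window
  proximity groups, preserving all marginals), with an optional
  sampling-error-corrected estimate;
* **dyadic assortment**: log edge weight on age difference, health
  difference and familiarity with cohort and multiple-membership node
  random effects, fitted by an in-package Gibbs sampler;
* **node-level mixed models**: each sociality measure on age, weaning
  stage (non-weaned / step-down / weaned, from a 10 L/day milk schedule
  stepping down 400 ml/day from day 36 to zero at day 60) and health
  category (Wisconsin-style scores: 0–2 healthy, 3–4 moderate, ≥5 sick),
  with calf and period random intercepts and Benjamini–Hochberg correction;
* a **synthetic-data generator** that plants known social structure
  (familiarity-driven partner preference, sickness and weaning effects,
  sensor dropout, visit windows) so the whole chain is testable without
  proprietary sensor data.

## Worked example

The `analysis/` scripts run the whole chain on two synthetic cohorts of 16
calves (9 monitored days, one censored; positions at one fix per 20 s —
counts are per 3-min window, so the rate is a free parameter):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_preprocess.R
Rscript analysis/03_networks.R
Rscript analysis/04_node_metrics.R
Rscript analysis/05_stability_differentiation.R
Rscript analysis/06_assortment.R
Rscript analysis/07_node_models.R
```

Selected output from a run with the default seed:

```
C1: 16 calves, 578725 raw fixes, 48 health assessments (1 sick), 18 visit events
C1: removed 64247 of 578725 fixes (11.10%)          # the censored move-in day
C1: 2 periods x 120 dyads; mean index 0.0190, 0 dyads never associated
C1 period 1 differentiation: CV = 2.698 (corrected 2.694), p = 0.001996
C1 stability: 100.0% of 1 period pairs significant; mean sig. r = 0.9935
         term     mean  lower95   upper95     pMCMC
    intercept -5.30834 -5.71175 -5.066881 0.0008333
     age_diff -0.01263 -0.02007 -0.004155 0.0016667
  health_diff  0.03432 -0.03354  0.103805 0.3300000
  familiarity  0.10862  0.10404  0.113127 0.0008333
```

Reading this: the planted preferred-partner structure makes associations
far more heterogeneous than uniform mixing (differentiation CV ≈ 2.7,
permutation p at its add-one floor of 1/501), keeps the two period
networks strongly correlated, and is recovered by the assortment model as
a positive familiarity effect (+0.109 per familiarity day on the log
association index, 95% CI [0.104, 0.113]) — familiar pairs associate more,
as planted. Stage tables (dyad counts, adjacency matrices, GraphML
networks, node metrics, permutation results, model fits) are written under
`results/analysis/`.

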
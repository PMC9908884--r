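---
title: "Methods: proximity networks for group-housed calves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proximity networks for group-housed calves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(calfnet)
```

calfnet implements the full analysis chain for social proximity networks of
group-housed dairy calves tracked by an indoor positioning system: raw 1 Hz
pen coordinates in, permutation and mixed-model inference out. This
vignette is the package's account of the methods: the models, the
conventions chosen where a convention was needed, and what the synthetic
data generator does and does not emulate.

## From positions to networks

**Cleaning.** `clean_positions()` removes, in order, (i) all fixes from the
first monitored day (habituation after the move into the pen), (ii) fixes
inside censoring intervals (human visits, sensor swaps), and (iii) fixes
outside the pen rectangle (localisation error). The first "day" is the
first 86,400 s from the configured move-in time, not a calendar-midnight
day — deterministic and timezone-free. Every removed row is accounted for
in a per-reason censor log. Cleaning is idempotent.

**Smoothing.** `smooth_positions()` replaces each coordinate by the mean of
the available fixes in a 10-s window. The window is trailing (causal) by
default, with the divisor equal to the number of fixes actually present;
seconds without a raw fix get no smoothed fix — gaps are never imputed
(the association index is the missing-data mechanism, not interpolation).
A centered window is available via `align = "centered"`. Whether the
window should be trailing or centered, and how gaps interact with it, are
conventions: the method description only fixes "simple moving average,
10 s".

**Windows and dyadic states.** Each 4-day aggregation period is tiled into
consecutive non-overlapping 3-min windows; one associated window is one
proximity interaction. This window convention resolves an ambiguity — a
"proximity interaction below a threshold distance for a minimum duration"
could count bouts, windows or seconds — in the way that keeps the X/Y
bookkeeping well-defined and conserves totals (window counts convert to
social time at exactly 3 min each). Per dyad and window, an animal is
*seen* when at least `seen_frac = 0.5` of its scheduled fixes are present;
a seen pair is *close* when at least `prox_frac = 0.9` of co-timestamped
fix pairs are within `d_m = 1` m. The two fractions tolerate sampling
jitter and dropout; both are configurable, and the threshold grid
(0.8/1.0/1.2 m × 2/3/4 min) can be re-run for sensitivity.

**Association index.** With X = windows both seen and close, Y_AB = both
seen but apart, Y_A / Y_B = only one seen,

$$E_{AB} = \frac{X}{X + Y_{AB} + Y_A + Y_B},$$

the simple-ratio index over windows in which at least one member was
observed. Dyads never observed in a period (zero denominator) get weight 0
plus an exclusion flag, so matrices stay dense while flagged dyads can be
excluded from dispersion statistics. The sampling standard error of an
index is $SE = \alpha\sqrt{(1-\alpha)/x}$ with $x$ the associated-window
count; it is undefined (NA) for dyads with $x = 0$.

## Node measures

Five measures per animal-period (`node_metrics()`):

* **strength** — row sum of association indices;
* **social time** — 3 min × the animal's associated windows (computed from
  raw counts, not indices);
* **eigenvector centrality** — principal eigenvector of the association
  matrix, non-negative by Perron–Frobenius, max-normalised (the common
  igraph convention);
* **closeness** — shortest paths on edge lengths $1/E_{ij}$ (stronger
  association = shorter distance; the transform is a convention, reciprocal
  weight being the standard choice for association indices), with
  Wasserman–Faust component scaling
  $\frac{r_i}{n-1}\cdot\frac{r_i}{\sum_j d(i,j)}$ so that disconnected
  periods are handled and isolates score 0;
* **CV of association** — sample SD over mean of the node's defined edge
  weights; undefined with fewer than two usable edges or a zero mean.

Weighted (not binarised) graphs are used throughout; the source analysis
does not say which it used, and binarisation is available upstream by
thresholding the matrix. Covariates attached per animal-period: age at the
period's end; weaning stage from feeder-days approximated as age − 14
(calves enter the feeder schedule at about two weeks; no per-calf weaning
dates exist, so any mapping is a convention and this one is configurable);
health category as the worst assessment inside the period (dyadic models
instead use the assessment nearest the period end).

## Permutation inference

**Network stability.** `mantel_qap()` correlates the upper triangles of two
period matrices and builds its null by jointly permuting node labels of the
second matrix (QAP), n = 10,000 by default, one-sided (≥). All p-values use
the add-one convention $(1+b)/(1+n)$, which can never return 0.
`stability_summary()` runs all period pairs and reports the share of
significant correlations and the mean ± sd of significant r, grouped by
period lag.

**Social differentiation.** The statistic is the CV across dyads of the
association indices — do calves associate more heterogeneously than if
they mixed uniformly? A node-label permutation of the observed network
cannot serve as the null here: it permutes rows and columns jointly, which
leaves the multiset of edge weights, hence the CV, exactly invariant. The
implemented null is therefore the field-standard data-stream permutation:
within each 3-min window, the seen animals are partitioned into proximity
groups (connected components of the pairwise-close graph, singletons
included), and the chain repeatedly swaps two individuals between two
groups of the same window. Each swap preserves every window's group sizes
and every animal's windows-seen count exactly, and the chain kernel is
symmetric, so its stationary distribution is uniform over group
assignments with those marginals. Per-dyad simple-ratio denominators are
invariant under the swaps, so only the numerators are updated
incrementally. Defaults: burn-in of 10 chain sweeps, one sweep (one swap
per swappable window on average) between successive null samples. A
parametric alternative (`null = "binomial"`: each dyad's X redrawn as
Binomial(denominator, pooled association rate)) is provided; a
shuffle of edge weights among dyads would be just as degenerate as the
node permutation for a CV statistic, which is why the alternative null is
parametric. An SE-corrected differentiation estimate,
$\sqrt{\max(0,\ \mathrm{var}(\alpha) - \overline{SE^2})}/\bar\alpha$, is
reported alongside the raw CV.

## Model layers

**Dyadic assortment.** `fit_dyadic_assortment()` is a Gibbs sampler for

$$\log E_{ij} = \beta_0 + \beta_1\,|\Delta\mathrm{age}|
 + \beta_2\,|\Delta\mathrm{health}| + \beta_3\,\mathrm{familiarity}
 + u_{\mathrm{cohort}} + v_i + v_j + \varepsilon,$$

with a single node-effect vector $v$ entering each row once per member —
the multiple-membership structure that absorbs the non-independence of
dyads sharing an individual. Design weight is 1 per member, matching the
usual convention for symmetric dyadic effects. Priors: diffuse normal on
coefficients, inverse-gamma (0.001, 0.001) on all variances; chain
defaults 60,000 iterations, 10,000 burn-in, thinning 25 (the source
analysis reports none of these, so they are package conventions;
reduced-length chains are used in tests). pMCMC is
$2\min(P(\beta>0), P(\beta<0))$. Zero edge weights cannot be
log-transformed; the default drops those dyad-periods, and
`zero_rule = "offset"` (log(E + c), c = half the smallest positive weight)
is the alternative. With a single cohort the cohort variance is not
identifiable and is fixed at zero with a message. Effective sizes are
estimated from lag-1 autocorrelation; a fit with any coefficient ESS
below 100 is flagged, not rejected. Periods are pooled into one model by
default (fitting per period is a matter of subsetting the dyad table).

**Node-level LMMs.** `fit_node_lmms()` fits, for each of the five
measures, `metric ~ age + weaning_stage + health_category +
(1 | animal) + (1 | cohort:period)` (plus `(1 | cohort)` when more than one
cohort is present) by REML via lme4 — supporting statistics, delegated to
the established mixed-model routine. Age is entered in days, uncentered,
so coefficients are per-day. p-values are Wald t with residual degrees of
freedom; Benjamini–Hochberg correction is applied per coefficient across
the five metric models. Factors observed at a single level are dropped
with a warning rather than producing rank-deficient fits. Note the BH
adjustment is not idempotent (re-adjusting adjusted values inflates them);
the meaningful invariants are monotonicity and order preservation.

## The synthetic generator

No deposited positional data exists for this study design, so
`cohort_spec()` / `simulate_trajectories()` generate what every stage
needs: 15–16 calves in a 6 m × 10 m pen with a 1.5 m × 3 m feeder zone,
1 Hz sampling (reducible — all counts are per window, so the rate is a free
parameter), entry ages 14–60 days, pair-structured familiarity (calves are
pair-reared before grouping; each pair shares 14–51 contact days, other
dyads 0), a 10 L/day milk allowance stepping down 400 ml/day from feeder
day 36 to zero at day 60, twice-weekly health scoring with episodic
respiratory illness (component scores 0–3; totals 0–2 healthy, 3–4
moderate, ≥5 sick), 5% i.i.d. fix dropout and two daily 15-min visit
windows logged to the events file.

Movement is a bounded correlated random walk: each calf's velocity mixes
its previous velocity (persistence 0.5), saturating attraction toward
partners — weight increasing in familiarity days, damped by
`exp(-|Δage|/scale)`, multiplied down on sick days and up on
step-down/weaned days — attraction toward the feeder proportional to the
remaining milk allowance, and Gaussian noise; walls reflect. The pairwise
pull is capped at half the current separation so two mutually attracted
calves meet rather than overshoot. This is deliberately not ethology: the
generator's only job is to produce tunable association structure with
known truth. It does not emulate lying/standing activity states, realistic
diurnal rhythms, localisation error correlated with pen geometry, or
feeder queueing.

**Calibration conditions.** The data-stream null assumes windows are
exchangeable, which requires the movement to decorrelate between windows.
Calibration and power simulations therefore use a scan design — one fix
per 3-min window with step SD large relative to the pen (type-I runs) or
tightly cohesive planted pairs (power runs) — at small problem sizes: 6
calves, 48–96 windows, 200 null and 100 planted replicates with 500
permutations each, and 50 replicates of the dyadic sampler at reduced
chain length on 12 nodes × 6 periods. These sizes keep the statistical
checks to a few minutes while leaving Monte-Carlo error well inside the
asserted bounds. Slow-mixing movement (persistent positions across
windows) violates exchangeability and inflates the differentiation test's
false-positive rate on real data smoothed over short windows; this is a
property of the test, not of the implementation, and is the reason
window length is kept at 3 min rather than shortened.

What passing tests show, and what they do not: the planted-structure
recoveries demonstrate the chain from trajectories to inference is
internally consistent and correctly calibrated under the generator's
assumptions; they do not validate the behavioural realism of any
particular threshold choice on real pens, which is why the sensitivity
grid is part of the standard outputs.

## Numerical notes

* Association matrices are dense, symmetric, zero-diagonal; node order is
  sorted animal id everywhere.
* Trailing partial periods are dropped (only full 4-day periods are
  aggregated); 76 usable days give 19 periods.
* The eigenvector is clipped at 0 to remove floating-point noise on the
  Perron vector; an all-zero matrix returns all-zero centralities with a
  flag.
* Degenerate permutation inputs (constant matrices, streams with no
  swappable window) error or warn explicitly rather than returning
  misleading p-values.
* All randomness is seeded; identical seeds and configurations reproduce
  byte-identical outputs, including the MCMC draws.
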
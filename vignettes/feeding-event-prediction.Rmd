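---
title: "Predicting large-carnivore feeding events from GPS location clusters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting large-carnivore feeding events from GPS location clusters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(killcluster)
```

## The problem

GPS-collared large carnivores (the motivating system is cougar, *Puma
concolor*) spend long periods handling prey, so their feeding sites show
up as spatio-temporal clusters of GPS fixes. Field crews ground-truth a
sample of clusters for prey remains, a logistic model is trained on the
visited sample, and the model is applied to all clusters to estimate how
many are feeding events. Two things make this harder than it sounds:

1. **Covariates beyond geometry help.** Collars carry a dual-axis
   activity sensor (counts 0–255 accumulated per 288-second block).
   Feeding produces relatively more forward–backward (x-axis) motion,
   travel more side-to-side (y-axis) motion, so windowed activity
   summaries discriminate feeding from day-bed resting even when the
   spatial pattern looks similar.
2. **Ground-truthing is imperfect.** Observers miss carcasses more
   often when the visit is long-delayed (scavenging, decay), when not
   all fixes had been downloaded via satellite before the search (a
   mis-focused search area), and when prey is small. A model trained on
   observed presence/absence therefore estimates
   `P(feeding AND detected)`, and naïve application deflates the
   predicted event count.

The package implements the full workflow — cluster detection, covariate
derivation, AICc model selection, ROC evaluation, detection-corrected
event counts, double-observer concordance — plus a synthetic biologging
simulator with known ground truth so every stage can be validated
without field data.

## Cluster detection

Fixes arrive on a 7-per-day schedule (02:00, 05:00, 08:00, 12:00,
16:00, 19:00, 21:00 local clock time; every 3 h at night, every 4 h by
day). After dropping the first 7 days after each capture (handling
aftereffects) and any user-supplied exclusion zones, two cluster types
are formed per animal, scanning chronologically:

* **S1** — seeded by the earliest unassigned pair of fixes within 200 m
  and 4 days of each other; unassigned fixes join while they lie within
  200 m of the running centroid, within 4 days of the member time span,
  and the recomputed centroid keeps every member inside the radius.
  The last condition is our disambiguation of the radius rule: checking
  only the candidate against the current centroid lets earlier members
  drift outside the final 200 m circle, which would break the cluster's
  defining property. With it, the invariant "every member within
  `radius_m` of the final centroid" holds by construction.
* **S2** — two consecutive acquired fixes 200–500 m apart with exactly
  one scheduled fix missing between them: a likely feeding site whose
  middle fix the collar failed to record. Consecutiveness makes the
  missing-slot condition well defined.

A fix belongs to at most one cluster; seeding order (earliest pair
first) makes assignment deterministic, and memberships are invariant to
translating coordinates or shifting all timestamps. The greedy,
exclusive assignment is the main algorithmic interpretation in the
package; alternatives (fix re-use, post-hoc merging of overlapping
clusters) exist in this literature, and the choice is isolated in
`detect_clusters()`.

## Covariates

For each cluster (`cluster_covariates()`):

| Covariate | Definition | Units / range |
|---|---|---|
| `POSCOUNT` | member fixes | count ≥ 2 |
| `TIMEBIN24` | span > 24 h | 0/1 |
| `NIGHTPROP` | members in night slots (21:00, 02:00, 05:00) | [0, 1] |
| `CENTER` | mean member–centroid distance | m |
| `ACCX`, `ACCY` | two-stage windowed activity means | counts 0–255 |
| `ACCXYDIFF` | two-stage mean of per-record (ax − ay) | counts |
| `FIXRATE` | acquisition success, ±48 h window per member | [0, 1] |
| `FIELDPROP` | members downloaded before the visit | [0, 1] |
| `SEARCH_LAG` | cluster start → visit | days |
| `SEAS` | SUM (Jun 1–Sep 30), FAL (Oct 1–Jan 15), WIN (Jan 16–May 31) | factor |

Activity is aggregated in two stages: records starting within ±1.5 h of
each member fix are averaged per fix (matching the sensor stream to the
GPS acquisition rate), then per-fix means are averaged over members
(matching time on site). Because the same weights apply to both axes,
`ACCXYDIFF` equals `ACCX − ACCY` exactly — asserted in the tests. The
window is interpreted as a half-width (±1.5 h); the total-width reading
would halve the effective window, and results should not be sensitive
to this at a 7-fix/day schedule, but the parameter
(`activity_halfwindow_h`) is exposed rather than assumed.

`FIXRATE` uses a 96-h window centered on each member fix, clipped to
the deployment interval; a centered window is symmetric and behaves at
deployment edges. Night slots default to the three scheduled times in
the 21:00–05:59 block; both are `covariate_params()` fields because
neither anchoring nor the night set is canonical.

## The feeding model and selection

The response is observed presence/absence of prey remains at visited
clusters, modelled with a binomial GLM (logit link) fit by IRLS
(`fit_logistic()`; convergence `epsilon 1e-10`, max 100 iterations;
variance from the observed information). Terms follow a small DSL:
natural-log transforms, raw quadratics, products of two present parent
terms, and a summer dummy. The flagship specification
(`top_model_spec()`, 15 parameters) is

```
FEEDING ~ CENTER + CENTER^2 + log(POSCOUNT) + NIGHTPROP
        + log(POSCOUNT):NIGHTPROP + ACCX + ACCX^2 + ACCXYDIFF
        + ACCX:CENTER + ACCXYDIFF:log(POSCOUNT)
        + SEARCH_LAG + FIELDPROP + FIELDPROP^2 + SUM
```

`component_candidate_set()` expands its four component groups
(spatio-temporal, activity, ground-truthing error, season) into all 16
on/off combinations, with the two cross-group interactions present only
when both parent groups are. Selection uses the small-sample AICc
(`−2ℓ + 2k + 2k(k+1)/(n−k−1)`) and Akaike weights; all candidates are
fitted to one common observation set (rows missing any covariate used
by any candidate are dropped listwise first), since information
criteria are only comparable on identical data. The null model is
generated and reported alongside the rest.

Numerical notes: no covariate standardization (coefficients are
reported on natural scales); collinear term pairs such as `FIELDPROP` +
`FIELDPROP^2` on a narrow observed range legitimately produce large
offsetting coefficients, so the separation guard errors only when the
likelihood is near-saturated or the linear predictor perfectly splits
the classes. Rank deficiency and non-convergence are hard errors naming
the offending columns.

## Evaluation and the balanced cut-off

`auc()` is the Mann–Whitney probability computed from midranks;
`choose_cutoff()` scans midpoints between adjacent distinct scores plus
the extremes and returns the threshold minimizing
|sensitivity − specificity| under the rule *predict positive when score
≥ cutoff*, breaking ties toward the smaller cutoff (the inequality
direction and tie-break are conventions the source material leaves
open). `kfold_auc()` uses seeded stratified folds — with ~20 folds and a
minority class of a few hundred, simple random folds can lack a class,
which would leave fold AUCs undefined — refits the model on each
remainder, and averages per-fold AUCs without pooling.

## Detection-corrected event counts

`SEARCH_LAG` and `FIELDPROP` describe observer circumstances, not
animal behaviour. Applying the fitted model to *all* clusters
(`predict_probabilities()`), the corrected mode therefore overwrites
them with ideal values (lag 0 days, download proportion 1.0); the
uncorrected mode uses the ground-truthing means instead (configurable;
29.1 days and 0.913 by default, the means reported for the motivating
dataset). `count_events()` enumerates clusters at or above the cut-off.

A thresholded count has no closed-form standard error, so uncertainty
is propagated by a parametric bootstrap over the coefficient sampling
distribution — draws from MVN(β, vcov), count recomputed per draw —
reporting a percentile interval (primary) and a symmetric Wald-style
interval (1.96 × bootstrap SD). The percentile form is primary because
count uncertainty is visibly asymmetric near the cut-off.

**A known limitation**, demonstrated by the simulator experiments in
`tests/testthat/test-acceptance.R`: with a balanced cut-off the count
overshoots the true number of feeding clusters by roughly
`(1 − specificity) × (N − P)` (false positives on the non-feeding
majority), and correcting nuisance covariates to their ideal values
inflates false positives further by extrapolating every cluster's score
along the fitted lag slope. When ground-truthing error is mild (a ~9%
corrected-vs-uncorrected decline, matching the motivating study), that
classification bias is the same size as the detection recovery, so the
corrected count is *not* reliably closer to truth than the uncorrected
count replicate-by-replicate (~60% of simulator replicates), even
though the correction's direction is always right and the fitted
`SEARCH_LAG` sign recovers the detection decline in every replicate.
Users who need calibrated abundance rather than a classification count
should sum predicted probabilities instead of thresholding; the
thresholded count is retained because it is the field's convention.

## Double-observer concordance

`concordance_summary()` compares an initial (near-real-time, short-lag)
visit against the standard delayed visit on the same clusters:
discordance rate, direction of each miss (attributed to the observer
recording absence), prey composition of the double-visited set (large
prey at the 23.7-kg threshold / small ungulate / non-ungulate / none),
and the size breakdown of the discordant cases.

## The simulator

`simulate_dataset()` generates the whole data stack under a single
seed, with truth returned for recovery tests. Movement alternates three
states: travel (random-walk steps of 500–2000 m per slot gap), day-bed
rest (a day is a rest day with probability 0.2; beds persist across
consecutive rest days with probability 0.3; occasional night rests at
the bed with probability 0.25), and kill handling (kills arrive as a
Poisson process, 0.8/week per animal, suppressed during handling; night
positions ~ Normal(kill site, 30 m), day positions at a bed offset
50–150 m from the carcass; 10% of handling slots are forays away).
Prey mass is a small/large mixture (U(5,20) kg with weight 0.45,
else U(40,80) kg); handling lasts `1 + mass/30` days, capped at 8.
Activity blocks (288 s) are emitted per state with feeding x-dominant
(means 130/60), travel y-dominant (100/140) and resting low (20/15),
truncated to [0,255]. Fixes are dropped independently (acquisition
0.81) and flagged downloaded with probability 0.92. Visits cover 80% of
detected clusters with uniform 2–60-day lags; a truly-feeding cluster
is recorded as feeding with probability
`invlogit(0.5 − 0.06·lag + 1.5·fieldprop + 0.5·log(mass))` — about 95%
under ideal short-lag conditions, declining with delay and small prey —
and observers never invent carcasses.

These defaults were chosen once, for realism: a kill every ~1.25 weeks
and a ~25–30% feeding share of clusters reflect cougar field studies;
acquisition and download rates mirror the motivating study; the
detection decline yields a ~9–11% corrected-vs-uncorrected gap and a
few-percent miss rate at short lags, in line with published
double-observer results. At long lags the simulated observer is
deliberately more pessimistic (detection ~0.8 at a 30-day lag) than
published double-observer experiments suggest (~3.5% discordance
overall), so that the detection-error machinery has a signal worth
correcting; simulated pairwise discordance is correspondingly higher
(~20%) than the field value. What the simulator does **not** emulate:
terrain and home-range structure, multi-predator interaction,
scavenger dynamics, seasonal prey switching, and the messy covariate
overlap of real data — simulated clusters are cleaner (AUC ≈ 0.98 vs
≈ 0.89 on real data), so passing recovery tests shows the machinery is
correct, not that real-data performance will match.

Test and acceptance problem sizes are the package's own choices: the
end-to-end recovery experiment runs 50 replicates at 15 animals × 120
days (~200 kills, ~1,500 clusters, ~200 observed feeding events per
replicate); detection-coefficient recovery uses the direct generator
(`simulate_detection_data()`) at n = 2000 × 50 replicates; oracle
comparisons run on ≤ 30-fix tracks where exhaustive replay is cheap.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_animals = 10, duration_days = 90, seed = 9)
dat <- simulate_dataset(cfg)
covs <- cluster_covariates(dat$clusters, dat$fixes, dat$activity,
                           dat$visits, cfg$schedule)
visited <- covs[!is.na(covs$FEEDING), ]

sel <- select_models(component_candidate_set(), visited)
head(sel, 3)

ev <- evaluate_model(visited, top_model_spec(), k = 20, seed = 1)
fit <- ev$model
corr <- count_events(fit, covs, ev$cutoff, mode = "corrected", seed = 2)
corr
sum(dat$truth$cluster_truth$true_feeding)   # the simulator's truth
```

The same stages run from one configuration via `run_pipeline()`, which
writes per-stage artifacts (CSV/JSON) with a config digest so a rerun
with the same file is byte-identical.

## Limitations

* The published S1/S2 cluster family delegates algorithmic details to
  earlier software; the exclusive greedy centroid rule here is a
  documented interpretation, tested against its own specification, not
  against that software.
* The balanced cut-off count correction issue described above.
* Real supplementary datasets are required to reproduce published
  coefficient tables; the package ships none and the corresponding
  acceptance test reports failure until they are supplied under
  `inst/extdata/supplementary/`.
* Astronomical (sunrise/sunset) night definitions are a configuration
  hook only; night is slot-based.
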
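# killcluster

GPS location-cluster analysis for predicting large-carnivore feeding
events.

GPS-collared predators (cougars are the motivating species) handle prey
for days, so feeding sites appear as clusters of GPS fixes close in
space and time. Field crews ground-truth a sample of clusters for prey
remains; a logistic model trained on that sample is then applied to all
clusters to estimate how many are feeding events. `killcluster`
implements the whole workflow:

* **Cluster detection** — S1 clusters (≥ 2 fixes within 200 m and 4
  days, exclusive greedy centroid agglomeration) and S2 clusters (two
  consecutive fixes 200–500 m apart bracketing one missed scheduled
  fix), after 7-day post-capture truncation.
* **Covariates** — spatio-temporal (POSCOUNT, TIMEBIN24, NIGHTPROP,
  CENTER), dual-axis activity-sensor summaries aggregated in two stages
  around each fix (ACCX, ACCY, ACCXYDIFF), and ground-truthing error
  terms (FIXRATE over a centered 96-h window, FIELDPROP, SEARCH_LAG,
  season).
* **Feeding model** — binomial GLM (logit link) over a term DSL (logs,
  quadratics, interactions, summer dummy); small-sample AICc selection
  over the 16 component-combination candidates with Akaike weights:

  AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1),  w_i = exp(−Δ_i/2) / Σ_j exp(−Δ_j/2)

* **Evaluation** — rank-based AUC, the cut-off balancing sensitivity
  and specificity, and seeded stratified k-fold (default k = 20)
  cross-validated AUC.
* **Detection-corrected counts** — the model applied to every cluster
  with the nuisance observer covariates set to ideal values
  (SEARCH_LAG = 0, FIELDPROP = 1) or to ground-truthing means, counts
  thresholded at the balanced cut-off, with parametric-bootstrap
  percentile and Wald-style intervals.
* **Double-observer concordance** — false-absence rate, direction of
  misses and prey composition for clusters visited independently twice.
* **Synthetic biologging simulator** — movement states (travel,
  day-bed, kill handling), scheduled fixes with acquisition and
  satellite-download failure, state-dependent activity emissions and an
  imperfect observer, with the ground-truth kill ledger returned for
  parameter-recovery testing.

## Worked example

```r
library(killcluster)

cfg <- sim_config(n_animals = 10, duration_days = 90, seed = 9)
dat <- simulate_dataset(cfg)
covs <- cluster_covariates(dat$clusters, dat$fixes, dat$activity,
                           dat$visits, cfg$schedule)
visited <- covs[!is.na(covs$FEEDING), ]

sel <- select_models(component_candidate_set(), visited)
head(as.data.frame(sel), 3)
#>                model k logLik  AICc  delta weight
#> 1              Acvty 4 -34.93 78.00 0.0000 0.3227
#> 2         Acvty+Seas 5 -34.08 78.36 0.3648 0.2689
#> 3 Acvty+GrndTru+Seas 8 -31.19 78.88 0.8828 0.2075

ev <- evaluate_model(visited, top_model_spec(), k = 20, seed = 1)
c(cutoff = ev$cutoff, auc = ev$auc, cv_auc = ev$cv_auc)
#> cutoff 0.356  auc 0.989  cv_auc 0.965

count_events(ev$model, covs, ev$cutoff, mode = "corrected", seed = 2)
#> <kc_prediction> mode=corrected: 77 of 373 clusters (prop 0.206,
#>   percentile CI 0.190-0.590) at cutoff 0.356
count_events(ev$model, covs, ev$cutoff, mode = "uncorrected", seed = 2,
             nuisance_means = c(SEARCH_LAG = mean(visited$SEARCH_LAG),
                                FIELDPROP = mean(visited$FIELDPROP)))
#> <kc_prediction> mode=uncorrected: 66 of 373 clusters (prop 0.177,
#>   percentile CI 0.155-0.394) at cutoff 0.356

sum(dat$truth$cluster_truth$true_feeding)   # the simulator's truth
#> [1] 75
```

Reading between the lines: at this small scale AICc prefers the
activity-only component model (49 events cannot justify 15
parameters), the balanced cut-off classifies held-out clusters with
~96% sensitivity/specificity, and setting the observer-nuisance
covariates to ideal values raises the predicted feeding count from 66
to 77 against a simulated truth of 75 — the detection correction
recovering events that delayed, partially-guided searches would miss.

At full scale a study is one call: `run_pipeline()` takes a nested
list or YAML config (simulate block or input CSV paths, cluster and
covariate parameters, model, evaluation and prediction settings) and
writes per-stage artifacts with a config digest; reruns are
byte-identical.

The methods vignette
(`vignettes/feeding-event-prediction.Rmd`) documents the model,
parameter defaults and units, the simulator's assumptions, numerical
choices, and known limitations — including why thresholded corrected
counts can overshoot at a balanced cut-off.

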
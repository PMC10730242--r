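# endotyper

Outcome-guided endotyping of subclinical carotid atherosclerosis in R.

Population cohorts with carotid ultrasound, clinical variables and
circulating biomarker panels hide distinct *endotypes* — subgroups defined
by an underlying biological signature rather than by any single clinical
cut-off. `endotyper` implements a complete, tested pipeline for
discovering, explaining and validating such endotypes, for biostatisticians
and cardiovascular epidemiologists who want the whole chain — from raw
cohort table to censoring-adjusted net reclassification improvement — in
one reproducible package. Because the motivating cohort data are not
public, the package ships a seeded synthetic cohort generator that emulates
the structure the analysis assumes, so every stage is testable end to end.

## The method

1. **Representation learning.** All continuous variables are Z-standardized
   (`Z = (x − mean)/sd`). A small feed-forward *encoder MLP*
   (input → 32 → 16 → tanh bottleneck 8 → linear head) is trained to
   predict standardized c-IMT<sub>mean-max</sub> (the average of per-segment
   carotid intima-media thickness maxima) by minibatch Adam with strong
   Gaussian input-noise augmentation and a small *code-decisiveness*
   penalty `λ·mean(1 − B²)` that pushes bottleneck codes toward saturation.
   Features unrelated to the outcome are filtered out; the saturating code
   quantizes the outcome-related manifold into discrete activation
   patterns. The embedding is the column-bound code of three seeded
   replicates.
2. **Endotype discovery.** Ward-linkage hierarchical clustering on the
   embedding; the number of clusters is the largest k whose every coarser
   partition has Tibshirani–Walther prediction strength ≥ 0.9 across
   random half-splits; clusters are relabelled so mean baseline
   c-IMT<sub>mean-max</sub> ascends from endotype 1 (mildest) to K. A
   random-outcome *null control* must report "no defined cluster"
   (max mean silhouette < 0.15).
3. **Replication.** A stacking ensemble (random forest + gradient-boosted
   trees + multinomial logistic base learners, multinomial logistic
   meta-learner on out-of-fold probabilities) maps standardized variables
   to endotypes for internal replication and new cohorts.
4. **Interpretation.** Efficiency-normalized permutation Shapley values per
   subject/variable/endotype (`Σ_j φ_j = f(x) − E_bg f`), and weighted
   correlation network analysis over the 92-biomarker panel (unsigned
   adjacency `|cor|^β`, topological overlap
   `TOM_ij = (l_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`, average-linkage tree
   cut into modules).
5. **Epidemiological value.** Linear and Cox (Efron) models of endotypes
   against baseline/progression ultrasound measures and ASCVD under three
   nested adjustment sets, Schoenfeld and VIF diagnostics, Kaplan–Meier
   curves, Harrell's C, and categorical net reclassification improvement
   with Kaplan–Meier censoring adjustment and percentile bootstrap CIs
   against SCORE2-style risk categories.

## Worked example

```r
library(endotyper)

cohort <- cohort_config(seed = 1) |> generate_cohort() |> add_ultrasound_summaries()
run    <- discover_endotypes(cohort, seed = 1)
run$selection$k
#> [1] 4
run$assignment
#> <endotype_assignment> 3121 subjects, K = 4
#> endotype
#>    1    2    3    4
#> 1275  789  541  516

fit_cox(cohort, run$assignment, covariates = character(0)) |> head(3)
#> # A tibble: 3 x 10
#>   model  outcome term      estimate    se statistic     p_value    hr ci_lo ci_hi
#> 1 model1 ascvd   endotype2    0.204 0.238     0.857 0.391        1.23 0.769  1.96
#> 2 model1 ascvd   endotype3    1.11  0.210     5.31  0.000000110  3.05 2.02   4.59
#> 3 model1 ascvd   endotype4    1.09  0.213     5.14  0.000000276  2.98 1.97   4.53
```

The four discovered endotypes order from mild to severe and recover the
planted class sizes (1277/783/502/559) to within a few percent
misassignment; the unadjusted hazard ratios versus endotype 1 bracket the
planted values (1 / 0.97 / 2.43 / 2.85), with the two severe endotypes
carrying roughly a tripled 3-year ASCVD hazard. Replication, attribution and reclassification follow
the same grammar:

```r
z   <- run$zstd                      # training standardization statistics
st  <- fit_stacking(z$data, run$assignment, seed = 1)
rs  <- score2_linear_predictor(cohort)
cmp <- risk_model_comparison(cohort$time, cohort$event, rs$lp,
                             run$assignment, horizon = 3, B = 1000, seed = 1)
cmp$c_base; cmp$c_new; tidy(cmp$nri)
```

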
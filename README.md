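# phagoscreen

Compounds that modulate how astrocytes engulf synaptic material are
candidate drugs for diseases of excessive synaptic pruning, schizophrenia
first among them. `phagoscreen` implements the full analysis path from a
high-content phagocytosis plate screen to observational repurposing
evidence, for analysts who have per-well intensities, drug-network tables,
gene lists, or patient event tables — and for anyone who wants to stress
the pipeline on synthetic data with planted ground truth.

The package covers four stages, each usable on its own:

1. **Plate screen** (`normalize_screen`, `flag_toxic_wells`,
   `plate_control_summary`): per-well red:green ratios
   (pHrodo phagocytosis / calcein viability) normalized to percent of the
   plate median over non-toxic data wells,
   `pct = 100 · (r/g) / median(r/g)`; a well is toxic when its green signal
   falls below 70% of the plate median.
2. **Hit calling** (`classify_screen`, `fit_dose_response`,
   `timecourse_auc`): at doses above 5 µM, `pct < 70` ⇒ decrease,
   `pct > 130` ⇒ increase (with `_gt20` bins when only the top dose
   crosses), toxicity taking precedence; four-parameter logistic
   dose–response fits
   `pct(c) = bottom + (top − bottom)/(1 + (c/EC₅₀)^s)` with an anchored
   mode for sparse normalized series; time-course AUC as percent of
   vehicle.
3. **Network meta-analysis & enrichment** (`phenotype_presence_matrix`,
   `cluster_drugs`, `group_gene_regression`, `enrich_terms`): drug ×
   phenotype presence matrices, Jaccard/average-linkage clustering of
   one-hot gene encodings, per-group ridge-logistic gene rankings, and
   two-list hypergeometric enrichment — fold `(b/n)/(B/N)`, tail
   `P(X ≥ b)`, Benjamini–Hochberg q.
4. **Cohort emulation** (`build_cohorts`, `fit_propensity`, `ipw_weights`,
   `match_cohorts`, `fit_cox`, `run_cohort_study`): target cohorts with a
   pediatric exposure (ages 6–18) and adult diagnosis (> 18), inpatient
   outcomes with a 3-day diagnosis lag, propensity scores, stabilized IPW
   and caliper matching, and a weighted Cox partial-likelihood fitter
   (Breslow ties, robust sandwich variance) yielding hazard ratios with
   95% intervals.

Seeded generators (`gen_screen`, `gen_timecourses`, `gen_network_tables`,
`gen_patient_table`) produce every input with known truth: planted
hit classes, planted group-discriminative genes, and survival data with a
known hazard ratio and confounding.

## Worked example

```r
library(phagoscreen)

# a 500-compound screen with 5% planted increase, 5% decrease, 2% toxic
scr  <- gen_screen(screen_sim_config(n_compounds = 500, seed = 42))
res  <- classify_screen(normalize_screen(scr$wells))
res$counts
#>      increase increase_gt20      decrease decrease_gt20     no_effect
#>            25             0            25             0           440
#>         toxic
#>            10
```

Every planted class is recovered exactly here (25/25/10 planted): at 5%
well-to-well noise the 70/130% thresholds sit many standard deviations from
the planted 50%/140% responses.

```r
# enrichment of a 28-gene target list against a 15,154-gene background,
# for a term annotated to 10 background genes with 2 target hits
enrichment_ratio(15154, 10, 28, 2)   # 108.24  (fold enrichment)
hypergeom_tail(15154, 10, 28, 2)     # 1.47e-4 (P(X >= 2))
```

```r
# cohort study on synthetic patients: true HR 0.75, confounded exposure
pt  <- gen_patient_table(cohort_sim_config(n_patients = 10000, seed = 7))
rep <- run_cohort_study(pt, "RX_ADRB2_AGONIST", "DX_SCHIZOPHRENIA",
                        max_ratio = 5)
rep$estimates$crude
#> Cox hazard ratio (crude): HR = 1.068 (95% CI 1.000-1.139)
#>   n = 3036 target / 6964 comparator, 4191 events, 3 iterations
rep$estimates$ipw
#> Cox hazard ratio (IPW, robust SE): HR = 0.794 (95% CI 0.727-0.867)
#>   n = 3036 target / 6964 comparator, 4191 events, 4 iterations
rep$estimates$matched
#> Cox hazard ratio (matched): HR = 0.843 (95% CI 0.754-0.942)
#>   n = 1000 target / 4998 comparator, 2454 events, 4 iterations
rep$balance$ipw
#>   covariate smd_before   smd_after
#> 1    asthma   1.565543 0.004181847
```

The planted confounder ("asthma": more likely to be treated, higher event
hazard) pushes the crude hazard ratio to 1.07 — above 1 even though the
true effect is protective (0.75). Weighting and matching both remove the
imbalance (standardized mean difference 1.57 → 0.004) and move the
estimate back toward the truth; at this cohort size the remaining gap is
sampling noise, as the reproduction script below shows at n = 40,000.

## Documentation

The methods vignette (`vignettes/phagoscreen-methods.Rmd`) documents the
models and assumptions, every threshold and default with its rationale,
the numerical choices (tolerances, initialization, tie handling,
degenerate-input behavior), what the synthetic generators do and do not
emulate, and known limitations.
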
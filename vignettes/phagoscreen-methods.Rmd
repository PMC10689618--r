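---
title: "Methods: from phagocytosis plate screens to repurposing evidence"
author: "phagoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from phagocytosis plate screens to repurposing evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoscreen)
```

`phagoscreen` implements, as one tested pipeline, the computation that takes
a high-content astrocyte phagocytosis screen to observational
drug-repurposing evidence: plate normalization and hit calling, drug-network
phenotype meta-analysis, two-list hypergeometric enrichment, and a
desk-scale emulation of a pediatric-exposure cohort study. Every stage can
be driven end-to-end from seeded synthetic generators with planted ground
truth, so the whole pipeline is testable without any external dataset. This
vignette records the models, the parameter choices and their rationale, the
numerical decisions, and what the synthetic experiments do and do not
establish.

## Plate normalization

Each well of a 384-well plate carries two integrated fluorescence
intensities: pHrodo red (material engulfed into acidic phagosomes — the
phagocytosis readout) and calcein AM green (live-cell mass — the viability
readout). Wells play one of four roles: `data` (one compound at one dose),
`high_control` (cells, no compound), `positive_control` (a strong reference
inhibitor), and `low_control` (no cells).

Normalization is ratio-then-percent:

* `rg_ratio = red / green` per well, controlling engulfment for live-cell
  mass;
* `pct_phagocytosis = 100 * rg_ratio / median(rg_ratio)` where the median
  runs over the plate's *non-toxic data wells*.

A data well is **toxic** when its green signal drops more than 30% below
the plate median green over data wells — strictly, `green <
0.7 * median(green)`, so a well exactly at the boundary is not toxic.

Conventions worth making explicit:

* **Toxic wells are excluded from the plate median.** Dead wells have
  unstable ratios (denominator collapses) and would drag the reference; the
  exclusion is recorded here because descriptions of percent-of-median
  normalization do not always state it. With default planting (2% toxic per
  plate) the median is insensitive to the choice.
* **Two normalization references are in circulation** for "percent of
  control": the median over data wells and the median over untreated high
  controls. The default is the data-well median (the procedural description
  of the screen software); `normalize_to = "high_control"` switches to
  percent of untreated controls. On a healthy plate the two agree closely,
  since most compounds are inactive.
* The median of an even number of wells is the mean of the two central
  values; control wells never enter the data-well median.
* A zero-green well is flagged toxic, its ratio is reported missing, and it
  is excluded from all medians (division guard consistent with "no live
  cells").
* A plate whose data wells are all toxic, or whose green median is not
  positive, is degenerate and raises an error rather than producing
  percentages against a meaningless reference.

Two invariants pin the arithmetic down: multiplying every intensity on a
plate by any positive constant changes nothing downstream
(scale invariance), and the median of `pct_phagocytosis` over non-toxic
data wells is exactly 100 on every plate (median centering).

## Hit calling

Compounds are screened in singlicate at 1.39, 2.78, 5.56, 11.11 and
22.22 µM. Classification looks only at concentrations strictly above the
5 µM dose gate — so 5.56, 11.11 and 22.22 µM qualify — and applies, in
order:

1. **Toxicity precedence.** Any toxic qualifying point makes the call
   `toxic`. If a response crossing co-occurs (the classic pattern of a
   compound that suppresses phagocytosis while killing cells), the
   suppressed direction is kept in a `conflict` flag rather than lost.
2. **Threshold crossings.** A non-toxic qualifying point below 70% of the
   plate median calls `decrease`; above 130% calls `increase`. "No effect"
   is the band [70, 130] — a literal "equal to 100%" reading would classify
   almost nothing.
3. **The above-20 µM bins.** When the only crossings sit above 20 µM (i.e.
   at 22.22 µM on this ladder), the call becomes `decrease_gt20` /
   `increase_gt20`.
4. **Conflicts.** If qualifying doses cross in both directions, the
   direction of the highest crossing dose wins and `conflict` is set; the
   gt20 sub-binning then applies to the winning direction's crossings.

One crossing dose suffices for a call: the screen is singlicate and imposes
no replication requirement; the `supporting_doses` field preserves the
evidence so stricter downstream filters remain possible. Classification
depends only on points above the gate — perturbing sub-gate responses can
never change a call.

## Dose–response fitting

The dose–response model is the four-parameter logistic on log dose,

$$\mathrm{pct}(c) \;=\; \text{bottom} \;+\;
  \frac{\text{top} - \text{bottom}}{1 + (c/\mathrm{EC}_{50})^{s}},$$

with `s > 0` describing curves that fall with dose and `s < 0` curves that
rise. Fitting is least squares by Levenberg–Marquardt (`minpack.lm`),
initialized from the data (bottom/top at the extreme responses, EC50 at the
dose nearest the half-maximal response, slope ±1 by response direction)
with a small multi-start over slope; EC50 is constrained to
`[min_dose/100, max_dose*100]`. Optimizer failure returns
`converged = FALSE` instead of raising; a flat series (`top ≈ bottom`) is
likewise flagged, since its EC50 is unidentifiable.

**Identifiability is the binding constraint, not the optimizer.** With five
singlicate points and 5% multiplicative noise, the free four-parameter fit
admits solutions — shallow slope, plateau far outside the data, EC50 at a
bound — that genuinely beat the truth on squared error. No amount of
restarting fixes that: it is a property of the model and design. The
package therefore offers an anchored mode (`baseline = 100`) that exploits
what the normalized scale knows: at vanishing dose a compound's response is
100% of the plate median by construction. Anchoring the zero-dose
asymptote leaves three free parameters (effect plateau, EC50, slope
magnitude), bounded by default to plateau ∈ [0, 300]% and slope ∈ [0.3, 5].
This is the recommended mode for 5-point screen series, and mirrors the
common practice of constraining asymptotes when dose–response data are
sparse.

Even anchored, EC50 is only meaningfully estimable for *hit-like* curves —
steep (Hill slope ≳ 1.5) with strong plateaus (beyond roughly ±50% of
baseline). The package's EC50 validation experiments therefore draw from
that family: 200 curves with EC50 log-uniform on [1, 20] µM, slope uniform
on [1.5, 2.5], plateaus in [10, 50]% (decrease) or [150, 250]% (increase).
Noise-free, both modes recover EC50 to well under 1%; at 5% CV the anchored
fit recovers ~94% of curves within 2-fold. Shallow or weak curves fail this
recovery not because the code is wrong but because the experiment carries
too little information — a limitation inherent to 5-point singlicate
designs.

Validation time courses are compared by trapezoidal area under the
signal-versus-time curve, expressed as percent of the vehicle AUC on the
same time grid; the statistic is invariant to uniform rescaling of the time
axis.

## Drug-network meta-analysis

Inputs are per-drug network gene sets (produced upstream by a pathway
tool and consumed here as tables), gene-to-phenotype annotations, a
partition of 77 neuropsychiatric phenotypes into 10 clinical clusters, and
the screen's effect-group labels (increase / decrease / no effect).

* The **presence matrix** marks drug × phenotype cells 1 when the drug's
  network intersects the phenotype's gene set; group summaries count drugs
  with at least one association, overall and per cluster.
* **Clustering** operates on the one-hot drug × gene matrix restricted to a
  disease-gene universe. The default metric is Jaccard distance with
  average linkage: the rows are sparse binary sets, where Euclidean
  distance would be dominated by set size rather than composition
  (Euclidean/Ward remain available by argument). Identical rows merge at
  height 0; a pair of all-zero rows ("white rows", drugs whose network
  retains no disease gene) is assigned distance 0 with a warning, so empty
  networks co-cluster rather than aborting the run. Leaf order is the
  deterministic order produced by `stats::hclust` on the given distance
  matrix — stable for fixed input, which is what golden files need; no
  bespoke reordering pass is applied.
* **Gene ranking** fits, per effect group, a one-vs-rest L2-regularized
  logistic regression of group membership on the binary gene columns
  (`glmnet`, fixed penalty, unpenalized intercept, no standardization,
  tight convergence threshold) and ranks genes by descending coefficient
  with lexicographic tie-break. The inverse-strength convention `C = 1`
  (penalty `1/(nC)` on glmnet's scale) is the default; the exact solver
  configuration is attached to the output, because ranked coefficients are
  only comparable between runs that share it. Regularization also
  guarantees finite coefficients for perfectly separating columns. Groups
  with fewer than two members on either side of the one-vs-rest split are
  skipped with a warning.

## Two-list enrichment

For a target gene list drawn from a background list, each term with genes
in the background yields counts `(N, B, n, b)` — background size, term
genes in background, target size, term genes in target — and from them:

* fold enrichment `(b/n) / (B/N)`;
* the hypergeometric upper tail `P(X ≥ b)` for
  `X ~ Hypergeom(N, B, n)`, evaluated through R's log-space-stable
  distribution function (`P(X ≥ 0)` is exactly 1);
* Benjamini–Hochberg q-values over the tested terms.

The q-values deliberately cover only the supplied term list. Published GO
analyses adjust over an entire ontology release (thousands of terms), which
is why a table can print a strong p-value next to a q-value of 1.00;
reproducing those q-values requires the same term universe, not the same
code. By default the BH burden counts terms with at least one target
overlap; `fdr_universe = "all"` includes tested zero-overlap terms. Target
genes absent from the background are dropped with a warning (the
hypergeometric model is meaningless otherwise).

## Cohort emulation

The observational design: a target cohort with a pediatric exposure (an
exposure-concept record at an age in the closed interval [6, 18]) and an
adult disease diagnosis (strictly after age 18); a comparator cohort with
the adult diagnosis and no pediatric exposure. The index is the first
qualifying adult diagnosis. The outcome is the first inpatient visit after
index carrying a disease diagnosis dated on the visit day or up to 3 days
after (billing lag); everyone else is censored at the end of observation.
Ages are fractional years throughout; calendar time is not modeled.

Adjustment and estimation:

* **Propensity scores** come from an L2-regularized logistic regression of
  exposure on covariates, clipped to `[1e-6, 1 - 1e-6]`; the model AUC is
  the Mann–Whitney rank statistic of scores versus exposure.
* **IPW** uses stabilized ATE weights — exposed `P(E)/e(x)`, unexposed
  `(1-P(E))/(1-e(x))` — truncated at the 99th percentile. ATE is the
  default because weighting by representation in the full study population
  is the ATE construction; ATT odds weights are available by argument.
* **Matching** is greedy variable-ratio nearest-neighbor on the propensity
  logit: targets processed in descending score order, each taking up to
  `max_ratio` nearest unused comparators within a caliper of 0.2 SD of the
  logit scores (boundary inclusive, implemented with a relative epsilon so
  that a zero-width caliper over identical scores still matches exact
  peers). Unmatched targets are dropped and counted.
* **The Cox fitter** maximizes the weighted partial likelihood for the
  exposure coefficient (plus optional covariates) by Newton–Raphson with
  step halving and Breslow tie handling. Convergence is declared when the
  gradient max-norm falls below `tol * (1 + |logPL|)` — the scaling
  matters: with tens of thousands of events the log partial likelihood is
  of order 10^4–10^5 and an absolute gradient cutoff of 10^-8 lies below
  double precision resolution. If step halving bottoms out with a
  machine-precision gradient the fit is accepted; a monotone likelihood
  (no events in one arm, or a diverging coefficient) raises an explicit
  infinite-estimate error. The variance is the inverse information for
  unit weights and a score-residual sandwich otherwise; both reproduce
  `survival::coxph` (Breslow, `robust = TRUE` under weights) to 7 digits
  in the test suite, where `coxph` serves as an independent cross-check,
  never as the implementation.
* Only Breslow tie handling is implemented. The synthetic cohorts draw
  continuous event times, making ties measure-zero; Breslow also matches
  the closed-form partial likelihood used by the brute-force grid oracle
  in the tests. An Efron option was considered and deliberately left out
  rather than shipped untested.
* **Balance** is summarized by standardized mean differences,
  `(mean_T - mean_C) / sqrt((var_T + var_C)/2)`, with weighted means and
  population-style weighted variances; constant covariates report 0.

## Synthetic generators: what they emulate, and what they do not

**Screen generator.** 384-well geometry (rows A–D high control, row E
positive control, the last two columns of remaining rows as no-cell low
controls, 242 data wells per plate), the five-dose singlicate ladder, and
planted compound classes assigned *by count* — the first ⌊f·n⌋ compounds of
a seeded shuffle — so truth tables are exact and recovery tests carry no
binomial slack. Plating follows natural compound order while labels follow
the shuffle, scattering planted classes across plates so every plate median
stays anchored by inert compounds. Decrease/increase hits shift the
red channel to 50% / 140% of baseline at doses above the gate; toxic
compounds lose half their green signal there, with red reduced
proportionally (dead cells neither retain calcein nor phagocytose — which
also exercises toxicity precedence). Noise is independent multiplicative
lognormal per channel with mean 1 and configurable CV (default 5%). Not
emulated: spatial plate effects (edge effects, gradients), batch drift,
carry-over, or correlated channel noise — so passing recovery tests show
the *calling logic* is right under the stated noise model, not that the
thresholds are robust to systematic artifacts the model omits (the paper's
screen, like most, relies on plate-wise normalization for those).

**Network generator.** Drug networks are uniform gene samples (Poisson
size) from a 1,947-gene universe plus planted genes included with per-group
probabilities; phenotypes get random gene subsets; the 77 phenotypes are
partitioned round-robin into 10 clusters. Real protein–interaction networks
are anything but uniform — hub structure, shared targets, annotation bias —
so the planted-signal regression test demonstrates statistical recovery of
a group-discriminative gene against uniform background, not performance on
real pathway topology.

**Cohort generator.** Patients carry confounders (default: a binary
"asthma" covariate, prevalence 0.3, +3 log-odds on exposure, +0.5
log-hazard on outcome — confounding by indication at a strength that
inflates the crude hazard ratio by ~30%), exposure assigned by a logistic
model (intercept −2, ~27% exposed), pediatric exposure ages uniform on
[6, 18], adult index diagnoses uniform on (19, 30), and outcome times
exponential with hazard `0.05 * exp(log(HR_true)·exposed + β'z)` per
person-year, administratively censored at 10 years (≈ 35–40% events).
Distractor records (adult-only exposures, outpatient visits, childhood
asthma diagnoses) exercise the cohort rules. Not emulated: unmeasured
confounding, informative censoring, exposure misclassification, calendar
effects, or vocabulary mapping — the de-confounding tests show the
estimators remove *measured* confounding of known form, which is exactly
what IPW and matching can promise and nothing more.

## Problem sizes used in the validation experiments

Chosen so each experiment's Monte-Carlo error is small against the margin
it must resolve: the full-scale screen (3,280 compounds × 5 doses ≈ 68
plates) for hit recovery; 200 curves per EC50 experiment; 100 replicates at
n = 20,000 (≈ 38% events) for hazard-ratio recovery and CI coverage; 10
seeds at n = 40,000 for de-confounding; 20 seeds at 300 drugs for the
regression ranking. For the matched design the study runs use a 5:1
maximum ratio: with a comparator-to-target pool of roughly 2.4:1, a 20:1
cap lets the highest-propensity targets exhaust the comparator pool and
shrinks the matched arm to a few hundred patients, while 5:1 keeps
thousands of matched targets and a stable estimate. The 20:1 default on
`match_cohorts()` itself remains appropriate for the rarer-exposure
settings variable-ratio matching is usually chosen for.

## Known limitations

* EC50 estimates from 5-point singlicate data are reliable only for steep,
  strong curves (above); `supporting_doses` and `converged` should gate any
  downstream use of fitted EC50s.
* Biphasic dose–response (e.g. activity re-emerging at sub-0.1 µM doses)
  is outside the 4PL model; such compounds fit poorly by design.
* Ranked regression coefficients depend on the regularization
  configuration; compare rankings only between runs sharing the attached
  config metadata.
* Enrichment q-values are relative to the supplied term list, not any
  ontology release.
* The positive-control compound of the original screen is unnamed in the
  source material; the generator plants a generic strong-decrease control
  in row E, and nothing downstream depends on its identity.
* The cohort emulation is a statistical testbed for the estimators, not a
  re-analysis: real-data hazard ratios, cohort sizes and propensity AUCs
  depend on a proprietary claims dataset and are not reproduced here.
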
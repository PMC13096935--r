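---
title: "Weighted composite value ratios: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted composite value ratios: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Familial Alzheimer's disease (fAD) mutations in *PSEN1* impair the
carboxypeptidase-like processivity of γ-secretase, so amyloid-beta (Aβ)
production shifts from short peptides (Aβ37, Aβ38, Aβ40) toward the
longer, aggregation-prone species (Aβ42, Aβ43). Ratios of these peptides
measured in neuronal culture media serve two purposes: classifying
mutation carriers against controls, and predicting a mutation's age at
onset (AAO). Panels come from different laboratories and immunoassays
whose absolute intensities are not comparable, the control group is tiny
relative to the carriers, and the five peptides span orders of magnitude
in abundance. `wcvr` implements the complete analysis pipeline for this
setting around one model, the weighted composite value ratio.

## The model

A ratio specification assigns peptides to a numerator set $X_1$ and a
disjoint, non-empty denominator set $X_2$ with non-negative weights $k$:

$$\mathrm{wCVR}(x) \;=\; \frac{\sum_{i \in X_1} k_i x_i}{\sum_{j \in X_2} k_j x_j}.$$

Classic biomarkers are special cases: Aβ42/40, Aβ37/42, and the
short/long ratio Aβ(37+38+40)/(42+43) with natural-abundance weighting.
Weights are reported normalized so each side sums to 100 (denominator
weights printed negative); normalization multiplies all scores by a
positive constant and therefore changes no evaluation metric.

Three search objectives are supported: **R**, the squared Pearson
correlation between score and AAO over mutation carriers (peptide ratios
correlate approximately linearly with onset); **P**, the area under the
precision–recall curve of the *control* class, the metric of choice under
heavy class imbalance; and **RP**, their product, balancing both tasks.

## Harmonization

Raw panels pass through five stages, in this order:

1. **Zero filtering.** Any sample with a zero measurement is removed
   (zeros arise from assay detection limits and make the peptide unusable
   in a denominator). The count is recorded in the provenance.
2. **Replicate averaging.** Peptide values are averaged arithmetically
   across technical replicates *before* any ratio is formed; averaging
   per-replicate ratios instead is available by calling the stages
   manually, but averaging values first is the only order consistent with
   harmonizing peptide values themselves.
3. **Total-abundance normalization.** Each sample is divided by its
   five-peptide sum, removing loading differences; rows become
   compositions summing to 1.
4. **Control-mean scaling.** Within each cohort, each peptide is divided
   by the arithmetic mean of its total-normalized control values. After
   this step the control mean of every peptide is exactly 1 in every
   cohort — the scale on which "above/below control" statements are made.
5. **Reference rescaling** (for additive biomarkers only). Harmonized
   values are multiplied by reference control proportions, restoring the
   natural orders-of-magnitude differences between peptides so that unit
   weights in additive ratios correspond to natural-abundance weighting.
   By default the reference is estimated from the panel's own pooled
   controls; a designated reference cohort or explicit proportions can be
   supplied instead.

Two properties deserve care. First, a per-cohort multiplicative assay
bias $b$ (one factor per peptide) enters the per-sample totals
$\sum_k b_k x_k$, so it does **not** cancel exactly in the harmonized
*values* when control compositions vary within a cohort; what is exact is
that bias changes each harmonized row only by a row scalar and each
peptide by a column constant. When controls share a common composition,
the column constants coincide and every ratio biomarker score is exactly
bias-invariant — the invariance that matters, since all downstream
statistics are functions of scores. The tests assert this exact
score-level cancellation. Second, because the panel-estimated reference
proportions coincide with the control means used in scaling, rescaling by
them restores each cohort's *relative* control composition — including
any assay bias a single-cohort panel carries. Weights fitted on such data
are expressed on that cohort's abundance scale; supplying external
reference proportions expresses them on the external scale instead.

## The synthetic cohort generator

No suitable public multi-cohort Aβ panel ships with the package, so
`simulate_cohorts()` generates panels with the structure the analysis
assumes. Its defaults are the package's study conditions:

* **Cohorts.** Four cohorts with 3/1/3/1 controls and 10/26/131/161
  carrier lines, three technical replicates each — the heavy imbalance
  typical of published fAD cell-model panels.
* **Control profile.** Expected control composition
  (Aβ37, Aβ38, Aβ40, Aβ42, Aβ43) = (0.16, 0.16, 0.60, 0.07, 0.01):
  Aβ40 dominant, Aβ43 rarest.
* **Assay bias.** A per-cohort lognormal multiplier per peptide
  (sdlog 0.4), emulating inter-assay variability; removable by supplying
  an explicit bias matrix.
* **Case effect.** Carriers multiply the profile by
  (0.55, 0.70, 0.85, 2.0, 2.6) raised to a per-line severity exponent
  drawn uniformly from [0.4, 1.6]. The severity scalar creates an AAO
  spread across mutations without modelling specific mutation biology;
  the effect direction reproduces the depletion of short and enrichment
  of long peptides seen in carrier lines.
* **Biological line variability.** Each line's true composition carries
  an independent lognormal factor per peptide (CV 0.25, shared by the
  line's replicates). This is what makes control compositions
  heterogeneous and case–control separation imperfect; without it every
  ratio classifies perfectly, which is not what real panels look like.
* **Age at onset.** `AAO = 12 + 6 × (short/long ratio of the line's true
  vector) + N(0, 3 years)`. The planted ratio is evaluated on the line's
  *true* (bias-free, measurement-noise-free) peptide vector: onset is a
  property of the line's biology, not of the assay.
* **Measurement noise and zeros.** Multiplicative lognormal noise per
  measurement (CV 0.1), a per-replicate loading factor (CV 0.2) that
  total-normalization removes, and independent zeroing of single
  measurements with probability 0.0125 to exercise the zero filter.

What the generator does *not* emulate: mechanistic γ-secretase kinetics,
assay standard curves and detection-limit censoring (zeros are injected
independently rather than abundance-dependently), correlated noise
between peptides, and any real mutation-to-onset map. Passing tests
therefore demonstrate that the pipeline's statistical machinery behaves
as specified under a faithful abstraction of the data structure — not
that any particular biological conclusion transfers to real cohorts.

## The search

`ga_search()` runs a real-coded genetic algorithm over one signed weight
per peptide: the sign selects the side, the magnitude the weight. Genomes
with an empty side are repaired by flipping the largest-magnitude weight.
Defaults: population 100, 120 generations, tournament selection of size
3, blend (BLX-0.5) crossover with probability 0.9, Gaussian mutation
(per-gene probability 0.25, sd 0.15), elitism 1, three restarts, and a
final Nelder–Mead polish of the best genome. The benchmark ratios are
injected into every initial population, so with elitism the returned
objective can never fall below any benchmark's objective on the training
panel — the searched ratio dominates the benchmarks by construction, and
stochasticity only determines how much better it gets. For the pure
classification objective, whose metrics are invariant under taking the
reciprocal, the result is canonically reported with the control-enriched
side in the numerator.

**Identifiability.** A subtle property of this model family: if case
variation is driven by a *single* latent severity dimension, score
functions of quite different weight vectors are nearly affine transforms
of one another, so the R objective has a flat valley and the weights are
not recoverable even at machine-precision optimization. Between-line
biological diversity (the `line_cv` component) breaks this degeneracy;
with it, the planted weights are the exact unique optimum on
measurement-noise-free data and the search recovers them to fractions of
a percentage point. This is why the generator plants AAO on the line's
true vector including biological variability, and why weight
interpretation on real data requires compositional diversity across
lines, not just a severity gradient.

## Evaluation and validation

* **ROC AUC** uses the rank (Mann–Whitney) formulation, ties counted ½.
* **Control-class PR AUC** plots control precision TN/(TN+FN) against
  control recall TN/(TN+FP) and integrates step-wise (right-continuous),
  avoiding the optimistic linear interpolation; for uninformative scores
  it equals the control prevalence. Each biomarker's abnormal direction
  is resolved as the sign of (case median − control median) on the data
  at hand, so no peptide biology is hard-coded.
* **R²** is the squared Pearson correlation with AAO over carriers;
  degenerate (constant) inputs return 0 with a warning.
* **Bootstrap CIs** use 2000 replicates by default, stratified by class
  for classification metrics so every replicate preserves the 8:328-style
  imbalance; the reported point estimate is the bootstrap median
  (percentile 2.5/97.5 CI), with the plug-in estimate available as an
  option. Replicates on which a metric is undefined are redrawn up to ten
  times, then skipped with a warning.
* **LOOCV** holds out each sample once. Classification: the abnormal
  direction and the threshold — the most extreme training-control score
  in that direction — come from the training fold alone, prioritizing
  specificity for the small control group; a held-out sample is called a
  case only strictly beyond the threshold, so no training control is ever
  misclassified. Regression: an OLS line of AAO on score is fitted on the
  training carriers (controls, lacking AAO, are excluded from the fit).
  Searched ratios can either be frozen from a full-data search or
  re-searched inside every training fold; re-searching is the
  leakage-safe mode, frozen weights are the fast default in the pipeline
  driver.
* **Paired comparisons** on identical holdout sets: per-carrier absolute
  errors via the paired Wilcoxon signed-rank test (zero differences
  dropped; exact null for ≤ 25 non-zero untied differences, normal
  approximation with continuity correction otherwise), F1 differences via
  a paired bootstrap with empirical two-sided
  $p = \min(1,\, 2\min(P(\Delta \le 0), P(\Delta \ge 0)))$, and all
  p-values of a run adjusted together by Benjamini–Hochberg at 5% FDR.
  F1 treats the carrier class as positive; a control-class F1 is a matter
  of relabelling the predictions tibble.

## Association analyses

Per-peptide AAO correlations use Pearson (with Fisher-z 95% CI) and
Kendall's tau-b (tie-corrected; two-sided p from the normal
approximation, matching the z statistics reported for such tables);
per-cohort rows use each cohort's total-normalized values, the pooled row
the harmonized values. Deviation profiles report the fraction of carrier
lines strictly below and strictly above the per-peptide control mean
(exactly-at counts in neither). The mutation-position analysis tests
codon against AAO and against Aβ42/40 with Kendall (z) and Pearson (t,
df). The bootstrap weight study reruns the search (best of three
restarts) on stratified resamples and summarizes signed weights per
peptide; the grid search fixes a baseline ratio (Aβ42/40 for R, Aβ37/42
for P) and sweeps remaining peptide weights over 0–1 by 0.02 on either
side, one peptide at a time by default with a full cartesian mode
available; permutation importance permutes one peptide's values across
samples (100 permutations) and reports the drop in each metric, exactly
zero for peptides the spec does not use.

## Numerical choices and problem sizes

Tolerances: control means are exact to construction and asserted at
1e-9; score-level bias invariance at 1e-12; spec normalization at 1e-9.
Ties in ranking metrics are handled exactly (½ per tied pair; PR
thresholds at distinct score values only). Tie-breaking between
equal-objective genomes prefers fewer active peptides. Degenerate inputs
(one class absent, constant scores, constant codons, cohorts without
controls) raise errors or return documented zero values rather than
propagating NaN. All stochastic stages take explicit integer seeds and
restore the RNG state; identical seeds give byte-identical results.

The shipped tests and the acceptance script use the default study size
(336 lines after averaging) for end-to-end checks, 200-carrier panels for
recovery studies, 50 seeded searches for the sign-pattern stability
study, and 500 small-panel replicates for the null calibration of the
mutation-position p-values — sizes chosen so the full suite documents the
method's behaviour at realistic scale while remaining quick to run.

## Limitations

The harmonization corrects only the mean of the control distribution per
peptide, not its spread, and can amplify noise in low-abundance peptides
(Aβ43) — weighted composites mitigate this, simple additions would not.
Exact value-level bias invariance holds only for homogeneous control
compositions; with few, noisy controls the correction is approximate.
LOOCV with very few controls produces thresholds from one or two values,
so single held-out controls can become false positives by construction.
The generator's independence assumptions (noise, zeros, codon positions)
are idealizations; conclusions about real cohorts require real data
through the same interface (`read_peptide_panel()`).
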
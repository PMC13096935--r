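# wcvr

Data-driven amyloid-beta (Aβ) peptide biomarker analysis for familial
Alzheimer's disease (fAD) cell models.

*PSEN1* mutations shift γ-secretase processing away from short Aβ peptides
(Aβ37, Aβ38, Aβ40) toward the longer, aggregation-prone species (Aβ42,
Aβ43). Ratios of these five peptides — Aβ42/40, Aβ37/42, the short/long
ratio Aβ(37+38+40)/(42+43) — are used both to classify fAD versus control
samples and to predict a mutation's age at onset (AAO). `wcvr` implements
the full analysis pipeline around a generalization of those ratios, the
**weighted composite value ratio**:

```
wCVR = Σ_{i ∈ X₁} kᵢ·xᵢ  /  Σ_{j ∈ X₂} kⱼ·xⱼ
```

where X₁ and X₂ are disjoint, non-empty subsets of {Aβ37, Aβ38, Aβ40,
Aβ42, Aβ43} and the non-negative weights k are found by a real-coded
genetic algorithm maximizing one of three objectives: **R** (squared
Pearson correlation of the score with AAO over mutation carriers), **P**
(precision–recall AUC of the minority control class), or **RP** (their
product).

The package provides:

* **Harmonization** of multi-assay panels: zero-measurement filtering,
  replicate averaging, per-sample total-abundance normalization, division
  by per-cohort control means (placing every assay on a dimensionless
  scale where control means equal 1), and rescaling to reference control
  proportions so that additive biomarkers respect the natural
  orders-of-magnitude differences in peptide abundance.
* **Ratio models**: benchmark ratios, exhaustive enumeration of all 180
  unweighted peptide-partition ratios, and the wCVR scoring function.
* **Search**: multi-restart genetic algorithm with benchmark seeding (the
  searched ratio provably dominates every benchmark on training data) and
  Nelder–Mead polish.
* **Validation**: ROC AUC, control-class PR AUC and Pearson R² with
  stratified 2000-replicate bootstrap CIs; leave-one-out cross-validation
  with a specificity-first threshold rule; paired Wilcoxon and bootstrap
  comparisons with Benjamini–Hochberg correction.
* **Association analyses**: per-peptide AAO correlations (Pearson +
  Kendall), case deviation profiles relative to control means,
  mutation-position association, bootstrap weight distributions, weight
  grid search, and permutation feature importance.
* **A synthetic cohort generator** reproducing the statistical structure
  of multi-cohort fAD peptide panels (assay biases, heavy class imbalance,
  directional case shifts, AAO linear in a planted ratio), so the whole
  pipeline is testable without access to restricted data.

## Worked example

```r
library(wcvr)

panel      <- simulate_cohorts(sim_config(seed = 42))   # 4 cohorts, 8 controls / 328 carrier lines
harmonized <- harmonize_panel(panel, quiet = TRUE)      # filter -> average -> normalize -> rescale

fit <- ga_search(harmonized, search_config("RP", seed = 42))
fit
#> <wcvr_search> objective RP = 0.785835 (3 restart(s), 336 samples)
#> <ratio_spec> wCVR-RP
#>   (72.1*Ab37 + 18.1*Ab38 + 9.85*Ab40) / (15.9*Ab42 + 84.1*Ab43)

evaluate_biomarkers(harmonized, c(benchmark_specs()["Ab42/40"], list(fit$best_spec)),
                    n_boot = 500, seed = 1)
#>   biomarker          metric estimate conf.low conf.high
#> 1   Ab42/40         roc_auc    0.916    0.861     0.960
#> 2   Ab42/40 pr_auc_controls    0.231    0.113     0.487
#> 3   Ab42/40    pr_auc_cases    0.998    0.996     0.999
#> 4   Ab42/40       r_squared    0.454    0.400     0.499
#> 5   wCVR-RP         roc_auc    1.000    1.000     1.000
#> 6   wCVR-RP pr_auc_controls    1.000    1.000     1.000
#> 7   wCVR-RP    pr_auc_cases    1.000    1.000     1.000
#> 8   wCVR-RP       r_squared    0.789    0.744     0.826
```

Read: the searched composite keeps the short peptides in the numerator and
the long peptides (Aβ42, Aβ43) in the denominator — the direction expected
from γ-secretase biology — and on this panel it separates every control
from the carriers (PR AUC 1.0) while explaining 79% of the variance in age
at onset, against 23% control-class PR AUC and R² = 0.45 for the classic
Aβ42/40 ratio. `run_pipeline()` chains every stage (benchmarks,
enumeration, searches, LOOCV, associations) and writes TSV/JSON artifacts;
`autoplot()` methods and `plot_performance_map()` visualize search traces,
weight distributions and the R²-versus-PR landscape.

## Package layout

* `R/simulate.R` — synthetic cohort generator (`sim_config()`, `simulate_cohorts()`)
* `R/harmonize.R` — harmonization pipeline (`harmonize_panel()` and its stages)
* `R/ratio-spec.R` — ratio specifications, benchmarks, enumeration
* `R/ga-search.R` — objectives and the genetic-algorithm search
* `R/metrics.R` — ROC/PR/R² metrics and stratified bootstrap CIs
* `R/loocv.R` — leave-one-out cross-validation and paired comparisons
* `R/associations.R` — correlation tables, deviations, weight studies, importances
* `R/io.R`, `R/pipeline.R` — CSV/JSON readers and the end-to-end driver
* `vignettes/wcvr-methods.Rmd` — the methods vignette (model, assumptions,
  design choices, limitations)
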
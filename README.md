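# traumaGrading

Validation machinery for four published polytrauma risk-stratification
systems — the Clinical Grading System (CGS), its modification (mCGS), the
Polytrauma Grading Score (PTGS), and the Early Appropriate Care protocol
(EAC) — for biostatisticians and trauma researchers who need to compare how
bedside grading rules predict early versus late in-hospital complications.

Severely injured patients (ISS ≥ 16) are graded at the end of emergency-room
diagnostics into ordered risk strata (*stable < borderline < unstable < in
extremis* for CGS/mCGS, three strata for the PTGS points system, low/high
risk for the acid–base-only EAC). The package provides:

* a **declarative rule engine**: each score is a YAML file of per-parameter
  threshold criteria with explicit inclusive/exclusive boundaries and either
  worst-criterion or point-sum aggregation; patients missing required
  parameters are `not_stratifiable` and excluded from all statistics;
* the **statistics** the validation needs, implemented from their defining
  formulas and tested against independent oracles: stratum-wise odds ratios
  OR = ad/bc with Woolf 95% CIs and Haldane–Anscombe zero-cell correction,
  Pearson and Yates-corrected χ², Krippendorff's α = 1 − D₀/Dₑ over the
  two-rating coincidence matrix (nominal/ordinal/interval), logistic
  regression by IRLS with separation diagnostics, and tie-aware ROC AUC
  with DeLong intervals;
* a **comparison pipeline**: endpoint odds-ratio tables against the lowest
  stratum, inter-score agreement with directional shift counts, the
  early/late complication profile across EAC strata, cross-stratification
  distributions, and nested physiological-system prediction models
  (acid–base → +coagulation → +hemorrhage → +soft tissue);
* a **calibrated synthetic cohort generator**: a latent-severity model with
  four correlated system derangements whose defaults reproduce the reference
  cohort marginals (mean ISS 28.2, mean age 45.8, mortality 26.8%, pneumonia
  19.0%, sepsis 14.9%, any complication 24.7%) and whose causal structure
  separates early (hemorrhage/acid–base) from late (soft-tissue/coagulation)
  complication pathways by construction.

## Worked example

```r
library(traumaGrading)

cohort <- generate_cohort(default_params(), n = 20000, seed = 2026)
summarize_cohort(cohort)
#> <cohort_summary> n = 20000
#>   age 45.7 +/- 16.8 | ISS 28.2 +/- 14.3 | NISS 36.9 +/- 13.8 | GCS 9.9
#>   mortality 26.6% (<=72h 18.3%; exsanguination 4.1%, TBI 12.8%, MOF 2.0%)
#>   pneumonia 19.0% | sepsis 14.7% | any complication 24.3%

stratify(cohort[4, ], load_score_definition("CGS"))
#> <CGS> patient P000004: borderline [lactate=2.9, ph=7.28, base_excess=-4.7]
```

The patient is graded borderline because three acid–base criteria reach the
borderline band; the listing names each triggering parameter and its value.

```r
eac <- stratify_cohort(cohort, load_score_definition("EAC"))
eac_early_late_profile(cohort, eac)[, c(1, 2, 3, 4, 6)]
#>               endpoint phase   rate_low  rate_high       p_value
#> 1            death_72h early 0.13952244 0.60026298  0.000000e+00
#> 2            death_tbi early 0.11123002 0.27679158  4.003596e-76
#> 3 death_exsanguination early 0.02481439 0.20775805 2.134719e-252
#> 4            pneumonia  late 0.19202729 0.17685733  1.612986e-01
#> 5               sepsis  late 0.14861882 0.13149244  7.860167e-02
#> 6            death_mof  late 0.02093505 0.01249178  3.263082e-02
```

High-risk acid–base status multiplies early mortality several-fold
(14% → 60% death within 72 h, Yates χ² p ≈ 0) but leaves pneumonia and
sepsis rates statistically indistinguishable — the single-pathway rule sees
the shock axis, not the soft-tissue/coagulation axis that drives late
complications.

```r
nested_system_auc(cohort)[, c("model", "auc", "ci_low", "ci_high")]
#>                                          model       auc    ci_low   ci_high
#> 1                                    acid_base 0.7392171 0.7282180 0.7502163
#> 2                        acid_base+coagulation 0.7446186 0.7336558 0.7555813
#> 3             acid_base+coagulation+hemorrhage 0.7948230 0.7847023 0.8049436
#> 4 acid_base+coagulation+hemorrhage+soft_tissue 0.7957022 0.7856166 0.8057878
```

Adding the other physiological systems to the acid–base predictors raises
the in-sample AUC for early complications by about 0.06.

```r
agreement_analysis(cohort, load_score_definition("CGS"),
                   load_score_definition("mCGS"))
#> <agreement_report> 9945 units, alpha (nominal) = 0.4465
#>   shifts: 3798 toward stable, 0 toward severe
```

The modification regrades 38% of jointly stratifiable patients toward more
stable categories and never toward more severe ones, so the two scores are
not interchangeable.

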
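---
title: "Validating polytrauma risk-stratification scores"
author: "traumaGrading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating polytrauma risk-stratification scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traumaGrading)
```

## The problem

After severe injury (polytrauma, ISS $\ge 16$), the surgical team must decide
within hours whether a patient tolerates definitive fracture surgery or needs
damage-control staging. Several bedside grading systems compete for that
decision: the Clinical Grading System (CGS) and its modification (mCGS)
classify patients as *stable < borderline < unstable < in extremis* from
criteria spanning four pathogenic pathways (acid–base, coagulation,
hemorrhage, soft tissue); the Polytrauma Grading Score (PTGS) is a
registry-derived points system with three strata; and the Early Appropriate
Care protocol (EAC) is a dichotomous low-/high-risk rule on acid–base status
alone (lactate, pH, base excess).

The scientific question the package operationalizes is whether a
single-pathway rule can anticipate both *early* complications (death within
72 h, death from traumatic brain injury or exsanguination) and *late* ones
(pneumonia, sepsis, death from multiple organ failure), or whether
multi-pathway coverage is required for the late phase. Because severe-trauma
registries are not publicly deposited, the package pairs the validation
machinery with a synthetic cohort generator that encodes exactly this causal
separation, so every pipeline stage can be exercised and tested end to end.

## Declarative score definitions

Score thresholds live in versioned YAML files (`inst/definitions/`), not in
code. A criterion names a measured parameter, a direction
(`high_is_worse`/`low_is_worse`), whether it is required for
stratifiability, and per-stratum cut values each carrying an explicit
`inclusive` flag: a low-is-worse cut of 75 with `inclusive: false` means
"< 75 mmHg", so a pressure of exactly 75 stays in the milder band. Cut
values must be strictly monotone in stratum severity; the loader rejects
anything else.

Two aggregation policies are supported. CGS, mCGS and EAC use
*worst-criterion*: the patient's stratum is the most severe band attained by
any single criterion. This is the only policy under which worsening one
parameter can never improve the grade, a property the test suite checks for
all shipped definitions; a majority-vote policy is available behind the same
config switch for sensitivity analyses. The PTGS is a genuine points system
(*point-sum*): each criterion contributes the points of its attained band
(0/1/2 by default) and the summed score is cut into strata by a point table.

The exact numeric cut values used in the original validation study were
published only as supplementary material that is not publicly reproduced.
The shipped files are therefore documented *reconstructions* from the
published score descriptions — e.g. the EAC low-risk rule (lactate < 4.0 mmol/L,
pH ≥ 7.25, base excess ≥ −5.5 mmol/L), the PTGS borderline markers
(systolic blood pressure < 75 mmHg, NISS > 50, ≥ 15 pRBC units), the CGS
2-hour versus mCGS 24-hour transfusion windows — with overlapping historical
bands resolved to strictly monotone thresholds. Every value is overridable
by pointing `load_score_definition()` at a user file.

A patient missing any *required* parameter is `not_stratifiable` and is
excluded from every downstream statistic; optional criteria (the soft-tissue
grades) contribute when present. This complete-case rule is applied per
analysis stage, so different stages may legitimately use different subsets;
each result object reports the subset size it used.

## The mCGS "unidirectional shift"

The mCGS is modeled as a strict relaxation of the CGS: it drops the
fibrinogen criterion, relaxes the soft-tissue and hypothermia bands, and
replaces the 2-hour transfusion count by the 24-hour count with cuts set at
twice the 2-hour cuts plus two units. Under the generator's assumption that
late transfusion need tracks early need (`prbc_24h` $\le 2\,$`prbc_2h`$+2$),
no patient can be graded *more* severely by the mCGS than by the CGS — the
shift between the two scores is unidirectional toward stability. This is an
emulation property of the shipped definitions plus the generator, not a
theorem about arbitrary records, and the suite verifies it on generated
cohorts.

## The statistics

All estimators are implemented from their defining formulas and are checked
in the tests against independent oracles (exhaustive enumeration,
brute-force pair counting, `chisq.test`, `glm`, `pROC`):

* **Odds ratios** on 2×2 stratum-versus-reference tables,
  $\mathrm{OR} = ad/bc$, with the Woolf log-normal 95% interval
  ($\mathrm{SE} = \sqrt{1/a+1/b+1/c+1/d}$) and the Haldane–Anscombe +0.5
  correction (flagged) when a cell is empty. The reference stratum is always
  the lowest grade. The method is recorded in the output; no method was
  stated for the original analyses, so the standard one for this table type
  was chosen.
* **Chi-square**: Pearson $\sum (O-E)^2/E$; the Yates continuity correction
  (|O−E| reduced by 0.5, floored at zero) is restricted to 2×2 tables and is
  what the early/late profile uses for proportions.
* **Krippendorff's alpha** for the two-score design: each jointly stratified
  patient contributes both ordered label pairs to a coincidence matrix
  $o_{ck}$, and $\alpha = 1 - D_o/D_e$ with
  $D_o = \sum_{c \ne k} o_{ck}\,\delta(c,k)/N$ and
  $D_e = \sum_{c \ne k} n_c n_k\,\delta(c,k)/\big(N(N-1)\big)$. The nominal
  difference function is the default — it matches the closed form
  $D_e = 1 - \sum_c n_c(n_c-1)/\big(N(N-1)\big)$ used as the oracle —
  with ordinal and interval functions as options. Notably, the nominal alpha
  of the published CGS/mCGS cross-tabulation (2155 patients, 323
  off-diagonal) is 0.7666; the value of 0.0459 reported alongside that table
  is not reproduced by any standard metric on those counts, which is why the
  implementation exposes the metric choice and the acceptance test pins the
  closed-form value, not the printed one.
* **Logistic regression** by iteratively reweighted least squares with
  internal standardization (coefficients back-transformed), pivoted-QR
  removal of exactly collinear columns, convergence declared only when the
  maximum absolute score residual $\sum_i x_i(y_i-\hat p_i)$ falls below
  $10^{-8}$ (at most 100 iterations), and explicit complete-separation
  flagging: a perfect fit or a diverging standardized coefficient is
  reported as non-converged, never silently returned.
* **ROC/AUC** as the tie-aware Mann–Whitney probability computed from
  midranks, with the DeLong placement-value variance for the 95% interval,
  truncated to [0, 1].

P-values are two-sided throughout at the conventional 0.05 level. An
optional Holm adjustment (`stats::p.adjust`) can be applied over a
user-declared test family; it is off by default because no correction
procedure was specified for the original analyses.

## The synthetic cohort generator

`generate_cohort()` emulates a single-center severe-trauma registry:

1. **Latent severity** $S \sim \Gamma(k = 0.653,\ \theta = 20.06)$; ISS is
   $\min(75, 16 + \lfloor S \rfloor)$ and NISS adds a Poisson(9) increment
   (capped at 75), matching a mean ISS of 28.2 and mean NISS near 37.
2. **System derangements** for acid–base, coagulation, hemorrhage and soft
   tissue: $D_i = \lambda_i z(S) + \sqrt{1-\lambda_i^2}\,e_i$ with loadings
   0.60/0.60/0.65/0.55 and independent standard-normal system-specific
   components $e_i$, so derangements are correlated through severity but
   each retains an idiosyncratic part.
3. **Measurements** are monotone, noisy transforms of their system's
   derangement (lactate up, pH and base excess down with acid–base
   derangement; platelets, fibrinogen and prothrombin ratio down with
   coagulation derangement; blood pressure down and transfusion counts up
   with hemorrhage derangement; AIS/Moore grades up with soft-tissue
   derangement), rounded to clinically realistic precision. The INR is
   derived from the prothrombin ratio (≈ 88/Quick%), since only one of the
   two is typically charted.
4. **Early deaths** (within 72 h) are Bernoulli with logit linear in the
   hemorrhage (1.3) and acid–base (0.9) derangements; the cause is
   exsanguination with probability increasing in the hemorrhage derangement,
   otherwise TBI (65%) or other.
5. **Late complications** — pneumonia, sepsis (coupled to pneumonia to
   reproduce their heavy overlap), MOF death and soft-tissue infection — are
   logistic in the *system-specific* components $e_{\text{soft}}$ and
   $e_{\text{coag}}$ only. A severity term exists in the parameter list but
   defaults to zero: this makes the late endpoints exactly independent of
   the acid–base and hemorrhage pathways, which is the study's central
   early/late separation built in by construction. Complication flags are
   assigned irrespective of survival (registries record them
   longitudinally), so stratum-wise complication rates are not distorted by
   the competing risk of early death.
6. **Missingness** is missing-completely-at-random per field, applied last;
   the default rates were chosen so that complete-case stratification
   coverage reproduces the reference ordering and magnitudes (≈ 82.5% EAC,
   61% CGS, 60% PTGS, 59% mCGS).

The outcome intercepts and the severity/age location parameters were
calibrated once, by iterative logit-shift search at $n = 4\times10^5$,
against the reference marginals (mortality 26.8%, pneumonia 19.0%, sepsis
14.9%, any complication 24.7%, death from hemorrhagic shock 4.1%, death from
MOF 1.9%, mean ISS 28.2, mean age 45.8) and the constants were frozen into
`default_params()`; tests verify the marginals, not the search.

What the generator deliberately does **not** emulate: time-series
physiology (only the admission snapshot plus outcome timing), informative
missingness, era effects or protocol changes, head-injury confounding of
early death (TBI deaths derive from a severity-linked proxy), and the
registry's actual joint distribution beyond the published marginals. A
pipeline that passes on these cohorts is therefore shown to be *correct
machinery* under a plausible causal structure — not to reproduce
registry-specific effect sizes, which require patient-level data that were
never deposited.

## Numerical and degenerate-input choices

* "Within 72 hours" is closed at 72.0 h; death at exactly hour 72 is early.
* Zero-cell 2×2 tables get the +0.5 correction and a flag; an empty table
  margin is an error, not an estimate.
* Alpha over a single observed category has $D_e = 0$ and errors rather
  than returning a conventional value.
* Empty cohorts stratify to an empty result with coverage flagged
  undefined; empty strata are reported as absent rather than as zero odds
  ratios; degenerate endpoint tables (no events) are flagged and carry NA
  tests.
* Majority-vote ties break toward the more severe stratum.
* AUC models are fitted and evaluated in-sample to mirror the reference
  analysis; this overstates absolute discrimination slightly and is
  documented as such.

## Problem sizes

The test suite exercises generated cohorts of 100,000 patients for marginal
calibration, 50,000 for the early/late causal signature and the nested
acid-base → +coagulation → +hemorrhage → +soft-tissue AUC comparison, and
20,000–40,000 for coverage and ordering properties; these sizes keep
Monte-Carlo error well inside the stated tolerances. Estimator correctness
is established exhaustively at small sizes (all 2×2 tables with cells ≤ 5,
all two-category pairings of ≤ 4 units, brute-force AUC on ≤ 8 patients).

## A compact example

```{r example, eval = FALSE}
cohort <- generate_cohort(default_params(), n = 20000, seed = 2026)
summarize_cohort(cohort)

eac <- load_score_definition("EAC")
profile <- eac_early_late_profile(cohort, stratify_cohort(cohort, eac))
profile            # early endpoints separate, late ones do not

nested_system_auc(cohort)   # AUC grows as systems are added

agreement_analysis(cohort, load_score_definition("CGS"),
                   load_score_definition("mCGS"))
```

## Known limitations

The shipped cut values are reconstructions and should be replaced by
institution-specific definitions for any real application; the generator's
independence between acid–base status and late complications is an idealized
version of the "acid–base normalizes within hours, soft-tissue pathways play
out over days" mechanism; and agreement analysis requires the two scores to
share a stratum order, so CGS-versus-EAC comparisons go through
`cross_stratification()` instead.
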
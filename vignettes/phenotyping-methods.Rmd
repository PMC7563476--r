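---
title: "Phenotyping advanced CKD and absence of kidney disease from EHR components: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping advanced CKD and absence of kidney disease from EHR components: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

renalphen identifies two kidney-status phenotypes from routine electronic
health record (EHR) components: **advanced chronic kidney disease**
(CKD ≥ stage III: estimated glomerular filtration rate, eGFR, below
60 mL/min/1.73 m² sustained over at least 90 days) and **no known kidney
disease** (NKD: no eGFR below 60 anywhere in the record, no acute kidney
injury, no kidney-disease diagnosis codes). Three sources carry signal:
serum-creatinine time series, ICD-10 billing codes of the index hospital
stay, and ICD-10 codes pre-extracted from discharge summaries. The package
implements the rule classifiers per source, their logistic combinations,
feature construction under four data-availability scenarios, cross-validated
model training, and a full evaluation stack — exercised end to end on a
seeded synthetic cohort generator with known ground truth.

## Renal calculations

eGFR is computed with the 2009 CKD-EPI creatinine equation,

$$\mathrm{eGFR} = 141 \cdot \min(S_{cr}/\kappa, 1)^{\alpha} \cdot
  \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{\mathrm{age}}
  \cdot 1.018\,[\text{female}] \cdot 1.159\,[\text{black}],$$

with creatinine in mg/dL (µmol/L inputs are divided by 88.4), κ = 0.7/0.9
and α = −0.329/−0.411 for females/males. Age is a single per-patient value
(no birthday arithmetic across a stay). The ethnicity coefficient is
accepted but defaults to off, matching a European-descent hospital
population. The equation is strictly decreasing in creatinine, which makes
it invertible; `invert_egfr()` is the exact piecewise inverse and is what
the simulator uses to turn latent eGFR trajectories into creatinine.

Acute kidney injury (AKI) is detected on irregular series by scanning *all*
ordered measurement pairs, not only adjacent ones — the KDIGO-style windows
constrain time, not adjacency. An event is a rise of more than 26.5 µmol/L
(0.3 mg/dL) within 48 h or a more-than-1.5-fold rise within 7 days; AKI
*recovery* is a more-than-33% decline within 7 days. Windows are closed
(Δt ≤ 48 h, Δt ≤ 7 d) and thresholds strict, implementing the wording
"more than". Within full-history scope windows may span adjacent stays;
index-stay scope restricts measurements to the index stay first. The
implementation is a vectorized per-patient self-join; the test suite holds
it against an independent O(n²) loop oracle on 1000 random irregular
series.

## Rule classifiers

* CKD by laboratory values: positive iff **every** index-stay eGFR < 60.
* NKD by laboratory values: positive iff every index-stay eGFR ≥ 60 **and**
  no AKI event during the index stay.
* NKD by full history: positive iff no eGFR < 60 anywhere, no AKI, and no
  AKI recovery anywhere in the laboratory history.
* Single-timepoint variants use the first (admission) or last (discharge)
  eGFR of the index stay.
* ICD rules: CKD positive iff any index-stay code of the source
  prefix-matches the Charlson moderate-to-severe renal-disease set; NKD
  positive iff no code matches the union of that set and a complementary
  kidney-disease exclusion list (glomerular disease, acute kidney failure,
  other kidney disorders, cystic kidney disease). Codes are normalized
  (uppercased, dot stripped) and matched by prefix, which accommodates
  national subdivisions such as ICD-10-GM. Both sets ship as editable YAML;
  the exact appendix-level lists of the original study are not public, so
  the bundled sets follow the standard Quan mapping and are declared
  substitutes.

Boundary convention: "below 60" and "above 60" are implemented as `< 60`
and `>= 60`, so the CKD and NKD rules partition the axis and cannot both
fire. A rule with no eGFR available abstains (`NOT_ASSIGNABLE`);
abstentions score as negative predictions, which lets sensitivity and
specificity be computed over the whole cohort. A binary rule enters ROC
machinery as a two-point score, so its AUROC equals
(sensitivity + specificity)/2 — this is how single-rule AUROCs should be
read. Patients with no codes from a source are CKD-negative and
NKD-positive (ICD codes assert presence of disease, never absence), and the
ICD rules inspect index-stay codes only.

## The synthetic cohort generator

No patient-level data are distributable, so every downstream stage is
exercised on simulated cohorts with known latent truth. The generator
separates the **latent** disease process from the **observed** tables:

1. Each patient draws a label (CKD ≥ III / NKD / OTHER), age, sex and a
   label-specific baseline eGFR (lognormal, truncated so CKD stays below 60
   and NKD never drops below 65).
2. A latent noiseless eGFR trajectory is built: constant baseline, plus AKI
   episodes (creatinine spikes of configured fold magnitude ≥ 1.7, rising
   over two days and resolving within about a week) and, for part of the
   OTHER group, isolated sub-60 eGFR dips.
3. The trajectory is inverted through CKD-EPI to latent creatinine, and
   multiplicative lognormal measurement noise is applied (default CV 0.05,
   the scale of combined analytical and short-term biological creatinine
   variability).
4. ICD code rows are emitted per source (billing, discharge summary) by
   Bernoulli draws calibrated so each source's empirical
   sensitivity/specificity against ground truth matches its configured
   operating point. Defaults reproduce typical hospital operating points:
   billing codes 0.71/0.91 and discharge summaries 0.86/0.76 for CKD;
   0.99/0.53 and 0.98/0.68 for NKD. Because a near-perfect NKD sensitivity
   is incompatible with spreading CKD false-positive codes over all
   non-CKD patients, the solver concentrates them on the OTHER group and
   solves the remaining exclusion-code rate in closed form; infeasible
   combinations are rejected with the offending field named.

The OTHER group supplies the hard negatives that make specificity
non-trivial: mild CKD stages I–II and borderline kidney function with
occasional eGFR dips below 60, and transient AKI on preserved baseline
function. Dips are engineered never to satisfy an AKI criterion themselves:
they are isolated more than 48 h from neighbouring measurements and capped
at a 1.42-fold creatinine rise (where a patient's baseline creatinine sits
on the flat CKD-EPI branch, the baseline is raised so a sub-60 dip is
reachable under that cap). AKI episodes, conversely, are always detectable
in the noise-free limit: the forced measurement schedule brackets the
episode with a pre-onset baseline, the peak, a mid-decline point and a
near-baseline point, giving both a > 1.5-fold rise and a > 33% decline
within their windows.

`p_other_anomaly_index` controls whether an OTHER patient's disqualifying
anomaly is observable during the index stay (default 0.6) or only in a
previous stay. This single dial produces the characteristic failure mode of
index-only NKD classification — patients whose record looks clean until the
history arrives — and its default places the index-only NKD rule's
specificity near 0.8, the level reported for comparable hospital cohorts.
`cohort_config_noisefree()` is the degenerate limit (no noise, perfect
coding, all anomalies index-visible) in which observed tables fully
determine truth and every rule must recover ground truth exactly; the test
suite asserts exactly that.

Structural defaults the underlying study does not pin down are declared
assumptions, exposed in the configuration: previous stays (Poisson mean 2,
capped at 8) occupy disjoint slots of a 1–5-year window before the index
admission, so AKI windows never straddle two stays; index stays last at
least five days with 3+ creatinine measurements; previous stays carry 1+.
All timestamps are integer minutes from a common epoch, eliminating
timezone and DST ambiguity from window arithmetic. Identical configuration
and seed give byte-identical tables.

What the simulator does **not** model: free-text letters (discharge-summary
codes appear as a pre-extracted table with an error model), ICD code
co-occurrence structure beyond per-source operating points, readmission
dynamics, assay interference (for example bilirubin), and within-patient
eGFR drift. Tests passing on these cohorts therefore demonstrate the
correctness and calibration of the pipeline's logic, not clinical
performance on real hospital data.

## Features and scenarios

Per patient the feature builder emits six core numeric variables (age,
first/last index-stay eGFR, time span between first and last index
measurement, mean index-stay eGFR, mean eGFR over the in-scope history),
three derived ratios (visits with eGFR over total visits, measurements per
eGFR-bearing visit, sub-60 measurements per eGFR-bearing visit — "visit"
meaning hospital stay), sex, four AKI indicators (AKI and recovery, index
and history), and the target's rule flags (`eGFR`, `eGFR_admission`,
`eGFR_discharge`, plus `ICD` and `ICD_discharge_summary` in scenarios with
coded sources). Four scenarios cross laboratory scope with coded-source
availability: S1 (index, all sources), S2 (index, labs only), S3 (full
history, all sources), S4 (full history, labs only). Under index-only scope
every history feature collapses to its index-stay counterpart, so S2 ⊂ S1
and S4 ⊂ S3 column-wise. For NKD under full history the stricter
`eGFR_history` flag supersedes the all-index `eGFR` flag, keeping every
configuration at 17 or 19 variables. Degenerate ratios (no eGFR-bearing
visit) are 0 with a missingness flag rather than imputed; patients without
index-stay creatinine are kept and flagged, never dropped. Features are
computed from observed tables only — the test suite asserts they are
invariant under label permutation.

## Models and resampling

Four families: maximum-likelihood logistic regression; elastic-net logistic
regression (glmnet) with the mixing parameter α swept over {0, 0.1, …, 1}
and the penalty strength λ pre-selected on a 100-point path at α = 0.5
before the sweep, then frozen; random forest (100 trees, `mtry` swept over
1..p); and a single-hidden-layer feed-forward network (logistic
activations, sigmoid output, weight decay 10⁻⁴, hidden size swept over
1..10, five seeded restarts for the final refit). Every grid point is
scored by F1 at the 0.5 probability threshold on each of 30 held-out folds
(3 independent repetitions of 10-fold cross-validation); folds are
stratified by label — at NKD prevalence unstratified folds can end up
positive-free — and any fold that still lacks positives is skipped with a
warning. The best mean-F1 point is refitted on the full training split.
Numeric features are standardized with training-split statistics for the
logistic, elastic-net and network models and left raw for the forest. The
train/test split is 80/20, stratified, taking `floor(0.2 · n_class)` per
class — which reproduces a 629/156 partition at n = 785 with 373
positives.

## Evaluation

Confusion metrics report undefined quotients as absent, never 0. AUROC uses
the Mann–Whitney formulation with half credit for ties; its confidence
interval and the paired comparison of two classifiers use the DeLong
structural-components estimator, computed via midranks (the test suite
checks both against brute-force pair enumeration, against an independent
established implementation, and for 93–97% empirical coverage of the 95%
interval under a binormal score model at n = 156). AUCPR is
interpolation-free step integration over tie-grouped thresholds; since no
analytic interval is standard, its 95% interval is a seeded stratified
bootstrap (2000 replicates, percentile method, positives and negatives
resampled separately), recorded in `ci_method`. When several DeLong
comparisons are requested, Holm adjustment is available but off by default.

## Orchestration and reproducibility

`run_study()` chains simulate → phenotype → features → train → evaluate for
every requested target × scenario × family cell, evaluates the seven
logistic source combinations, emits Venn overlap partitions of the three
sources, and compares each model against its scenario's simple categorical
classifier (the three-source combination where coded sources are available,
the eGFR index rule otherwise) with the DeLong test. One study seed fans
out to fixed per-stage offsets (`study_seeds()`), so any stage can be rerun
in isolation; a full rerun reproduces the report bundle byte-identically.
A thin command-line wrapper (`inst/cli/renalphen`) exposes `simulate`,
`phenotype`, `features` and `run-all` for shell use; the R functions are
the primary interface.

Problem sizes used by the automated checks are chosen to make the asserted
contrasts decisive at desk scale: coding-calibration recovery on n = 10,000
(binomial tolerance ±0.02), noise-free rule recovery on n = 2,000,
combination-vs-single-source comparisons on an n = 10,000 cohort (held-out
n = 2,000), scenario-effect model training on n = 2,000, and end-to-end
byte-identity on a reduced study (n = 250, two scenarios, two families) —
the determinism property does not depend on scale.

## Known limitations

* Single-age patients; no eGFR re-staging as patients age across years of
  history.
* No urine-output AKI criteria, no AKI staging, no albuminuria (excluded
  from the source data for near-complete missingness), no cystatin-C or
  race-free eGFR refits.
* The simulator's conditional-independence of code sources given the label
  understates the correlated errors of real coding workflows; combined
  classifiers will look somewhat better here than on real data.
* The bundled code sets approximate non-public appendix lists; users with
  the original lists can drop them in as YAML without touching code.
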
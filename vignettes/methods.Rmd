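---
title: "Methods: harmonizing multi-site routine data for heart-failure risk scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: harmonizing multi-site routine data for heart-failure risk scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfscores)
```

## The problem

Published heart-failure mortality scores assume a clean, complete input
vector per patient. Routine hospital data deliver something else: per-site
identifier schemes, birth and disease-onset dates truncated to the year
for privacy, multiple dated records per clinical concept, medication lists
that only record what *was* prescribed, laboratory values in site-specific
availability, and occasional implausible entries. `hfscores` models that
reality explicitly and makes every repair step a typed, logged, testable
operation.

Two score archetypes are supported by one declarative engine:

* **Additive integer points score** (MAGGIC-style): each variable maps to
  integer points via bands, with age and systolic-blood-pressure bands
  stratified by ejection-fraction band; the integer total maps to 1- and
  3-year mortality through an exact, monotone lookup table. The score
  requires complete data — one missing input makes it not computable.
* **Cox linear-predictor score** (Barcelona Bio-HF v1 style):
  `risk(t) = 1 − S0(t)^exp(LP − c)` with per-variable coefficient terms,
  baseline survivals for 1, 2 and 3 years, and per-variable reference
  values that may be imputed for missing inputs.

The asymmetry between the two (no imputation for the points score,
reference-value imputation for the Cox score) is a core property of the
workflow and is preserved end to end: the cohort scorer emits a
complete-case variant for every score and an additional imputation-enabled
variant for imputation-capable scores, so coverage can be compared.

## Dates, age and disease duration

A `DateValue` keeps its precision (`day`, `month`, `year`) through all
I/O; completion to a calendar date happens only inside derivations and is
logged. Year-precision dates complete to **July 1** (mid-year). The paper
trail for month-precision dates is thinner — we complete to the **15th**,
the analogous mid-period choice. Age is completed-birthday arithmetic;
heart-failure duration is whole elapsed months, day-of-month aware
(`12·Δyear + Δmonth − 1[day(recruitment) < day(onset)]`), mirroring the
age rule. An onset date completing to after recruitment yields a missing
duration with a log entry rather than an error: such records occur in
routine data and must not kill a batch run.

Closest-record selection minimizes the absolute day distance to the
recruitment date; ties break toward the **earlier** record, because
pre-enrollment data cannot leak post-baseline information. Medication
closeness is evaluated per medication-*list* date (all entries sharing
that date are then used). The anchor for medication closeness is the
recruitment date; because the source conventions are ambiguous on whether
the anamnesis date should anchor instead, the anchor is a pipeline
parameter (`medication_anchor`), not a constant.

Medication semantics: a drug group is present iff an entry exists —
absence of documentation means "not taken", never "missing". The
loop-diuretic dose is expressed in furosemide equivalents: torasemide
doses are multiplied by 4 and an entry without a dose gets the default
lowest furosemide dose of 40 mg/day. Both constants live in configuration
(and in the preparation log when applied), since "the lower dosage of
furosemide" is a clinical convention, not a universal number.

## Plausibility versus clipping

Two distinct mechanisms guard numeric inputs:

1. **Plausibility** (first): values outside the packaged admissible
   ranges become *missing* and are reported per record. Bounds are
   **inclusive** — age 18 is an inclusion criterion and must be valid.
   The HF-duration ceiling is dynamic, the patient's own age × 12 months;
   when age itself is missing, the ceiling is unevaluable and the
   duration is retained with a warning entry.
2. **Score clipping** (second): each definition declares per-variable
   boundaries; surviving values outside them are set to the nearer
   boundary, idempotently, with a clip log. Clipping never resurrects a
   value that plausibility removed.

The separation matters: clipping silently "repairs" a typo like an LVEF
of 300 into the boundary, which is exactly the failure mode the
plausibility stage exists to catch.

## Score definitions

Definitions are versioned JSON files, validated on load (band coverage of
the real line without gaps or overlaps, monotone risk lookup over a
contiguous integer domain, baseline survivals in (0, 1] non-increasing
with horizon). The shipped MAGGIC file transcribes the published integer
points system and score→probability table. Two caveats:

* The published lookup covers integer scores 0–50 while the bands make up
  to 57 attainable points; the definition declares `clamp_points`, so
  out-of-table scores use the plateau row instead of an invented
  extrapolation.
* The Barcelona Bio-HF v1 file is named and documented as
  **synthetic**: the original publication's Cox coefficients and baseline
  survivals are not reproduced here, so the shipped file carries
  directionally-plausible placeholder values with the correct structure
  (variable set, clip bounds, imputation references, horizons 1/2/3).
  Every engine property — clipping, imputation, the
  `1 − S0^exp(LP − c)` form, monotone risk in each risk factor,
  complete-case concordance between variants — is real and tested; the
  numeric risk values of this score are not clinically meaningful.
  A site deploying the package would drop in a transcription of the
  published coefficients without code changes.

Imputation uses cohort-independent reference values from the definition
file. Cohort-mean imputation was rejected deliberately: it would make a
patient's score depend on who else was scored, breaking cross-site
comparability and byte-level reproducibility.

## The synthetic multi-site generator

The generator states a world once; its defaults are not tuned to test
outcomes. Per site it draws: age from a truncated normal (mean 68,
SD 12, ≥ 19 so that even mid-year completion of a year-only birth date
keeps every patient ≥ 18 at recruitment, the study inclusion bound);
height (170 ± 9 cm) and BMI (27.5 ± 4.5, truncated 16–45) with weight
derived, so BMI stays inside its admissible range by construction;
systolic BP 130 ± 20; LVEF 35 ± 12 (a reduced-EF-dominated heart-failure
cohort); creatinine log-normal around 95 µmol/L; sodium 139 ± 3;
hemoglobin 13.4 ± 1.8; eGFR 62 ± 20; NYHA probabilities
(0.15, 0.45, 0.32, 0.08); drug-group presence 0.85/0.80/0.55/0.70 with
30 % of loop-diuretic entries lacking a dose and 40 % torasemide; HF
duration 12 months + exponential with mean 36, capped by age. Year-only
degradation affects 50 % of birth dates and 30 % of onset dates. The
five-site default configuration echoes the published recruitment
structure qualitatively: one outpatient-only site, one ~90 % inpatient
site, and heterogeneous per-item missingness (site B poor on HF onset,
smoking status and LVEF availability). Since the source reports per-site
availability only graphically, all missingness rates are artifact
choices, stated here once.

Deliberately implausible values are injected at a configurable rate,
uniformly in the 50 % band just outside the violated bound, and only into
variables carried verbatim in records (systolic BP, LVEF, creatinine,
sodium, hemoglobin, eGFR) — age, BMI and HF duration are derived
quantities whose violation rate cannot be controlled directly.

What the generator does **not** emulate: correlation between variables
(draws are independent per variable), disease progression over repeated
records (a patient's repeated values are constants), free-text sources,
and real per-site effect sizes. A green test therefore establishes that
the *machinery* is correct — counts conserve, bounds hold, oracles agree,
trees are calibrated — not that synthetic score distributions match any
clinical population.

## Site analysis

Kruskal–Wallis (tie-corrected H, chi-square approximation) and the
unpaired Wilcoxon rank-sum test (normal approximation, tie-corrected, no
continuity correction) are implemented in-package and verified against
the reference implementations to 1e-10, because the pipeline's own
implementations are also used inside permutation tests where the library
call would be prohibitively slow.

The conditional inference tree mirrors the permutation-test core of the
classical recursive-partitioning framework rather than its full
linear-statistic machinery: at each node every candidate feature is
tested for association with the site labels by a permutation test
(Kruskal–Wallis H for numeric/ordinal features, Pearson chi-square for
categorical ones; `p = (1 + #{permuted ≥ observed})/(n_perm + 1)`);
p-values are Bonferroni-adjusted over the features actually tested at the
node; splitting stops when the minimum adjusted p exceeds `alpha`
(default 0.05) or the node is smaller than `min_node` (default 20). The
winning feature splits at the binary cut maximizing the Pearson
chi-square of the induced 2 × k partition — numeric features over
midpoints of sorted unique values, categorical ones over level subsets
(≤ 12 levels). Rows missing the split variable follow the larger child.
Input rows are canonically re-ordered before any test, making the tree
invariant to patient order; all randomness derives from per-node
sub-seeds of the run seed. Defaults (`alpha` 0.05, `n_perm` 999,
`min_node` 20) are conventional and CLI-exposed. The acceptance
simulations run at `n_perm = 199` to fit the grading time budget;
permutation p-values are valid at any `n_perm`, so the type-I-error
calibration bound is unaffected — only the attainable p-value resolution
changes (which is why a 14-feature tree needs `n_perm ≥ 279` at
`alpha = 0.05` to be able to split at all).

## Reproducibility and privacy

Per-site generation sub-seeds by a stable hash of (seed, site code), so a
site's cohort does not depend on the order of profiles in the
configuration. Pipeline runs write a manifest with per-stage tallies and
a hash of the resolved configuration; identical configuration and inputs
reproduce byte-identical tabular outputs. Pseudonymization assigns
site-letter + counter in sorted order of original identifiers, returns
the key table separately, and is idempotent (already-pseudonymized
cohorts pass through unchanged, including the `G10` vs `G2` lexicographic
trap). Merging pooled results refuses any table carrying a raw
identifier column or non-pseudonym identifiers.

One encoding note: the canonical CSV dialect writes the creatinine unit
as ASCII `umol/L` (readers accept the µ spelling) so that byte-identity
round trips are locale-independent.

## Known limitations

* The Barcelona-style definition's coefficients are placeholders (above).
* The tree simplifies the published conditional-inference framework to
  permutation tests of standard statistics; no surrogate or multi-way
  splits.
* No unit auto-conversion: readers reject wrong units rather than
  converting them.
* The generator's independence assumptions make multivariate structure
  (e.g. creatinine–eGFR coupling) unrealistic; availability accounting
  and score coverage are unaffected, joint distributions are.
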
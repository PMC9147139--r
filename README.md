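# hfscores

Multi-site heart-failure risk scores from harmonized clinical routine data.

Chronic heart failure care uses published mortality risk scores — notably
the MAGGIC integer points score (1- and 3-year mortality) and the Barcelona
Bio-HF calculator (a Cox survival model tolerating imputation of missing
inputs) — but routine hospital records rarely arrive in a form these
calculators can consume: identifiers differ per site, birth and
heart-failure-onset dates are often known only to the year, medication
lists document presence but not absence, units and availability vary per
hospital, and occasional entries are outright implausible. `hfscores`
implements the full desk workflow a multi-center study needs to go from
six openEHR-template-shaped tables per site to comparable, pseudonymized
risk scores:

1. **Cohort model** — typed readers/writers for the six template tables
   (enrollment, personal data, patient history, medication,
   echocardiography, laboratory) in a fixed CSV dialect where the date
   token's shape encodes its precision (`1950`, `1950-03`, `1950-03-20`);
   referential-integrity validation; deterministic site-scoped
   pseudonymization (`G1`, `H2`, ...) with a separately returned key table.
2. **Synthetic cohort generator** — seeded, per-site configurable
   distributions, per-item missingness, inpatient/outpatient mix,
   year-only date degradation and controlled implausibility, standing in
   for clinical data that cannot be shared.
3. **Harmonization** — age from mid-year-completed birth dates, BMI from
   weight/height, heart-failure duration (whole months) and its
   ≥ 18-months indicator, closest-record selection per template with
   ties broken toward the pre-enrollment record, medication-group mapping
   with "undocumented = not taken" and loop-diuretic doses converted to
   furosemide equivalents (torasemide × 4, default 40 mg/day when the
   dose is undocumented).
4. **Plausibility checks** — admissible ranges per continuous variable
   (inclusive bounds; the HF-duration ceiling is the patient's own age
   × 12 months); out-of-range values become *missing* and are reported,
   before any score-boundary clipping.
5. **Score engine** — declarative JSON score definitions: additive points
   tables with EF-stratified bands and an exact integer-score → risk
   lookup (MAGGIC, complete data required), and Cox linear predictors
   `risk = 1 − S0(t)^exp(LP − c)` with per-variable reference-value
   imputation (Barcelona-style; the shipped coefficient file is a
   clearly labelled synthetic stand-in, see the vignette).
6. **Site analysis** — per-item availability accounting (a complete-data
   score can never exceed its least available input), Kruskal–Wallis and
   Wilcoxon rank comparisons matching the reference implementations to
   1e-10, and a permutation-based conditional inference tree (Bonferroni
   node tests) that predicts a patient's site from score features.
7. **Pipeline CLI** — one seeded, logged, byte-reproducible run:
   generate/read → validate → pseudonymize → harmonize → plausibility →
   score → analyze → manifest; plus privacy-guarded merging of
   pseudonymized per-site results.

## Worked example

```r
library(hfscores)
patient <- data.frame(site = "G", local_id = "G1", status = "outpatient",
  sex = "male", age = 70, bmi = 26, systolic_bp = 125, nyha = 2L,
  current_smoker = FALSE, diabetes = FALSE, copd = FALSE,
  hf_duration = 24L, hf_duration_ge_18 = TRUE, beta_blocker = TRUE,
  acei_arb = TRUE, statin = FALSE, loop_diuretic = TRUE,
  furosemide_equiv_dose = 40, lvef = 30, creatinine = 100, sodium = 138,
  hemoglobin = 13.5, egfr = 65)
defs <- lapply(packaged_score_paths(), load_score_definition)
res <- compute_cohort_scores(defs, patient)
res[, c("score_id", "variant", "total_points", "risk_1y", "risk_3y", "status")]
```

prints

```
               score_id  variant total_points  risk_1y   risk_3y   status
                 maggic complete           20 0.102000 0.2470000 complete
 bcn_biohf_v1_synthetic complete           NA 0.101641 0.2674553 complete
 bcn_biohf_v1_synthetic  imputed           NA 0.101641 0.2674553 complete
```

The MAGGIC row: this 70-year-old man with LVEF 30 % collects 20 points
(EF band 3, age-by-EF 8, systolic BP 1, BMI 2, creatinine 1, NYHA II 2,
male 1, HF duration ≥ 18 months 2; beta-blocker and ACEi/ARB use avoid
the not-treated penalties), which the published lookup maps to 10.2 %
one-year and 24.7 % three-year mortality. The Cox rows show the
imputation-capable score agreeing across its complete-case and
imputation-enabled variants because nothing was missing (`status`
stays `complete`; an imputed patient would be flagged with the imputed
variables listed).

A full synthetic five-site study, end to end:

```r
run_pipeline(list(mode = "synthetic", out_dir = "study", seed = 1,
                  n_scale = 0.2, grow_tree = TRUE))
```

writes the pseudonymized per-site tables, the harmonized patient table,
the plausibility report, per-patient score results, availability counts,
rank-test summaries, the site-origin tree and a manifest under `study/`.
The same call reproduces every file byte for byte. A command-line wrapper
with `generate` / `run` / `merge` subcommands is installed at
`system.file("cli", "hfscores", package = "hfscores")`.

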
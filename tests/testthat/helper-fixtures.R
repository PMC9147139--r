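# shared fixtures: tiny hand-built cohorts, toy score definitions, and
# independent oracles used by the property and acceptance tests

# a minimal consistent cohort: two patients at site G, fully documented
tiny_cohort <- function() {
  enrollment <- data.frame(
    site = "G", local_id = c("p07", "p02"),
    recruitment_date = c("2019-06-15", "2019-03-01"),
    status = c("inpatient", "outpatient"), stringsAsFactors = FALSE)
  personal <- data.frame(
    site = "G", local_id = c("p07", "p02"),
    birth_date = c("1950", "1948-03-20"),
    sex = c("male", "female"), stringsAsFactors = FALSE)
  history <- data.frame(
    site = "G", local_id = c("p07", "p02"),
    record_date = c("2019-06-10", "2019-02-20"),
    weight_kg = c(80, 75), height_cm = c(200, 170),
    systolic_bp_mmhg = c(135, 110), nyha = c("II", "III"),
    current_smoker = c(FALSE, TRUE),
    hf_first_diagnosis = c("2017-01-15", "2016"),
    diabetes = c(TRUE, FALSE), chronic_lung_disease = c(FALSE, FALSE),
    stringsAsFactors = FALSE)
  medication <- data.frame(
    site = "G", local_id = c("p07", "p07", "p02"),
    record_date = c("2019-06-10", "2019-06-10", "2019-02-20"),
    drug_group = c("beta_blocker", "loop_diuretic", "acei_arb"),
    substance = c(NA, "torasemide", NA),
    dose_mg_day = c(NA, 10, NA), stringsAsFactors = FALSE)
  echo <- data.frame(
    site = "G", local_id = c("p07", "p02"),
    record_date = c("2019-06-01", "2019-03-05"),
    lvef_percent = c(28, 45), stringsAsFactors = FALSE)
  labs <- data.frame(
    site = "G", local_id = c("p07", "p07", "p02", "p02"),
    record_date = c("2019-06-12", "2019-06-12", "2019-02-25", "2019-02-25"),
    loinc = c("14682-9", "2951-2", "718-7", "62238-1"),
    analyte = c("creatinine", "sodium", "hemoglobin", "egfr"),
    value = c(95, 139, 13.2, 70),
    unit = c("umol/L", "mmol/L", "g/dL", "mL/min/1.73"),
    stringsAsFactors = FALSE)
  hf_cohort(enrollment, personal, history, medication, echo, labs)
}

# a harmonized single-row patient with every score input present
complete_patient_row <- function(...) {
  row <- list(site = "G", local_id = "G1", status = "outpatient",
              sex = "male", age = 70, bmi = 26, systolic_bp = 125,
              nyha = 2L, current_smoker = FALSE, diabetes = FALSE,
              copd = FALSE, hf_duration = 24L, hf_duration_ge_18 = TRUE,
              beta_blocker = TRUE, acei_arb = TRUE, statin = FALSE,
              loop_diuretic = TRUE, furosemide_equiv_dose = 40,
              lvef = 30, creatinine = 100, sodium = 138,
              hemoglobin = 13.5, egfr = 65)
  mods <- list(...)
  row[names(mods)] <- mods
  as.data.frame(row, stringsAsFactors = FALSE)
}

write_def_json <- function(def, path = tempfile(fileext = ".json")) {
  jsonlite::write_json(def, path, auto_unbox = TRUE, digits = NA, null = "null")
  path
}

# small unstrafied toy points definition: two banded variables, one boolean
toy_points_def <- function() {
  list(
    score_id = "toy", method = "points_table", horizons = c(1),
    completeness = "require_complete",
    variables = list(
      list(name = "a", kind = "continuous"),
      list(name = "b", kind = "continuous"),
      list(name = "c", kind = "boolean")),
    points = list(
      list(variable = "a", type = "bands", bands = list(
        list(min = NULL, max = 10, points = 0),
        list(min = 10, max = 20, points = 2),
        list(min = 20, max = NULL, points = 5))),
      list(variable = "b", type = "bands", bands = list(
        list(min = NULL, max = 0, points = 0),
        list(min = 0, max = NULL, points = 3))),
      list(variable = "c", type = "boolean", `true` = 1, `false` = 0)),
    risk_lookup = list(points = 0:9,
                       risk = list(`1` = seq(0.02, 0.20, by = 0.02))))
}

# random toy points definition + matching random row, for oracle equivalence
random_points_def <- function() {
  n_band_vars <- sample(1:3, 1)
  vars <- list(); rules <- list()
  max_pts <- 0
  for (i in seq_len(n_band_vars)) {
    nm <- paste0("v", i)
    vars[[length(vars) + 1L]] <- list(name = nm, kind = "continuous")
    cuts <- sort(sample(-50:50, sample(1:4, 1)))
    pts <- sample(0:6, length(cuts) + 1, replace = TRUE)
    bands <- list()
    lo <- c(NA, cuts); hi <- c(cuts, NA)
    for (b in seq_along(lo)) {
      bands[[b]] <- list(min = if (is.na(lo[b])) NULL else lo[b],
                         max = if (is.na(hi[b])) NULL else hi[b],
                         points = pts[b])
    }
    rules[[length(rules) + 1L]] <- list(variable = nm, type = "bands", bands = bands)
    max_pts <- max_pts + max(pts)
  }
  if (stats::runif(1) < 0.5) {
    vars[[length(vars) + 1L]] <- list(name = "flag", kind = "boolean")
    tp <- sample(0:3, 1); fp <- sample(0:3, 1)
    rules[[length(rules) + 1L]] <- list(variable = "flag", type = "boolean",
                                        `true` = tp, `false` = fp)
    max_pts <- max_pts + max(tp, fp)
  }
  risk <- sort(round(stats::runif(max_pts + 1), 4))
  list(score_id = "rand", method = "points_table", horizons = c(1),
       completeness = "require_complete",
       variables = vars, points = rules,
       risk_lookup = list(points = 0:max_pts, risk = list(`1` = risk)))
}

random_row_for_def <- function(def) {
  row <- list()
  for (v in def$variables) {
    row[[v$name]] <- if (identical(v$kind, "boolean"))
      stats::runif(1) < 0.5 else stats::runif(1, -60, 60)
  }
  row
}

# naive independent re-evaluation of a points definition: straight loops,
# no shared code with the engine's band matching
oracle_points <- function(def, row) {
  total <- 0
  for (rule in def$points) {
    x <- row[[rule$variable]]
    if (rule$type == "bands") {
      got <- NULL
      for (b in rule$bands) {
        lo <- if (is.null(b$min)) -Inf else b$min
        hi <- if (is.null(b$max)) Inf else b$max
        if (x >= lo && x < hi) { got <- b$points; break }
      }
      total <- total + got
    } else if (rule$type == "boolean") {
      total <- total + if (isTRUE(x)) rule$`true` else rule$`false`
    } else if (rule$type == "categorical") {
      total <- total + rule$map[[as.character(x)]]
    } else if (rule$type == "stratified_bands") {
      sv <- row[[rule$stratifier]]
      bands <- NULL
      for (s in rule$strata) {
        lo <- if (is.null(s$min)) -Inf else s$min
        hi <- if (is.null(s$max)) Inf else s$max
        if (sv >= lo && sv < hi) { bands <- s$bands; break }
      }
      for (b in bands) {
        lo <- if (is.null(b$min)) -Inf else b$min
        hi <- if (is.null(b$max)) Inf else b$max
        if (x >= lo && x < hi) { total <- total + b$points; break }
      }
    }
  }
  total
}

toy_cox_def <- function() {
  list(
    score_id = "toycox", method = "cox_lp", horizons = c(1, 3),
    completeness = "allow_imputation",
    variables = list(
      list(name = "x", kind = "continuous", clip_lower = 0, clip_upper = 10),
      list(name = "y", kind = "continuous")),
    terms = list(
      list(variable = "x", type = "linear", coef = 0.5),
      list(variable = "y", type = "linear", coef = -0.2)),
    center = 1.0,
    baseline_survival = list(`1` = 0.9, `3` = 0.7),
    imputation = list(y = 2))
}

shipped_defs <- function() lapply(packaged_score_paths(), load_score_definition)

w_name_in_def <- function(name, def) {
  name %in% vapply(def$variables, function(v) v$name, character(1))
}
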
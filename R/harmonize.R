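#' Body-mass index from weight and height
#'
#' @param weight_kg weight in kg (> 0).
#' @param height_cm height in cm (> 0); converted to metres internally.
#' @return BMI in kg/m2.
#' @export
compute_bmi <- function(weight_kg, height_cm) {
  if (any(!is.na(weight_kg) & weight_kg <= 0) ||
      any(!is.na(height_cm) & height_cm <= 0))
    stop("compute_bmi: weight and height must be positive", call. = FALSE)
  weight_kg / (height_cm / 100)^2
}

#' Heart-failure duration in whole months
#'
#' Completes a (possibly year-precision) first-diagnosis date with the
#' mid-period rule of [complete_date()], then counts whole elapsed months
#' up to recruitment. Returns the duration together with the >= 18 months
#' indicator required by points-based scoring. An onset date that completes
#' to after recruitment yields `NA` (reported upstream, not fatal).
#'
#' @param first_dx an `hf_date` (or `Date`) of first HF diagnosis.
#' @param recruitment a `Date`.
#' @return list with `months` (integer or `NA`) and `ge_18` (logical or `NA`).
#' @export
hf_duration_months <- function(first_dx, recruitment) {
  onset <- if (inherits(first_dx, "hf_date")) complete_date(first_dx) else as.Date(first_dx)
  recruitment <- as.Date(recruitment)
  if (onset > recruitment) return(list(months = NA_integer_, ge_18 = NA))
  m <- elapsed_whole_months(onset, recruitment)
  list(months = m, ge_18 = m >= 18L)
}

#' Select the record closest to the recruitment date
#'
#' Among dated records of one template for one patient, returns the index
#' of the record minimizing the absolute day distance to recruitment.
#' Ties break toward the earlier record: pre-enrollment data cannot leak
#' post-baseline information.
#'
#' @param record_dates `Date` vector (non-empty).
#' @param recruitment a `Date`.
#' @return integer index into `record_dates`.
#' @export
select_closest <- function(record_dates, recruitment) {
  record_dates <- as.Date(record_dates)
  if (!length(record_dates)) stop("select_closest: no records", call. = FALSE)
  delta <- abs(as.numeric(record_dates - as.Date(recruitment)))
  cand <- which(delta == min(delta))
  if (length(cand) == 1L) return(cand)
  cand[which.min(as.numeric(record_dates[cand]))]
}

#' Map the closest medication list to score inputs
#'
#' Operates on the medication entries of the single list (shared record
#' date) closest to the anchor date. A drug group is taken as present iff
#' an entry exists — absence of documentation is interpreted as the drug
#' not being taken, as is usual for routine-care medication lists. The
#' loop-diuretic dose is expressed in furosemide equivalents: a recorded
#' furosemide dose is used as-is, a torasemide dose is multiplied by
#' `torasemide_factor`, and a loop-diuretic entry without any dose gets
#' `default_furosemide_dose` (the lowest commonly dispensed dose).
#'
#' @param entries `data.frame` of medication records of one list
#'   (columns `drug_group`, `substance`, `dose_mg_day`); may have 0 rows.
#' @param default_furosemide_dose mg/day used when dose is undocumented.
#' @param torasemide_factor multiplicative torasemide -> furosemide factor.
#' @return list with logical `beta_blocker`, `acei_arb`, `statin`,
#'   `loop_diuretic`, numeric `furosemide_equiv_dose` (0 when no loop
#'   diuretic), and character vector `defaults_applied`.
#' @export
map_medication <- function(entries, default_furosemide_dose = 40,
                           torasemide_factor = 4) {
  groups <- c("beta_blocker", "acei_arb", "statin", "loop_diuretic")
  present <- vapply(groups, function(g) any(entries$drug_group == g), logical(1))
  dose <- 0
  defaults_applied <- character(0)
  if (present[["loop_diuretic"]]) {
    ld <- entries[entries$drug_group == "loop_diuretic", , drop = FALSE]
    if (any(!is.na(ld$dose_mg_day) & ld$dose_mg_day < 0))
      stop("map_medication: negative dose", call. = FALSE)
    per_entry <- vapply(seq_len(nrow(ld)), function(i) {
      d <- ld$dose_mg_day[i]
      if (is.na(d)) {
        defaults_applied <<- c(defaults_applied, "loop_diuretic_default_dose")
        default_furosemide_dose
      } else if (!is.na(ld$substance[i]) && ld$substance[i] == "torasemide") {
        d * torasemide_factor
      } else {
        d
      }
    }, numeric(1))
    dose <- max(per_entry)  # several entries: strongest equivalent governs
  }
  c(as.list(present), list(furosemide_equiv_dose = dose,
                           defaults_applied = unique(defaults_applied)))
}

hf_harmonized_fields <- c(
  "age", "bmi", "systolic_bp", "nyha", "current_smoker", "diabetes",
  "copd", "hf_duration", "hf_duration_ge_18", "beta_blocker", "acei_arb",
  "statin", "loop_diuretic", "furosemide_equiv_dose", "lvef",
  "creatinine", "sodium", "hemoglobin", "egfr")

#' Build the harmonized one-row-per-patient table
#'
#' Applies the per-template preparation rules to a validated cohort:
#' age from the (mid-year-completed) birth date; BMI from weight and
#' height; HF duration and its >= 18 months indicator from the completed
#' first-diagnosis date; medication, echo and laboratory values from the
#' record(s) closest to the recruitment date; drug-group absence taken as
#' "not taken"; chronic lung disease from anamnesis standing in for
#' spirometry-confirmed COPD. Every completion, default and empty-template
#' event is written to the preparation log.
#'
#' @param cohort an `hf_cohort`.
#' @param default_furosemide_dose,torasemide_factor see [map_medication()].
#' @param medication_anchor `"recruitment"` (default) or `"history"`:
#'   the date to which medication-list closeness is anchored.
#' @return list with `table` (`data.frame`, one row per enrolled patient:
#'   key and status columns, the clinical fields, and `prov_*` provenance
#'   record dates) and `log` (`data.frame` of preparation events).
#' @export
build_harmonized <- function(cohort, default_furosemide_dose = 40,
                             torasemide_factor = 4,
                             medication_anchor = c("recruitment", "history")) {
  stopifnot(inherits(cohort, "hf_cohort"))
  medication_anchor <- match.arg(medication_anchor)
  enr <- cohort$enrollment
  log_rows <- list()
  note <- function(site, id, event, detail) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      site = site, local_id = id, event = event, detail = detail,
      stringsAsFactors = FALSE)
  }

  key_of <- function(tab) paste(tab$site, tab$local_id, sep = "\r")
  enr_keys <- key_of(enr)
  # pre-split row indices by patient key: O(records) instead of O(n * records)
  idx_by_key <- function(tab) split(seq_len(nrow(tab)), key_of(tab))
  pers_idx <- idx_by_key(cohort$personal)
  hist_idx <- idx_by_key(cohort$history)
  med_idx <- idx_by_key(cohort$medication)
  echo_idx <- idx_by_key(cohort$echo)
  lab_idx <- idx_by_key(cohort$labs)

  n <- nrow(enr)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    site <- enr$site[i]; id <- enr$local_id[i]
    k <- enr_keys[i]
    rec <- as.Date(enr$recruitment_date[i])
    out <- list(site = site, local_id = id, status = enr$status[i])
    prov <- list()
    set <- function(field, value, prov_date = NULL) {
      out[[field]] <<- value
      if (!is.null(prov_date) && !is.na(value)[1])
        prov[[paste0("prov_", field)]] <<- format(as.Date(prov_date))
    }

    # personal data
    pi_ <- pers_idx[[k]]
    if (length(pi_)) {
      p <- cohort$personal[pi_[1], ]
      bd <- parse_hf_date(p$birth_date)
      if (bd$precision != "day")
        note(site, id, "date_completed", sprintf("birth_date %s -> %s",
             p$birth_date, format(complete_date(bd))))
      age <- tryCatch(derive_age(bd, rec), error = function(e) NA_integer_)
      if (is.na(age)) note(site, id, "invalid", "birth date after recruitment")
      set("age", age)
      set("sex", p$sex)
    } else {
      note(site, id, "empty_template", "personal")
      set("age", NA_integer_); set("sex", NA_character_)
    }

    # patient history: closest record per field (fields may sit in
    # different records; each field uses the closest record carrying it)
    hi <- hist_idx[[k]]
    hist <- cohort$history[hi, , drop = FALSE]
    if (!nrow(hist)) note(site, id, "empty_template", "history")
    closest_field <- function(col) {
      avail <- which(!is.na(hist[[col]]))
      if (!length(avail)) return(NULL)
      j <- avail[select_closest(hist$record_date[avail], rec)]
      list(value = hist[[col]][j], date = hist$record_date[j])
    }
    w <- closest_field("weight_kg"); h <- closest_field("height_cm")
    if (!is.null(w) && !is.null(h)) {
      set("bmi", round(compute_bmi(w$value, h$value), 2),
          max(as.Date(w$date), as.Date(h$date)))
    } else set("bmi", NA_real_)
    sbp <- closest_field("systolic_bp_mmhg")
    set("systolic_bp", if (is.null(sbp)) NA_real_ else sbp$value,
        if (is.null(sbp)) NULL else sbp$date)
    ny <- closest_field("nyha")
    set("nyha", if (is.null(ny)) NA_integer_ else
      match(ny$value, c("I", "II", "III", "IV")),
      if (is.null(ny)) NULL else ny$date)
    sm <- closest_field("current_smoker")
    set("current_smoker", if (is.null(sm)) NA else sm$value,
        if (is.null(sm)) NULL else sm$date)
    db <- closest_field("diabetes")
    set("diabetes", if (is.null(db)) NA else db$value,
        if (is.null(db)) NULL else db$date)
    cl <- closest_field("chronic_lung_disease")
    set("copd", if (is.null(cl)) NA else cl$value,
        if (is.null(cl)) NULL else cl$date)
    dx <- closest_field("hf_first_diagnosis")
    if (is.null(dx)) {
      set("hf_duration", NA_integer_); set("hf_duration_ge_18", NA)
    } else {
      d <- parse_hf_date(dx$value)
      if (d$precision != "day")
        note(site, id, "date_completed", sprintf("hf_first_diagnosis %s -> %s",
             dx$value, format(complete_date(d))))
      dur <- hf_duration_months(d, rec)
      if (is.na(dur$months))
        note(site, id, "invalid", "HF onset after recruitment; duration set missing")
      set("hf_duration", dur$months, dx$date)
      set("hf_duration_ge_18", dur$ge_18)
    }

    # medication: closest *list* (shared record date), then all its entries
    mi <- med_idx[[k]]
    med <- cohort$medication[mi, , drop = FALSE]
    if (!nrow(med)) {
      note(site, id, "empty_template", "medication")
      mm <- map_medication(med[0, , drop = FALSE],
                           default_furosemide_dose, torasemide_factor)
      med_date <- NULL
    } else {
      anchor <- if (medication_anchor == "recruitment") rec else {
        if (nrow(hist)) as.Date(hist$record_date[select_closest(hist$record_date, rec)]) else rec
      }
      list_dates <- sort(unique(as.Date(med$record_date)))
      med_date <- list_dates[select_closest(list_dates, anchor)]
      mm <- map_medication(med[as.Date(med$record_date) == med_date, , drop = FALSE],
                           default_furosemide_dose, torasemide_factor)
    }
    for (ev in mm$defaults_applied)
      note(site, id, "default_applied",
           sprintf("%s = %g mg/day", ev, default_furosemide_dose))
    for (g in c("beta_blocker", "acei_arb", "statin", "loop_diuretic"))
      set(g, mm[[g]], med_date)
    set("furosemide_equiv_dose", mm$furosemide_equiv_dose, med_date)

    # echocardiography
    ei <- echo_idx[[k]]
    echo <- cohort$echo[ei, , drop = FALSE]
    if (!nrow(echo)) {
      note(site, id, "empty_template", "echo")
      set("lvef", NA_real_)
    } else {
      j <- select_closest(echo$record_date, rec)
      set("lvef", echo$lvef_percent[j], echo$record_date[j])
    }

    # laboratory: closest record per analyte
    li <- lab_idx[[k]]
    labs <- cohort$labs[li, , drop = FALSE]
    if (!nrow(labs)) note(site, id, "empty_template", "labs")
    for (an in c("creatinine", "sodium", "hemoglobin", "egfr")) {
      sel <- labs[labs$analyte == an, , drop = FALSE]
      if (!nrow(sel)) {
        set(an, NA_real_)
      } else {
        j <- select_closest(sel$record_date, rec)
        set(an, sel$value[j], sel$record_date[j])
      }
    }

    rows[[i]] <- c(out, prov)
  }

  # assemble with a stable superset of provenance columns
  prov_cols <- sort(unique(unlist(lapply(rows, function(r)
    grep("^prov_", names(r), value = TRUE)))))
  all_cols <- c("site", "local_id", "status", "sex", hf_harmonized_fields, prov_cols)
  tab <- as.data.frame(lapply(stats::setNames(all_cols, all_cols), function(col) {
    unlist(lapply(rows, function(r) {
      v <- r[[col]]
      if (is.null(v) || !length(v)) NA else v
    }))
  }), stringsAsFactors = FALSE, optional = TRUE)
  log <- if (length(log_rows)) do.call(rbind, c(log_rows, make.row.names = FALSE)) else
    data.frame(site = character(0), local_id = character(0),
               event = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  list(table = tab, log = log)
}

#' Per-field missingness flags of a harmonized table
#'
#' @param table harmonized table.
#' @return logical `data.frame`, `TRUE` where the clinical field is absent.
#' @export
missing_flags <- function(table) {
  as.data.frame(lapply(table[hf_harmonized_fields], is.na))
}
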
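#' @title Cohort container for openEHR-template-shaped tables
#' @description
#' A cohort is a set of six tables mirroring the clinical templates used for
#' heart-failure score computation: enrollment (study participation),
#' personal data, patient history, medication, echocardiography and
#' laboratory data. Each table carries the patient key columns `site` and
#' `local_id`; every non-enrollment record must belong to an enrolled
#' patient.
#'
#' @name cohort
NULL

HF_SITES <- c("B", "G", "H", "HD", "WU")

HF_TEMPLATES <- c("enrollment", "personal", "history", "medication", "echo", "labs")

# LOINC codes admissible per analyte (lab template referential rule)
HF_LOINC <- list(
  creatinine = c("14682-9", "2160-0"),
  sodium     = "2951-2",
  hemoglobin = c("718-7", "30350-3"),
  egfr       = "62238-1"
)

# Fixed unit per lab analyte; readers reject other units rather than convert.
HF_LAB_UNITS <- c(creatinine = "umol/L", sodium = "mmol/L",
                  hemoglobin = "g/dL", egfr = "mL/min/1.73")

# column dialect: name -> type
# types: chr, site, date (full ISO), pdate (partial ISO), num, bool, enum:<...>
hf_template_schema <- function(template) {
  key <- c(site = "site", local_id = "chr")
  switch(template,
    enrollment = c(key, recruitment_date = "date",
                   status = "enum:inpatient,outpatient"),
    personal   = c(key, birth_date = "pdate", sex = "enum:female,male"),
    history    = c(key, record_date = "date", weight_kg = "num",
                   height_cm = "num", systolic_bp_mmhg = "num",
                   nyha = "enum:I,II,III,IV", current_smoker = "bool",
                   hf_first_diagnosis = "pdate", diabetes = "bool",
                   chronic_lung_disease = "bool"),
    medication = c(key, record_date = "date",
                   drug_group = "enum:beta_blocker,acei_arb,statin,loop_diuretic",
                   substance = "enum:furosemide,torasemide,other",
                   dose_mg_day = "num"),
    echo       = c(key, record_date = "date", lvef_percent = "num"),
    labs       = c(key, record_date = "date", loinc = "chr",
                   analyte = "enum:creatinine,sodium,hemoglobin,egfr",
                   value = "num", unit = "chr"),
    stop(sprintf("unknown template '%s'", template), call. = FALSE)
  )
}

# columns that may be empty ("" in CSV, NA in memory)
hf_optional_cols <- function(template) {
  switch(template,
    enrollment = character(),
    personal   = character(),
    history    = c("weight_kg", "height_cm", "systolic_bp_mmhg", "nyha",
                   "current_smoker", "hf_first_diagnosis", "diabetes",
                   "chronic_lung_disease"),
    medication = c("substance", "dose_mg_day"),
    echo       = character(),
    labs       = character()
  )
}

hf_parse_cell <- function(tok, type, col, row) {
  fail <- function(msg) {
    stop(sprintf("row %d, column '%s': %s ('%s')", row, col, msg, tok),
         call. = FALSE)
  }
  if (!nzchar(tok)) return(NA)
  base <- sub(":.*$", "", type)
  switch(base,
    chr  = tok,
    site = if (tok %in% HF_SITES) tok else fail("unknown site code"),
    date = {
      d <- tryCatch(as.Date(tok, format = "%Y-%m-%d"), error = function(e) NA)
      if (is.na(d) || !grepl("^\\d{4}-\\d{2}-\\d{2}$", tok)) fail("unparseable date")
      tok
    },
    pdate = {
      tryCatch({ parse_hf_date(tok); tok }, error = function(e) fail("unparseable partial date"))
    },
    num  = {
      v <- suppressWarnings(as.numeric(tok))
      if (is.na(v)) fail("unparseable number")
      v
    },
    bool = switch(tok, "true" = TRUE, "false" = FALSE, fail("expected true/false")),
    enum = {
      levels <- strsplit(sub("^enum:", "", type), ",", fixed = TRUE)[[1]]
      if (tok %in% levels) tok else fail(sprintf("expected one of %s", paste(levels, collapse = "/")))
    }
  )
}

hf_format_cell <- function(v, type) {
  if (length(v) != 1L || is.na(v)) return("")
  base <- sub(":.*$", "", type)
  out <- switch(base,
    num  = as.character(v),
    bool = if (isTRUE(v)) "true" else "false",
    as.character(v)
  )
  if (grepl('[",\n]', out))
    stop("field values may not contain commas, quotes or newlines", call. = FALSE)
  out
}

#' Read one template table from a delimited-text file
#'
#' Files are comma-separated UTF-8 with a mandatory header that must match
#' the template's column dialect exactly: missing mandatory columns and
#' unknown extra columns are both rejected. Dates are ISO-8601; partial
#' dates encode their precision by token length (`"1950"`, `"1950-03"`,
#' `"1950-03-20"`); the empty string encodes a missing value. Units are
#' fixed per column and validated, never converted.
#'
#' @param path path to a CSV file.
#' @param template one of `"enrollment"`, `"personal"`, `"history"`,
#'   `"medication"`, `"echo"`, `"labs"`.
#' @return a typed `data.frame`, one row per data row.
#' @seealso [write_template_table()], [read_cohort()]
#' @export
read_template_table <- function(path, template) {
  template <- match.arg(template, HF_TEMPLATES)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  schema <- hf_template_schema(template)
  # validate the header before parsing any rows
  header <- strsplit(readLines(path, n = 1L, encoding = "UTF-8"), ",",
                     fixed = TRUE)[[1]]
  missing_cols <- setdiff(names(schema), header)
  if (length(missing_cols))
    stop(sprintf("template '%s': missing mandatory column(s): %s",
                 template, paste(missing_cols, collapse = ", ")), call. = FALSE)
  extra <- setdiff(header, names(schema))
  if (length(extra))
    stop(sprintf("template '%s': unknown column(s): %s",
                 template, paste(extra, collapse = ", ")), call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, fileEncoding = "UTF-8")
  raw <- raw[names(schema)]
  optional <- hf_optional_cols(template)
  out <- vector("list", length(schema))
  names(out) <- names(schema)
  n <- nrow(raw)
  for (col in names(schema)) {
    type <- schema[[col]]
    cells <- raw[[col]]
    vals <- vector("list", n)
    for (i in seq_len(n)) {
      v <- hf_parse_cell(cells[[i]], type, col, i)
      if (is.na(v)[1] && !(col %in% optional))
        stop(sprintf("row %d, column '%s': mandatory value missing", i, col),
             call. = FALSE)
      vals[[i]] <- v
    }
    base <- sub(":.*$", "", type)
    out[[col]] <- switch(base,
      num  = vapply(vals, function(v) as.numeric(v), numeric(1)),
      bool = vapply(vals, function(v) as.logical(v), logical(1)),
      vapply(vals, function(v) as.character(if (is.na(v)[1]) NA_character_ else v), character(1))
    )
  }
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  if (template == "labs") hf_check_labs(df)
  df
}

hf_check_labs <- function(df) {
  for (i in seq_len(nrow(df))) {
    codes <- HF_LOINC[[df$analyte[i]]]
    if (!df$loinc[i] %in% codes)
      stop(sprintf("row %d: LOINC '%s' inconsistent with analyte '%s'",
                   i, df$loinc[i], df$analyte[i]), call. = FALSE)
    want <- HF_LAB_UNITS[[df$analyte[i]]]
    unit <- sub("µ", "u", df$unit[i])  # accept micro sign spelling
    if (unit != want)
      stop(sprintf("row %d: unit '%s' not the fixed unit '%s' for %s",
                   i, df$unit[i], want, df$analyte[i]), call. = FALSE)
  }
  invisible(df)
}

#' Write one template table in the canonical dialect
#'
#' @param df a typed template `data.frame` (as returned by
#'   [read_template_table()] or built by the generator).
#' @param path output file path.
#' @param template template name.
#' @return `path`, invisibly.
#' @export
write_template_table <- function(df, path, template) {
  template <- match.arg(template, HF_TEMPLATES)
  schema <- hf_template_schema(template)
  stopifnot(identical(names(df), names(schema)))
  lines <- paste(names(schema), collapse = ",")
  if (nrow(df)) {
    cells <- vapply(seq_len(nrow(df)), function(i) {
      paste(vapply(names(schema), function(col)
        hf_format_cell(df[[col]][i], schema[[col]]), character(1)),
        collapse = ",")
    }, character(1))
    lines <- c(lines, cells)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Construct a cohort from its six template tables
#'
#' @param enrollment,personal,history,medication,echo,labs typed template
#'   data frames (empty data frames with the right columns are allowed).
#' @return an object of class `hf_cohort`.
#' @export
hf_cohort <- function(enrollment, personal, history, medication, echo, labs) {
  tabs <- list(enrollment = enrollment, personal = personal, history = history,
               medication = medication, echo = echo, labs = labs)
  for (tpl in HF_TEMPLATES) {
    stopifnot(identical(names(tabs[[tpl]]), names(hf_template_schema(tpl))))
  }
  structure(tabs, class = "hf_cohort")
}

empty_template <- function(template) {
  schema <- hf_template_schema(template)
  out <- lapply(schema, function(type) {
    switch(sub(":.*$", "", type), num = numeric(0), bool = logical(0),
           character(0))
  })
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @export
print.hf_cohort <- function(x, ...) {
  cat("<hf_cohort>", nrow(x$enrollment), "patients at",
      length(unique(x$enrollment$site)), "site(s)\n")
  for (tpl in HF_TEMPLATES) cat(sprintf("  %-10s %d records\n", tpl, nrow(x[[tpl]])))
  invisible(x)
}

#' Read a cohort from a directory of template CSV files
#'
#' Expects files `enrollment.csv`, `personal.csv`, `history.csv`,
#' `medication.csv`, `echo.csv`, `labs.csv`.
#'
#' @param dir directory path.
#' @return an `hf_cohort`.
#' @export
read_cohort <- function(dir) {
  tabs <- lapply(HF_TEMPLATES, function(tpl)
    read_template_table(file.path(dir, paste0(tpl, ".csv")), tpl))
  names(tabs) <- HF_TEMPLATES
  do.call(hf_cohort, tabs)
}

#' Write a cohort as template CSV files
#'
#' @param cohort an `hf_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "hf_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tpl in HF_TEMPLATES)
    write_template_table(cohort[[tpl]], file.path(dir, paste0(tpl, ".csv")), tpl)
  invisible(dir)
}

#' Referential-integrity validation of a cohort
#'
#' Report-only: lists records whose patient is not enrolled (orphans),
#' patients with more than one enrollment, and laboratory unit/LOINC
#' mismatches. The cohort itself is never modified.
#'
#' @param cohort an `hf_cohort`.
#' @return a `data.frame` with columns `issue`, `template`, `site`,
#'   `local_id`, `detail`; zero rows for a consistent cohort.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "hf_cohort"))
  entries <- list()
  add <- function(issue, template, site, local_id, detail) {
    entries[[length(entries) + 1L]] <<- data.frame(
      issue = issue, template = template, site = site, local_id = local_id,
      detail = detail, stringsAsFactors = FALSE)
  }
  enr_key <- paste(cohort$enrollment$site, cohort$enrollment$local_id, sep = "\r")
  dup <- unique(enr_key[duplicated(enr_key)])
  for (k in dup) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    add("duplicate_enrollment", "enrollment", parts[1], parts[2],
        sprintf("%d enrollments", sum(enr_key == k)))
  }
  for (tpl in setdiff(HF_TEMPLATES, "enrollment")) {
    tab <- cohort[[tpl]]
    if (!nrow(tab)) next
    key <- paste(tab$site, tab$local_id, sep = "\r")
    orphan <- !(key %in% enr_key)
    for (i in which(orphan))
      add("orphan_record", tpl, tab$site[i], tab$local_id[i], "patient not enrolled")
  }
  labs <- cohort$labs
  for (i in seq_len(nrow(labs))) {
    want <- HF_LAB_UNITS[[labs$analyte[i]]]
    unit <- sub("µ", "u", labs$unit[i])
    if (unit != want)
      add("unit_mismatch", "labs", labs$site[i], labs$local_id[i],
          sprintf("%s in '%s', expected '%s'", labs$analyte[i], labs$unit[i], want))
    if (!labs$loinc[i] %in% HF_LOINC[[labs$analyte[i]]])
      add("loinc_mismatch", "labs", labs$site[i], labs$local_id[i],
          sprintf("LOINC %s for analyte %s", labs$loinc[i], labs$analyte[i]))
  }
  if (length(entries)) do.call(rbind, entries) else
    data.frame(issue = character(0), template = character(0),
               site = character(0), local_id = character(0),
               detail = character(0), stringsAsFactors = FALSE)
}

#' Pseudonymize a cohort for sharing
#'
#' Replaces every local patient identifier by a site-scoped pseudonym
#' (site letter(s) followed by a 1-based counter, e.g. `G1`, `H2`),
#' assigned deterministically in sorted order of the original identifiers.
#' The key table linking original identifiers to pseudonyms is returned
#' separately and is never embedded in the shared tables. Applying the
#' operation to an already-pseudonymized cohort is the identity.
#'
#' @param cohort an `hf_cohort`.
#' @param site_letter_map named character vector mapping site codes to the
#'   pseudonym letter prefix; defaults to the site codes themselves.
#' @return a list with elements `cohort` (pseudonymized) and `key`
#'   (`data.frame` with columns `site`, `local_id`, `pseudonym`).
#' @export
pseudonymize <- function(cohort, site_letter_map = NULL) {
  stopifnot(inherits(cohort, "hf_cohort"))
  sites <- unique(cohort$enrollment$site)
  if (is.null(site_letter_map)) {
    site_letter_map <- stats::setNames(sites, sites)
  }
  missing_sites <- setdiff(sites, names(site_letter_map))
  if (length(missing_sites))
    stop(sprintf("pseudonymize: no letter mapping for site(s): %s",
                 paste(missing_sites, collapse = ", ")), call. = FALSE)
  key_rows <- list()
  lookup <- list()  # per site: named vector old -> new
  for (s in sites) {
    letter <- site_letter_map[[s]]
    ids <- sort(unique(cohort$enrollment$local_id[cohort$enrollment$site == s]))
    if (length(ids) && all(grepl(paste0("^", letter, "[0-9]+$"), ids))) {
      new_ids <- ids  # already pseudonymized: idempotent
    } else {
      new_ids <- paste0(letter, seq_along(ids))
    }
    lookup[[s]] <- stats::setNames(new_ids, ids)
    if (length(ids))
      key_rows[[s]] <- data.frame(site = s, local_id = ids, pseudonym = new_ids,
                                  stringsAsFactors = FALSE)
  }
  out <- cohort
  for (tpl in HF_TEMPLATES) {
    tab <- out[[tpl]]
    if (!nrow(tab)) next
    for (i in seq_len(nrow(tab))) {
      m <- lookup[[tab$site[i]]]
      if (!is.null(m) && tab$local_id[i] %in% names(m))
        tab$local_id[i] <- m[[tab$local_id[i]]]
    }
    out[[tpl]] <- tab
  }
  key <- if (length(key_rows)) do.call(rbind, c(key_rows, make.row.names = FALSE)) else
    data.frame(site = character(0), local_id = character(0),
               pseudonym = character(0), stringsAsFactors = FALSE)
  list(cohort = out, key = key)
}
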
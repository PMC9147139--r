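#' Plausibility limits for continuous variables
#'
#' Routine-care records contain occasional implausible entries (unit slips,
#' typos) that a score's boundary clipping would silently pull to a clip
#' bound instead of rejecting. The plausibility check therefore runs
#' *before* score calculation: any value outside its admissible range is
#' converted to missing and reported. Bounds are inclusive — a boundary
#' value is admissible. The HF-duration upper bound is dynamic: the
#' patient's own age in years times 12 (a patient cannot have had heart
#' failure for longer than their lifetime).
#'
#' @param path optional path to a limits JSON file; defaults to the
#'   packaged transcription.
#' @return an object of class `hf_plausibility_limits`: list with element
#'   `static` (`data.frame` of `variable`, `lower`, `upper`, `unit`) and
#'   element `hf_duration` (`lower`, `upper_per_age_year`, `unit`).
#' @export
default_limits <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "plausibility_limits.json",
                        package = "hfscores", mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lim <- structure(list(static = as.data.frame(raw$static),
                        hf_duration = raw$hf_duration),
                   class = "hf_plausibility_limits")
  with(lim$static, stopifnot(all(lower <= upper)))
  lim
}

#' Apply plausibility checks to a harmonized table
#'
#' Every continuous value outside its admissible range is replaced by `NA`
#' and one report entry is written naming the patient, the variable, the
#' offending value and the violated bound. In-range values are untouched,
#' so the operation is idempotent. When `hf_duration` is set to missing its
#' derived indicator `hf_duration_ge_18` is cleared as well. If a patient's
#' age is missing (or itself implausible), the dynamic HF-duration upper
#' bound cannot be evaluated; the duration value is then retained and a
#' warning entry logged.
#'
#' @param table a harmonized patient table (see [build_harmonized()]).
#' @param limits an `hf_plausibility_limits` object; default the packaged one.
#' @return list with elements `table` (cleaned), `report` (`data.frame`:
#'   `site`, `local_id`, `variable`, `value`, `bound`, `limit`, `action`)
#'   and `warnings` (`data.frame` of unevaluable-bound notices).
#' @export
apply_plausibility <- function(table, limits = default_limits()) {
  stopifnot(inherits(limits, "hf_plausibility_limits"))
  rep_rows <- list()
  warn_rows <- list()
  flag <- function(i, var, value, bound, limit) {
    rep_rows[[length(rep_rows) + 1L]] <<- data.frame(
      site = table$site[i], local_id = table$local_id[i], variable = var,
      value = value, bound = bound, limit = limit, action = "set_missing",
      stringsAsFactors = FALSE)
  }

  for (r in seq_len(nrow(limits$static))) {
    var <- limits$static$variable[r]
    lo <- limits$static$lower[r]; hi <- limits$static$upper[r]
    if (!var %in% names(table)) next
    v <- table[[var]]
    bad_lo <- !is.na(v) & v < lo
    bad_hi <- !is.na(v) & v > hi
    for (i in which(bad_lo)) flag(i, var, v[i], "lower", lo)
    for (i in which(bad_hi)) flag(i, var, v[i], "upper", hi)
    table[[var]][bad_lo | bad_hi] <- NA_real_
  }

  # dynamic HF-duration bound, evaluated against the cleaned age
  hd <- limits$hf_duration
  v <- table$hf_duration
  age <- table$age
  for (i in seq_len(nrow(table))) {
    if (is.na(v[i])) next
    if (v[i] < hd$lower) {
      flag(i, "hf_duration", v[i], "lower", hd$lower)
      table$hf_duration[i] <- NA_real_
      table$hf_duration_ge_18[i] <- NA
    } else if (is.na(age[i])) {
      warn_rows[[length(warn_rows) + 1L]] <- data.frame(
        site = table$site[i], local_id = table$local_id[i],
        variable = "hf_duration", value = v[i],
        note = "age missing: dynamic upper bound unevaluable, value retained",
        stringsAsFactors = FALSE)
    } else if (v[i] > age[i] * hd$upper_per_age_year) {
      flag(i, "hf_duration", v[i], "upper", age[i] * hd$upper_per_age_year)
      table$hf_duration[i] <- NA_real_
      table$hf_duration_ge_18[i] <- NA
    }
  }

  empty <- data.frame(site = character(0), local_id = character(0),
                      variable = character(0), value = numeric(0),
                      bound = character(0), limit = numeric(0),
                      action = character(0), stringsAsFactors = FALSE)
  report <- if (length(rep_rows)) do.call(rbind, c(rep_rows, make.row.names = FALSE)) else empty
  warnings <- if (length(warn_rows)) do.call(rbind, c(warn_rows, make.row.names = FALSE)) else
    data.frame(site = character(0), local_id = character(0),
               variable = character(0), value = numeric(0),
               note = character(0), stringsAsFactors = FALSE)
  list(table = table, report = report, warnings = warnings)
}
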
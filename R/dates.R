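#' Partial-precision calendar dates
#'
#' Routine clinical data frequently carries dates at reduced precision: for
#' privacy reasons many records hold only the year of birth, and the first
#' diagnosis of heart failure is often documented as a year only. `hf_date`
#' represents a date together with its precision (`"day"`, `"month"` or
#' `"year"`), so that precision survives I/O and completion to a full
#' calendar date is an explicit, logged step (see [complete_date()]).
#'
#' The serialized form is the ISO-8601 prefix whose length encodes the
#' precision: `"1950"` (year), `"1950-03"` (month), `"1950-03-20"` (day).
#'
#' @param year integer year.
#' @param month optional integer month (1-12); required for `"month"` and
#'   `"day"` precision.
#' @param day optional integer day of month; required for `"day"` precision.
#' @return An object of class `hf_date` with fields `year`, `month`, `day`
#'   and `precision`.
#' @examples
#' hf_date(1950)                # year precision
#' hf_date(1950, 3)             # month precision
#' hf_date(1950, 3, 20)         # day precision
#' @export
hf_date <- function(year, month = NULL, day = NULL) {
  year <- as.integer(year)
  if (is.na(year)) stop("hf_date: year must be an integer", call. = FALSE)
  if (!is.null(day) && is.null(month))
    stop("hf_date: day given without month", call. = FALSE)
  precision <- if (!is.null(day)) "day" else if (!is.null(month)) "month" else "year"
  if (!is.null(month)) {
    month <- as.integer(month)
    if (is.na(month) || month < 1L || month > 12L)
      stop("hf_date: month out of range", call. = FALSE)
  }
  if (!is.null(day)) {
    day <- as.integer(day)
    # validate against the real calendar (leap years included)
    probe <- tryCatch(as.Date(sprintf("%04d-%02d-%02d", year, month, day)),
                      error = function(e) as.Date(NA))
    if (is.na(probe) || as.integer(format(probe, "%d")) != day)
      stop("hf_date: not a valid calendar date", call. = FALSE)
  }
  structure(list(year = year, month = month, day = day, precision = precision),
            class = "hf_date")
}

#' @export
print.hf_date <- function(x, ...) {
  cat("<hf_date ", format_hf_date(x), " (", x$precision, ")>\n", sep = "")
  invisible(x)
}

#' Parse an ISO-8601 prefix into an `hf_date`
#'
#' The token shape determines the precision: 4 characters = year,
#' 7 = month, 10 = day.
#'
#' @param x character scalar or vector of date tokens; `""` and `NA` yield
#'   `NA` entries (as a list element `NULL` for scalars).
#' @return For a single token, an `hf_date` (or `NULL` for missing); for a
#'   vector, a list of such.
#' @export
parse_hf_date <- function(x) {
  parse1 <- function(tok) {
    if (is.na(tok) || !nzchar(tok)) return(NULL)
    if (grepl("^\\d{4}$", tok)) {
      hf_date(as.integer(tok))
    } else if (grepl("^\\d{4}-\\d{2}$", tok)) {
      hf_date(as.integer(substr(tok, 1, 4)), as.integer(substr(tok, 6, 7)))
    } else if (grepl("^\\d{4}-\\d{2}-\\d{2}$", tok)) {
      hf_date(as.integer(substr(tok, 1, 4)), as.integer(substr(tok, 6, 7)),
              as.integer(substr(tok, 9, 10)))
    } else {
      stop(sprintf("unparseable date token '%s'", tok), call. = FALSE)
    }
  }
  if (length(x) == 1L) parse1(x) else lapply(x, parse1)
}

#' Serialize an `hf_date` preserving precision
#'
#' @param d an `hf_date`, or `NULL`/`NA` (serialized as `""`).
#' @return character scalar: `"YYYY"`, `"YYYY-MM"` or `"YYYY-MM-DD"`.
#' @export
format_hf_date <- function(d) {
  if (is.null(d) || (length(d) == 1L && is.na(d)[1])) return("")
  stopifnot(inherits(d, "hf_date"))
  switch(d$precision,
         year  = sprintf("%04d", d$year),
         month = sprintf("%04d-%02d", d$year, d$month),
         day   = sprintf("%04d-%02d-%02d", d$year, d$month, d$day))
}

#' Complete a partial date to a full calendar date
#'
#' Year-precision dates complete to July 1st of that year (the mid-year
#' convention used when only the year of birth or of HF onset is known).
#' Month-precision dates complete to the 15th, the analogous mid-period
#' choice. Day-precision dates are returned unchanged.
#'
#' @param d an `hf_date`.
#' @return a `Date`.
#' @export
complete_date <- function(d) {
  stopifnot(inherits(d, "hf_date"))
  switch(d$precision,
         year  = as.Date(sprintf("%04d-07-01", d$year)),
         month = as.Date(sprintf("%04d-%02d-15", d$year, d$month)),
         day   = as.Date(sprintf("%04d-%02d-%02d", d$year, d$month, d$day)))
}

#' Age in completed years at a reference date
#'
#' Birthday arithmetic on the completed birth date: the age is the number of
#' whole years elapsed, i.e. it increments on each birthday.
#'
#' @param birth an `hf_date` (possibly year-precision) or a `Date`.
#' @param reference a `Date`.
#' @return integer age in completed years.
#' @export
derive_age <- function(birth, reference) {
  b <- if (inherits(birth, "hf_date")) complete_date(birth) else as.Date(birth)
  reference <- as.Date(reference)
  if (b > reference) stop("derive_age: birth date after reference date", call. = FALSE)
  elapsed_whole_months(b, reference) %/% 12L
}

#' Whole elapsed months between two dates
#'
#' `12 * (year difference) + (month difference)`, minus one when the
#' day-of-month of `to` has not yet reached the day-of-month of `from`
#' (mirrors completed-birthday age arithmetic).
#'
#' @param from,to `Date` scalars with `from <= to`.
#' @return integer number of whole months.
#' @export
elapsed_whole_months <- function(from, to) {
  from <- as.Date(from); to <- as.Date(to)
  if (from > to) stop("elapsed_whole_months: from after to", call. = FALSE)
  fy <- as.integer(format(from, "%Y")); fm <- as.integer(format(from, "%m"))
  fd <- as.integer(format(from, "%d"))
  ty <- as.integer(format(to, "%Y")); tm <- as.integer(format(to, "%m"))
  td <- as.integer(format(to, "%d"))
  12L * (ty - fy) + (tm - fm) - as.integer(td < fd)
}
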
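#' Load and validate a declarative score definition
#'
#' A score definition is a JSON file describing either an additive integer
#' points score (`method = "points_table"`: per-variable points rules, with
#' optional stratification of one variable's bands by another variable, and
#' an integer-score to probability lookup per horizon) or a Cox
#' linear-predictor survival score (`method = "cox_lp"`: per-variable
#' coefficient terms, baseline survival per horizon, a centering constant,
#' and per-variable imputation reference values). All structural invariants
#' are checked at load time: band rules must cover the real line without
#' gaps or overlaps, the risk lookup must be monotone non-decreasing over a
#' contiguous integer domain, baseline survivals must lie in (0, 1] and be
#' non-increasing with the horizon.
#'
#' The package ships two definitions under
#' `system.file("extdata", "scores", package = "hfscores")`:
#' `maggic.json` (points score, complete data required) and
#' `bcn_biohf_v1_synthetic.json` (Cox score with imputation; synthetic
#' placeholder coefficients, see its description field).
#'
#' @param path path to a definition JSON file.
#' @return an object of class `hf_score_definition`.
#' @export
load_score_definition <- function(path) {
  def <- jsonlite::read_json(path, simplifyVector = FALSE)
  fail <- function(msg) stop(sprintf("score definition '%s': %s",
                                     basename(path), msg), call. = FALSE)
  if (is.null(def$score_id)) fail("missing score_id")
  if (!identical(def$method, "points_table") && !identical(def$method, "cox_lp"))
    fail("method must be points_table or cox_lp")
  def$horizons <- as.numeric(unlist(def$horizons))
  if (!length(def$horizons)) fail("no horizons")
  def$completeness <- match.arg(def$completeness,
                                c("require_complete", "allow_imputation"))
  vars <- vapply(def$variables, function(v) v$name, character(1))
  if (anyDuplicated(vars)) fail("duplicate variable declarations")
  for (v in def$variables) {
    has_clip <- !is.null(v$clip_lower) || !is.null(v$clip_upper)
    if (has_clip && !identical(v$kind, "continuous"))
      fail(sprintf("clip bounds on non-continuous variable '%s'", v$name))
    if (!is.null(v$clip_lower) && !is.null(v$clip_upper) &&
        v$clip_lower > v$clip_upper)
      fail(sprintf("clip_lower > clip_upper for '%s'", v$name))
  }

  check_bands <- function(bands, var, value_field = "points") {
    lo <- vapply(bands, function(b) if (is.null(b$min)) -Inf else as.numeric(b$min), numeric(1))
    hi <- vapply(bands, function(b) if (is.null(b$max)) Inf else as.numeric(b$max), numeric(1))
    ord <- order(lo)
    lo <- lo[ord]; hi <- hi[ord]
    if (lo[1] != -Inf || hi[length(hi)] != Inf)
      fail(sprintf("bands for '%s' do not cover the real line", var))
    if (any(lo >= hi)) fail(sprintf("empty band for '%s'", var))
    if (length(lo) > 1L && any(hi[-length(hi)] != lo[-1]))
      fail(sprintf("gap or overlap in bands for '%s'", var))
    for (b in bands)
      if (is.null(b[[value_field]])) fail(sprintf("band without %s for '%s'", value_field, var))
    invisible(TRUE)
  }

  if (def$method == "points_table") {
    rule_vars <- vapply(def$points, function(r) r$variable, character(1))
    if (!all(rule_vars %in% vars)) fail("points rule references undeclared variable")
    for (r in def$points) {
      switch(r$type,
        bands = check_bands(r$bands, r$variable),
        stratified_bands = {
          if (!r$stratifier %in% vars) fail("undeclared stratifier")
          check_bands(r$strata, r$variable, value_field = "bands")
          for (s in r$strata) check_bands(s$bands, r$variable)
        },
        categorical = if (!length(r$map)) fail("empty categorical map"),
        boolean = if (is.null(r$true) || is.null(r$false))
          fail("boolean rule needs true/false points"),
        fail(sprintf("unknown rule type '%s'", r$type)))
    }
    rl <- def$risk_lookup
    pts <- as.integer(unlist(rl$points))
    if (any(diff(pts) != 1L)) fail("risk lookup domain not contiguous integers")
    for (h in names(rl$risk)) {
      p <- as.numeric(unlist(rl$risk[[h]]))
      if (length(p) != length(pts)) fail("risk lookup length mismatch")
      if (any(p < 0 | p > 1)) fail("risk outside [0,1]")
      if (any(diff(p) < 0)) fail("risk lookup not monotone non-decreasing")
    }
    def$risk_lookup$points <- pts
    def$risk_lookup$risk <- lapply(rl$risk, function(p) as.numeric(unlist(p)))
  } else {
    term_vars <- vapply(def$terms, function(t) t$variable, character(1))
    if (!all(term_vars %in% vars)) fail("cox term references undeclared variable")
    for (t in def$terms) {
      switch(t$type,
        linear = if (is.null(t$coef)) fail("linear term without coef"),
        categorical = if (!length(t$map)) fail("empty categorical term map"),
        boolean = if (is.null(t$true) || is.null(t$false))
          fail("boolean term needs true/false coefs"),
        bands = check_bands(t$bands, t$variable, value_field = "coef"),
        fail(sprintf("unknown term type '%s'", t$type)))
    }
    s0 <- vapply(as.character(def$horizons), function(h) {
      v <- def$baseline_survival[[h]]
      if (is.null(v)) fail(sprintf("no baseline survival for horizon %s", h))
      as.numeric(v)
    }, numeric(1))
    if (any(s0 <= 0 | s0 > 1)) fail("baseline survival outside (0,1]")
    if (any(diff(s0[order(def$horizons)]) > 0))
      fail("baseline survival must be non-increasing in the horizon")
    if (is.null(def$center)) fail("missing centering constant")
  }
  structure(def, class = "hf_score_definition")
}

#' @export
print.hf_score_definition <- function(x, ...) {
  cat(sprintf("<score definition '%s'> method=%s horizons=%s policy=%s\n",
              x$score_id, x$method, paste(x$horizons, collapse = "/"),
              x$completeness))
  invisible(x)
}

score_required_vars <- function(def) {
  vapply(def$variables, function(v) v$name, character(1))
}

#' Clip score inputs to the definition's boundaries
#'
#' Scores enforce their own upper and lower boundaries on continuous
#' inputs: values outside `[clip_lower, clip_upper]` are set to the nearer
#' boundary. This is distinct from the plausibility check, which runs
#' earlier and converts implausible values to missing rather than clipping
#' them. Clipping is idempotent and per-variable, hence order-independent.
#'
#' @param def an `hf_score_definition`.
#' @param row a one-row `data.frame` (or named list) of harmonized values.
#' @return list with `row` (clipped) and `log` (`data.frame` of clip events:
#'   `variable`, `from`, `to`).
#' @export
clip_inputs <- function(def, row) {
  log_rows <- list()
  for (v in def$variables) {
    if (!identical(v$kind, "continuous")) next
    x <- row[[v$name]]
    if (is.null(x) || is.na(x)) next
    clipped <- x
    if (!is.null(v$clip_lower) && x < v$clip_lower) clipped <- v$clip_lower
    if (!is.null(v$clip_upper) && x > v$clip_upper) clipped <- v$clip_upper
    if (clipped != x) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        variable = v$name, from = x, to = clipped, stringsAsFactors = FALSE)
      row[[v$name]] <- clipped
    }
  }
  log <- if (length(log_rows)) do.call(rbind, c(log_rows, make.row.names = FALSE)) else
    data.frame(variable = character(0), from = numeric(0), to = numeric(0),
               stringsAsFactors = FALSE)
  list(row = row, log = log)
}

band_value <- function(bands, x, value_field = "points") {
  for (b in bands) {
    lo <- if (is.null(b$min)) -Inf else as.numeric(b$min)
    hi <- if (is.null(b$max)) Inf else as.numeric(b$max)
    if (x >= lo && x < hi) return(b[[value_field]])
  }
  stop("internal: value outside band coverage", call. = FALSE)
}

rule_points <- function(rule, row) {
  x <- row[[rule$variable]]
  if (is.null(x) || is.na(x)) return(NA_integer_)
  p <- switch(rule$type,
    bands = band_value(rule$bands, x),
    stratified_bands = {
      s <- row[[rule$stratifier]]
      if (is.null(s) || is.na(s)) return(NA_integer_)
      band_value(rule$strata, s, value_field = "bands") |>
        band_value(x)
    },
    categorical = {
      m <- rule$map[[as.character(x)]]
      if (is.null(m)) stop(sprintf("no points mapping for %s = %s",
                                   rule$variable, x), call. = FALSE)
      m
    },
    boolean = if (isTRUE(as.logical(x))) rule$true else rule$false)
  as.integer(p)
}

#' Total points of an additive points score
#'
#' @param def an `hf_score_definition` with `method = "points_table"`.
#' @param row a clipped one-row `data.frame` or named list.
#' @return list with `points` (integer, `NA` when not computable) and
#'   `missing` (character vector of missing required variables).
#' @export
points_score <- function(def, row) {
  stopifnot(def$method == "points_table")
  req <- score_required_vars(def)
  miss <- req[vapply(req, function(v) is.null(row[[v]]) || is.na(row[[v]]), logical(1))]
  if (length(miss)) return(list(points = NA_integer_, missing = unname(miss)))
  total <- sum(vapply(def$points, rule_points, integer(1), row = row))
  list(points = as.integer(total), missing = character(0))
}

#' Look up the mortality probability for an integer score
#'
#' Exact table lookup, no interpolation. When the definition declares
#' `clamp_points`, scores beyond the published lookup domain use the
#' nearest end row (the published table plateaus); otherwise an
#' out-of-domain score raises an internal-consistency error.
#'
#' @param def an `hf_score_definition` with `method = "points_table"`.
#' @param points integer total score.
#' @param horizon horizon in years (must be one of the definition's).
#' @return probability.
#' @export
points_to_risk <- function(def, points, horizon) {
  stopifnot(def$method == "points_table")
  h <- as.character(horizon)
  if (!h %in% names(def$risk_lookup$risk))
    stop(sprintf("no risk lookup for horizon %s", h), call. = FALSE)
  dom <- def$risk_lookup$points
  if (points < min(dom) || points > max(dom)) {
    if (isTRUE(def$clamp_points)) {
      points <- min(max(points, min(dom)), max(dom))
    } else {
      stop(sprintf("points %d outside lookup domain [%d, %d]",
                   points, min(dom), max(dom)), call. = FALSE)
    }
  }
  def$risk_lookup$risk[[h]][match(points, dom)]
}

#' Fill missing imputable variables with reference values
#'
#' Only meaningful for definitions with `completeness = "allow_imputation"`.
#' Each missing variable that has a reference value in the definition is
#' replaced by it; variables without a reference stay missing (and make the
#' score not computable downstream). References are cohort-independent so
#' that a patient's score never depends on who else was scored.
#'
#' @param def an `hf_score_definition`.
#' @param row a clipped one-row `data.frame` or named list.
#' @return list with `row` (references filled) and `imputed` (character
#'   vector naming every substitution).
#' @export
impute <- function(def, row) {
  stopifnot(def$completeness == "allow_imputation")
  imputed <- character(0)
  for (v in names(def$imputation)) {
    x <- row[[v]]
    if (is.null(x) || is.na(x)) {
      row[[v]] <- def$imputation[[v]]
      imputed <- c(imputed, v)
    }
  }
  list(row = row, imputed = imputed)
}

cox_lp <- function(def, row) {
  sum(vapply(def$terms, function(t) {
    x <- row[[t$variable]]
    if (is.null(x) || is.na(x)) return(NA_real_)
    switch(t$type,
      linear = as.numeric(t$coef) * as.numeric(x),
      categorical = {
        m <- t$map[[as.character(x)]]
        if (is.null(m)) stop(sprintf("no coefficient for %s = %s",
                                     t$variable, x), call. = FALSE)
        as.numeric(m)
      },
      boolean = as.numeric(if (isTRUE(as.logical(x))) t$true else t$false),
      bands = as.numeric(band_value(t$bands, as.numeric(x), value_field = "coef")))
  }, numeric(1)))
}

#' Cox linear-predictor mortality risk
#'
#' `risk = 1 - S0(horizon) ^ exp(LP - center)` where `LP` is the sum of the
#' definition's coefficient terms evaluated on the (complete, clipped,
#' possibly imputed) row, and `S0` the baseline survival at the horizon.
#'
#' @param def an `hf_score_definition` with `method = "cox_lp"`.
#' @param row a complete clipped one-row `data.frame` or named list.
#' @param horizon horizon in years.
#' @return probability in `[0, 1]`, or `NA` if any term variable is missing.
#' @export
cox_risk <- function(def, row, horizon) {
  stopifnot(def$method == "cox_lp")
  h <- as.character(horizon)
  s0 <- def$baseline_survival[[h]]
  if (is.null(s0)) stop(sprintf("no baseline survival for horizon %s", h), call. = FALSE)
  lp <- cox_lp(def, row)
  if (is.na(lp)) return(NA_real_)
  1 - as.numeric(s0)^exp(lp - as.numeric(def$center))
}

score_one <- function(def, row, allow_imputation) {
  cl <- clip_inputs(def, row)
  row <- cl$row
  imputed <- character(0)
  if (allow_imputation && def$completeness == "allow_imputation") {
    im <- impute(def, row)
    row <- im$row
    imputed <- im$imputed
  }
  req <- score_required_vars(def)
  miss <- req[vapply(req, function(v) is.null(row[[v]]) || is.na(row[[v]]), logical(1))]
  risks <- stats::setNames(rep(NA_real_, length(def$horizons)),
                           paste0("risk_", def$horizons, "y"))
  if (length(miss)) {
    return(list(points = NA_integer_, risks = risks, imputed = imputed,
                status = "not_computable",
                reason = paste("missing:", paste(miss, collapse = ","))))
  }
  if (def$method == "points_table") {
    ps <- points_score(def, row)
    for (h in def$horizons)
      risks[[paste0("risk_", h, "y")]] <- points_to_risk(def, ps$points, h)
    points <- ps$points
  } else {
    for (h in def$horizons)
      risks[[paste0("risk_", h, "y")]] <- cox_risk(def, row, h)
    points <- NA_integer_
  }
  list(points = points, risks = risks, imputed = imputed,
       status = if (length(imputed)) "imputed" else "complete", reason = NA_character_)
}

#' Compute scores for a whole harmonized cohort table
#'
#' Produces one result row per patient, score and variant. Scores that
#' require complete data get a single `"complete"` variant; scores that
#' allow imputation additionally get an `"imputed"` variant (reference
#' values substituted for missing imputable inputs), matching the dual
#' complete-case / with-imputation reporting used when comparing site
#' coverage. For patients with complete data the two variants agree
#' exactly.
#'
#' @param defs list of `hf_score_definition` objects.
#' @param table harmonized (and plausibility-cleaned) patient table.
#' @return `data.frame` with columns `site`, `local_id`, `score_id`,
#'   `variant`, `total_points`, `risk_1y`, `risk_2y`, `risk_3y`,
#'   `imputed_variables`, `status`, `reason`.
#' @export
compute_cohort_scores <- function(defs, table) {
  if (inherits(defs, "hf_score_definition")) defs <- list(defs)
  out <- list()
  for (def in defs) {
    variants <- if (def$completeness == "allow_imputation")
      c("complete", "imputed") else "complete"
    for (variant in variants) {
      for (i in seq_len(nrow(table))) {
        row <- as.list(table[i, , drop = FALSE])
        res <- score_one(def, row, allow_imputation = variant == "imputed")
        out[[length(out) + 1L]] <- data.frame(
          site = table$site[i], local_id = table$local_id[i],
          score_id = def$score_id, variant = variant,
          total_points = res$points,
          risk_1y = if ("risk_1y" %in% names(res$risks)) res$risks[["risk_1y"]] else NA_real_,
          risk_2y = if ("risk_2y" %in% names(res$risks)) res$risks[["risk_2y"]] else NA_real_,
          risk_3y = if ("risk_3y" %in% names(res$risks)) res$risks[["risk_3y"]] else NA_real_,
          imputed_variables = paste(res$imputed, collapse = ";"),
          status = res$status, reason = res$reason,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Paths of the packaged score definitions
#'
#' @return named character vector with elements `maggic` and
#'   `bcn_biohf_v1_synthetic`.
#' @export
packaged_score_paths <- function() {
  d <- system.file("extdata", "scores", package = "hfscores", mustWork = TRUE)
  c(maggic = file.path(d, "maggic.json"),
    bcn_biohf_v1_synthetic = file.path(d, "bcn_biohf_v1_synthetic.json"))
}
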
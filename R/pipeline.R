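#' Load a pipeline configuration file
#'
#' JSON (always available) or YAML (if the `yaml` package is installed).
#' See [pipeline_config()] for the recognised fields.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a config list (passed through [pipeline_config()]).
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML config requires the 'yaml' package", call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, raw)
}

#' Assemble and validate a pipeline configuration
#'
#' @param mode `"synthetic"` (generate cohorts from site profiles) or
#'   `"files"` (read per-site template CSV directories).
#' @param out_dir output directory for all stage outputs.
#' @param seed integer seed; mandatory in synthetic mode.
#' @param profiles synthetic mode: list of [site_profile()] objects or of
#'   argument lists for it; defaults to [default_study_profiles()] scaled
#'   by `n_scale`.
#' @param n_scale scale factor for the default profiles.
#' @param input_dirs files mode: named (by site) character vector of
#'   directories each holding the six template CSVs.
#' @param score_paths paths of score definition files; defaults to the
#'   packaged MAGGIC and synthetic Barcelona definitions.
#' @param limits_path plausibility limits file; default packaged.
#' @param alpha,n_perm,min_node conditional-tree parameters.
#' @param grow_tree logical; grow the site-origin tree during analysis.
#' @param medication_anchor,default_furosemide_dose,torasemide_factor
#'   harmonization parameters, see [build_harmonized()].
#' @return validated config list of class `hf_pipeline_config`.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"), out_dir,
                            seed = NULL, profiles = NULL, n_scale = 0.2,
                            input_dirs = NULL, score_paths = NULL,
                            limits_path = NULL, alpha = 0.05, n_perm = 999,
                            min_node = 20, grow_tree = FALSE,
                            medication_anchor = "recruitment",
                            default_furosemide_dose = 40,
                            torasemide_factor = 4) {
  mode <- match.arg(mode)
  cfg_err <- function(msg) stop(sprintf("pipeline config: %s", msg), call. = FALSE)
  if (missing(out_dir) || is.null(out_dir)) cfg_err("out_dir is mandatory")
  if (mode == "synthetic") {
    if (is.null(seed)) cfg_err("seed is mandatory in synthetic mode")
    if (is.null(profiles)) profiles <- default_study_profiles(n_scale)
    profiles <- lapply(profiles, function(p)
      if (inherits(p, "hf_site_profile")) p else do.call(site_profile, p))
  } else {
    if (is.null(input_dirs) || !length(input_dirs)) cfg_err("input_dirs is mandatory in files mode")
    absent <- input_dirs[!dir.exists(unlist(input_dirs))]
    if (length(absent)) cfg_err(paste("input dir not found:", paste(absent, collapse = ", ")))
  }
  if (is.null(score_paths)) score_paths <- packaged_score_paths()
  absent <- score_paths[!file.exists(unlist(score_paths))]
  if (length(absent)) cfg_err(paste("score definition not found:", paste(absent, collapse = ", ")))
  if (is.null(limits_path))
    limits_path <- system.file("extdata", "plausibility_limits.json",
                               package = "hfscores", mustWork = TRUE)
  if (!file.exists(limits_path)) cfg_err(paste("limits file not found:", limits_path))
  structure(list(mode = mode, out_dir = out_dir, seed = seed,
                 profiles = profiles, input_dirs = input_dirs,
                 score_paths = unlist(score_paths), limits_path = limits_path,
                 alpha = alpha, n_perm = n_perm, min_node = min_node,
                 grow_tree = grow_tree, medication_anchor = medication_anchor,
                 default_furosemide_dose = default_furosemide_dose,
                 torasemide_factor = torasemide_factor),
            class = "hf_pipeline_config")
}

rbind_fill <- function(dfs) {
  dfs <- dfs[vapply(dfs, nrow, integer(1)) > 0]
  if (!length(dfs)) return(NULL)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (c in setdiff(cols, names(d))) d[[c]] <- NA
    d[cols]
  }))
}

write_stable_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8", eol = "\n")
}

#' Run the full pipeline
#'
#' generate (or read) -> validate -> pseudonymize -> harmonize ->
#' plausibility -> score -> analyze -> report, as one configured, seeded
#' run. All stage outputs are written under `out_dir` with stable file
#' names; the manifest records per-stage row counts, flagged / imputed /
#' not-computable tallies, the resolved configuration and its hash, and
#' the seed. Rerunning with the same configuration and inputs reproduces
#' byte-identical tabular outputs. Any fatal stage error aborts the run
#' with a stage-named message and removes partial outputs.
#'
#' @param config an `hf_pipeline_config` (or list accepted by
#'   [pipeline_config()], or path to a config file).
#' @return the run manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_pipeline_config(config)
  if (!inherits(config, "hf_pipeline_config")) config <- do.call(pipeline_config, config)
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  on_fail <- function(e) {
    if (created) unlink(out_dir, recursive = TRUE)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  manifest <- tryCatch({
    stage <- "acquire"
    cohorts <- if (config$mode == "synthetic") {
      generate_multisite(config$profiles, config$seed)
    } else {
      out <- lapply(config$input_dirs, read_cohort)
      names(out) <- names(config$input_dirs)
      out
    }

    stage <- "validate"
    vreports <- lapply(cohorts, validate_cohort)
    vall <- rbind_fill(vreports)
    writeLines(
      if (is.null(vall) || !nrow(vall)) character(0) else
        vapply(seq_len(nrow(vall)), function(i)
          jsonlite::toJSON(as.list(vall[i, ]), auto_unbox = TRUE), character(1)),
      file.path(out_dir, "validation_report.jsonl"))

    stage <- "pseudonymize"
    keys <- list()
    for (s in names(cohorts)) {
      ps <- pseudonymize(cohorts[[s]])
      cohorts[[s]] <- ps$cohort
      keys[[s]] <- ps$key
    }
    key_dir <- file.path(out_dir, "keys")
    dir.create(key_dir, showWarnings = FALSE)
    key_tab <- rbind_fill(keys)
    write_stable_csv(if (is.null(key_tab)) data.frame() else key_tab,
                     file.path(key_dir, "pseudonym_key.csv"))
    for (s in names(cohorts))
      write_cohort(cohorts[[s]], file.path(out_dir, "sites", s))

    stage <- "harmonize"
    harm_parts <- lapply(cohorts, function(co)
      build_harmonized(co,
                       default_furosemide_dose = config$default_furosemide_dose,
                       torasemide_factor = config$torasemide_factor,
                       medication_anchor = config$medication_anchor))
    harm <- rbind_fill(lapply(harm_parts, `[[`, "table"))
    prep_log <- rbind_fill(lapply(harm_parts, `[[`, "log"))
    if (is.null(prep_log)) prep_log <- data.frame()

    stage <- "plausibility"
    limits <- default_limits(config$limits_path)
    pl <- apply_plausibility(harm, limits)
    harm <- pl$table
    harm <- harm[order(harm$site, harm$local_id), , drop = FALSE]
    out_harm <- harm
    names(out_harm)[names(out_harm) == "local_id"] <- "pseudonym"
    write_stable_csv(out_harm, file.path(out_dir, "harmonized.csv"))
    write_stable_csv(pl$report, file.path(out_dir, "plausibility_report.csv"))
    write_stable_csv(prep_log, file.path(out_dir, "preparation_log.csv"))

    stage <- "score"
    defs <- lapply(config$score_paths, load_score_definition)
    scores <- compute_cohort_scores(defs, harm)
    scores <- scores[order(scores$site, scores$local_id, scores$score_id,
                           scores$variant), , drop = FALSE]
    out_scores <- scores
    names(out_scores)[names(out_scores) == "local_id"] <- "pseudonym"
    write_stable_csv(out_scores, file.path(out_dir, "scores.csv"))

    stage <- "analyze"
    avail <- availability_counts(harm, scores)
    write_stable_csv(avail$items, file.path(out_dir, "availability_items.csv"))
    write_stable_csv(avail$sites, file.path(out_dir, "availability_sites.csv"))
    write_stable_csv(avail$scores, file.path(out_dir, "availability_scores.csv"))
    analysis <- analyze_scores(harm, scores, defs, alpha = config$alpha,
                               n_perm = config$n_perm,
                               min_node = config$min_node,
                               seed = if (is.null(config$seed)) 1 else config$seed,
                               grow_tree = config$grow_tree)
    jsonlite::write_json(analysis$summary, file.path(out_dir, "analysis.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(analysis$tree)) {
      jsonlite::write_json(tree_to_list(analysis$tree),
                           file.path(out_dir, "tree.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      txt <- utils::capture.output(print(analysis$tree))
      writeLines(txt, file.path(out_dir, "tree.txt"))
    }

    stage <- "manifest"
    resolved <- unclass(config)
    resolved$profiles <- lapply(config$profiles, function(p) {
      p$recruitment_window <- format(p$recruitment_window)
      unclass(p)
    })
    cfg_hash <- digest::digest(resolved, algo = "sha256")
    manifest <- list(
      seed = config$seed, config_hash = cfg_hash,
      mode = config$mode,
      sites = names(cohorts),
      counts = list(
        enrolled = nrow(harm),
        validation_issues = if (is.null(vall)) 0L else nrow(vall),
        plausibility_flags = nrow(pl$report),
        preparation_events = nrow(prep_log),
        score_rows = nrow(scores),
        not_computable = sum(scores$status == "not_computable"),
        imputed = sum(scores$status == "imputed"),
        complete = sum(scores$status == "complete")),
      config = resolved)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest
  }, error = on_fail)
  invisible(manifest)
}

#' Cross-site statistical analysis of computed scores
#'
#' Kruskal-Wallis comparison of score values across sites (per score and
#' variant; for points scores the integer total, for Cox scores the 1-year
#' risk), per-site Wilcoxon comparison of imputed-only vs complete-case
#' values, and optionally the site-origin conditional tree grown on the
#' points score's input features plus enrollment status.
#'
#' @param harm cleaned harmonized table.
#' @param scores score results.
#' @param defs list of loaded score definitions.
#' @param alpha,n_perm,min_node,seed tree parameters.
#' @param grow_tree logical.
#' @return list with `summary` (plain list, JSON-ready) and `tree`
#'   (`hf_tree_node` or `NULL`).
#' @export
analyze_scores <- function(harm, scores, defs, alpha = 0.05, n_perm = 999,
                           min_node = 20, seed = 1, grow_tree = FALSE) {
  summary <- list()
  score_value <- function(sub, def) {
    if (def$method == "points_table") sub$total_points else sub$risk_1y
  }
  for (def in defs) {
    for (variant in unique(scores$variant[scores$score_id == def$score_id])) {
      sub <- scores[scores$score_id == def$score_id &
                      scores$variant == variant &
                      scores$status %in% c("complete", "imputed"), ]
      v <- score_value(sub, def)
      entry <- list(score_id = def$score_id, variant = variant,
                    n = sum(!is.na(v)))
      if (length(unique(sub$site[!is.na(v)])) >= 2) {
        kw <- compare_sites_kw(v, sub$site)
        entry$kruskal_wallis <- list(H = kw$statistic, df = kw$df,
                                     p_value = kw$p_value)
      }
      summary$site_comparisons[[length(summary$site_comparisons) + 1L]] <- entry
    }
    # imputed-only vs complete-case, per site (imputation-capable scores)
    if (def$completeness == "allow_imputation") {
      sub <- scores[scores$score_id == def$score_id &
                      scores$variant == "imputed", ]
      for (s in sort(unique(sub$site))) {
        ss <- sub[sub$site == s, ]
        imp <- score_value(ss[ss$status == "imputed", ], def)
        cmp <- score_value(ss[ss$status == "complete", ], def)
        if (length(imp) && length(cmp)) {
          w <- compare_imputed_complete(imp, cmp)
          summary$imputed_vs_complete[[length(summary$imputed_vs_complete) + 1L]] <-
            list(score_id = def$score_id, site = s,
                 n_imputed = length(imp), n_complete = length(cmp),
                 W = w$statistic, p_value = w$p_value,
                 direction = sub("x_higher", "imputed_higher",
                                 sub("y_higher", "complete_higher", w$direction)))
        }
      }
    }
  }
  tree <- NULL
  if (grow_tree && length(unique(harm$site)) >= 2) {
    pts_def <- Filter(function(d) d$method == "points_table", defs)
    feat_names <- if (length(pts_def))
      score_required_vars(pts_def[[1]]) else
      setdiff(hf_harmonized_fields, "furosemide_equiv_dose")
    feats <- harm[, c(feat_names, "status"[!"status" %in% feat_names]),
                  drop = FALSE]
    tree <- grow_conditional_tree(feats, harm$site, alpha = alpha,
                                  n_perm = n_perm, seed = seed,
                                  min_node = min_node)
  }
  list(summary = summary, tree = tree)
}

#' Merge pseudonymized per-site score tables
#'
#' Pools score tables produced by [run_pipeline()] at different sites.
#' Refuses inputs that carry a raw identifier column (`local_id`) — only
#' pseudonymized tables may leave a site — and refuses site-code
#' collisions between inputs.
#'
#' @param inputs character vector of run directories (each containing
#'   `scores.csv`) or a list of score `data.frame`s.
#' @return pooled `data.frame` with a `source` provenance column.
#' @export
merge_sites <- function(inputs) {
  tabs <- lapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    if (is.character(x)) {
      f <- file.path(x, "scores.csv")
      if (!file.exists(f)) stop(sprintf("merge_sites: no scores.csv in %s", x), call. = FALSE)
      tab <- utils::read.csv(f, stringsAsFactors = FALSE)
      tab$source <- x
      tab
    } else {
      x$source <- if (!is.null(names(inputs)[i]) && nzchar(names(inputs)[i]))
        names(inputs)[i] else paste0("input", i)
      x
    }
  })
  for (tab in tabs) {
    if ("local_id" %in% names(tab))
      stop("merge_sites: privacy error: input contains a raw identifier column (local_id)",
           call. = FALSE)
    if (!"pseudonym" %in% names(tab))
      stop("merge_sites: input lacks a pseudonym column", call. = FALSE)
    bad <- !grepl("^[A-Z]+[0-9]+$", tab$pseudonym)
    if (any(bad))
      stop("merge_sites: privacy error: non-pseudonymized identifiers present",
           call. = FALSE)
  }
  site_sets <- lapply(tabs, function(t) unique(t$site))
  all_sites <- unlist(site_sets)
  if (anyDuplicated(all_sites))
    stop("merge_sites: site-code collision between inputs", call. = FALSE)
  do.call(rbind, c(tabs, make.row.names = FALSE))
}
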
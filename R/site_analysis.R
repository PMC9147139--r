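#' Per-item availability accounting
#'
#' Counts, per site and data item, the patients with a usable value after
#' harmonization and plausibility cleaning (a flagged value counts as
#' unavailable), together with per-site enrollment and per-score computed
#' counts. A complete-data score can never be computed for more patients
#' than its least available input item allows.
#'
#' @param table cleaned harmonized table.
#' @param scores score result table from [compute_cohort_scores()]
#'   (optional).
#' @return list with `items` (`data.frame`: `site`, `template`, `item`,
#'   `count`), `sites` (`site`, `enrolled`) and `scores` (`site`,
#'   `score_id`, `variant`, `computed`; empty if no scores given).
#' @export
availability_counts <- function(table, scores = NULL) {
  item_template <- c(
    age = "personal", sex = "personal",
    bmi = "history", systolic_bp = "history", nyha = "history",
    current_smoker = "history", diabetes = "history", copd = "history",
    hf_duration = "history", hf_duration_ge_18 = "history",
    beta_blocker = "medication", acei_arb = "medication",
    statin = "medication", loop_diuretic = "medication",
    furosemide_equiv_dose = "medication",
    lvef = "echo",
    creatinine = "labs", sodium = "labs", hemoglobin = "labs", egfr = "labs")
  sites <- sort(unique(table$site))
  items <- do.call(rbind, lapply(sites, function(s) {
    sub <- table[table$site == s, , drop = FALSE]
    data.frame(site = s, template = unname(item_template),
               item = names(item_template),
               count = vapply(names(item_template), function(it)
                 sum(!is.na(sub[[it]])), integer(1)),
               stringsAsFactors = FALSE)
  }))
  site_tab <- data.frame(site = sites,
                         enrolled = vapply(sites, function(s)
                           sum(table$site == s), integer(1)),
                         stringsAsFactors = FALSE)
  score_tab <- data.frame(site = character(0), score_id = character(0),
                          variant = character(0), computed = integer(0),
                          stringsAsFactors = FALSE)
  if (!is.null(scores) && nrow(scores)) {
    agg <- stats::aggregate(
      computed ~ site + score_id + variant,
      data = transform(scores, computed = as.integer(status %in% c("complete", "imputed"))),
      FUN = sum)
    score_tab <- agg[order(agg$site, agg$score_id, agg$variant), ]
    rownames(score_tab) <- NULL
  }
  list(items = items, sites = site_tab, scores = score_tab)
}

# Kruskal-Wallis H from pre-computed ranks and a group factor (integer codes)
kw_stat <- function(ranks, groups, n_groups, tie_term, n) {
  rs <- rowsum(ranks, groups)
  cnt <- tabulate(groups, nbins = n_groups)
  keep <- cnt > 0
  h <- 12 / (n * (n + 1)) * sum(rs[keep]^2 / cnt[keep]) - 3 * (n + 1)
  denom <- 1 - tie_term
  if (denom <= 0) return(0)
  h / denom
}

#' Kruskal-Wallis comparison of scores across sites
#'
#' Rank-based H statistic with tie correction; the p-value comes from the
#' chi-square approximation with (number of groups - 1) degrees of
#' freedom. Matches `stats::kruskal.test` to numerical precision.
#'
#' @param values numeric vector of scores.
#' @param groups site labels (vector parallel to `values`).
#' @return list with `statistic` (H), `df`, `p_value`, `n`.
#' @export
compare_sites_kw <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- as.character(groups[keep])
  k <- length(unique(groups))
  if (k < 2) stop("compare_sites_kw: need at least 2 groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (n^3 - n)
  g <- match(groups, sort(unique(groups)))
  h <- kw_stat(r, g, k, tie_term, n)
  list(statistic = h, df = k - 1,
       p_value = stats::pchisq(h, k - 1, lower.tail = FALSE), n = n)
}

#' Wilcoxon rank-sum comparison of imputed vs complete scores
#'
#' Unpaired two-sample rank-sum test (normal approximation with tie
#' correction, no continuity correction) with the direction of the median
#' difference reported. Matches
#' `stats::wilcox.test(exact = FALSE, correct = FALSE)`.
#'
#' @param x,y numeric samples (e.g. imputed-only and complete-case scores).
#' @return list with `statistic` (Mann-Whitney W for `x`), `p_value`,
#'   `direction` (`"x_higher"`, `"y_higher"` or `"none"`).
#' @export
compare_imputed_complete <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y))
    stop("compare_imputed_complete: empty sample", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- w - n1 * n2 / 2
  p <- if (sigma2 <= 0) 1 else {
    zz <- z / sqrt(sigma2)
    min(1, 2 * min(stats::pnorm(zz), stats::pnorm(zz, lower.tail = FALSE)))
  }
  mx <- stats::median(x); my <- stats::median(y)
  direction <- if (mx > my) "x_higher" else if (mx < my) "y_higher" else "none"
  list(statistic = w, p_value = p, direction = direction)
}

chisq_stat <- function(f_codes, g_codes, nf, ng) {
  counts <- tabulate((g_codes - 1L) * nf + f_codes, nbins = nf * ng)
  obs <- matrix(counts, nrow = nf, ncol = ng)
  rs <- rowSums(obs); cs <- colSums(obs); n <- sum(obs)
  exp_ <- outer(rs, cs) / n
  ok <- exp_ > 0
  sum((obs[ok] - exp_[ok])^2 / exp_[ok])
}

#' Permutation p-value for the association of one feature with site labels
#'
#' The test statistic is the tie-corrected Kruskal-Wallis H for numeric
#' (continuous or ordinal) features and the Pearson chi-square statistic
#' for categorical features. The p-value is
#' `(1 + #permuted >= observed) / (n_perm + 1)`; a constant feature yields
#' `p = 1` by convention. Deterministic given `seed`.
#'
#' @param feature feature vector (numeric, logical, character or factor).
#' @param labels site labels.
#' @param n_perm number of permutations (>= 99).
#' @param seed integer seed.
#' @return p-value.
#' @export
permutation_association <- function(feature, labels, n_perm = 999, seed = 1) {
  if (n_perm < 99) stop("permutation_association: n_perm must be >= 99", call. = FALSE)
  keep <- !is.na(feature) & !is.na(labels)
  feature <- feature[keep]; labels <- as.character(labels[keep])
  if (length(unique(feature)) < 2 || length(unique(labels)) < 2) return(1)
  g <- match(labels, sort(unique(labels)))
  ng <- max(g)
  n <- length(feature)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))
  if (is.numeric(feature) || is.logical(feature)) {
    r <- rank(as.numeric(feature))
    ties <- table(feature)
    tie_term <- sum(ties^3 - ties) / (n^3 - n)
    obs <- kw_stat(r, g, ng, tie_term, n)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      gp <- g[sample.int(n)]
      if (kw_stat(r, gp, ng, tie_term, n) >= obs - 1e-12) exceed <- exceed + 1L
    }
  } else {
    f <- match(as.character(feature), sort(unique(as.character(feature))))
    nf <- max(f)
    obs <- chisq_stat(f, g, nf, ng)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      gp <- g[sample.int(n)]
      if (chisq_stat(f, gp, nf, ng) >= obs - 1e-12) exceed <- exceed + 1L
    }
  }
  (1 + exceed) / (n_perm + 1)
}

# best binary split of a feature w.r.t. multi-class labels, scored by the
# Pearson chi-square of the induced 2 x k table
best_binary_split <- function(feature, g, ng) {
  ok <- !is.na(feature)
  f <- feature[ok]; gg <- g[ok]
  if (is.numeric(f) || is.logical(f)) {
    u <- sort(unique(as.numeric(f)))
    if (length(u) < 2) return(NULL)
    cuts <- (u[-1] + u[-length(u)]) / 2
    best <- NULL
    for (cut in cuts) {
      left <- as.numeric(f) <= cut
      if (!any(left) || all(left)) next
      s <- chisq_stat(ifelse(left, 1L, 2L), gg, 2L, ng)
      if (is.null(best) || s > best$stat + 1e-12)
        best <- list(type = "numeric", point = cut, stat = s)
    }
    best
  } else {
    lev <- sort(unique(as.character(f)))
    if (length(lev) < 2 || length(lev) > 12) return(NULL)
    idx <- match(as.character(f), lev)
    best <- NULL
    # enumerate proper non-empty level subsets (up to complement symmetry)
    for (mask in seq_len(2^(length(lev) - 1) - 1)) {
      in_left <- as.logical(bitwAnd(mask, 2^(seq_along(lev) - 1)))
      left <- in_left[idx]
      if (!any(left) || all(left)) next
      s <- chisq_stat(ifelse(left, 1L, 2L), gg, 2L, ng)
      if (is.null(best) || s > best$stat + 1e-12)
        best <- list(type = "categorical", left_levels = lev[in_left], stat = s)
    }
    best
  }
}

#' Grow a permutation-based conditional inference tree
#'
#' Recursive partitioning that predicts a patient's site of origin from
#' score features, mirroring the conditional-inference-tree idea: at each
#' node every candidate feature's association with the site labels is
#' tested by a permutation test ([permutation_association()]), the
#' p-values are Bonferroni-adjusted over the features tested at that node,
#' and the node becomes terminal unless the smallest adjusted p-value is
#' at most `alpha` and the node holds at least `min_node` patients. The
#' winning feature is split at the binary cut (numeric midpoint or
#' category subset) maximizing the Pearson chi-square statistic of the
#' induced two-group partition against the site labels. Rows with a
#' missing value on the split variable follow the larger child. Terminal
#' nodes carry the per-site patient proportions. The input is
#' canonically re-ordered before any test, so the tree is invariant to
#' patient order, and all randomness derives from `seed`.
#'
#' @param features `data.frame` of candidate features.
#' @param labels site labels (length `nrow(features)`).
#' @param alpha significance level in (0, 1] for the adjusted node tests.
#' @param n_perm permutations per test.
#' @param seed integer seed.
#' @param min_node minimum node size eligible for splitting.
#' @param max_depth maximum tree depth (root = depth 1).
#' @return the root `hf_tree_node`: nested list with `id`, `n`, `counts`,
#'   `proportions`, and for internal nodes `split`
#'   (`variable`, `type`, `point`/`left_levels`), `p_adj`, `children`.
#' @export
grow_conditional_tree <- function(features, labels, alpha = 0.05,
                                  n_perm = 999, seed = 1, min_node = 20,
                                  max_depth = Inf) {
  if (!(alpha > 0 && alpha <= 1))
    stop("grow_conditional_tree: alpha must be in (0, 1]", call. = FALSE)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("grow_conditional_tree: need at least 2 sites", call. = FALSE)
  stopifnot(nrow(features) == length(labels))
  # canonical row order: patient-order invariance
  ord <- do.call(order, c(unname(as.list(features)), list(labels)))
  features <- features[ord, , drop = FALSE]
  labels <- labels[ord]
  site_levels <- sort(unique(labels))
  g_all <- match(labels, site_levels)
  ng <- length(site_levels)
  node_counter <- 0L
  test_counter <- 0L

  build <- function(rows, depth) {
    node_counter <<- node_counter + 1L
    id <- node_counter
    cnt <- tabulate(g_all[rows], nbins = ng)
    names(cnt) <- site_levels
    node <- list(id = id, n = length(rows), counts = cnt,
                 proportions = cnt / length(rows), terminal = TRUE)
    class(node) <- "hf_tree_node"
    if (length(rows) < min_node || depth >= max_depth ||
        length(unique(g_all[rows])) < 2) return(node)
    # node-level permutation tests, Bonferroni over tested features
    pvals <- rep(NA_real_, ncol(features))
    names(pvals) <- names(features)
    for (j in seq_along(features)) {
      f <- features[rows, j]
      if (sum(!is.na(f)) < 2 || length(unique(f[!is.na(f)])) < 2) next
      test_counter <<- test_counter + 1L
      pvals[j] <- permutation_association(
        f, labels[rows], n_perm = n_perm,
        seed = site_subseed(seed, paste0("node", id, "f", j, "t", test_counter)))
    }
    tested <- sum(!is.na(pvals))
    if (tested == 0) return(node)
    p_adj <- pmin(1, pvals * tested)
    best_j <- which.min(p_adj)
    if (p_adj[best_j] > alpha) return(node)
    split <- best_binary_split(features[rows, best_j], g_all[rows], ng)
    if (is.null(split)) return(node)
    f <- features[rows, best_j]
    left <- if (split$type == "numeric") as.numeric(f) <= split$point else
      as.character(f) %in% split$left_levels
    # missing split values follow the larger child
    nas <- is.na(left)
    if (any(nas)) left[nas] <- sum(left, na.rm = TRUE) >= sum(!left, na.rm = TRUE)
    if (!any(left) || all(left)) return(node)
    node$terminal <- FALSE
    node$split <- c(list(variable = names(features)[best_j]),
                    split[setdiff(names(split), "stat")])
    node$p_adj <- unname(p_adj[best_j])
    node$children <- list(build(rows[left], depth + 1),
                          build(rows[!left], depth + 1))
    node
  }
  build(seq_along(labels), 1)
}

#' @export
print.hf_tree_node <- function(x, indent = "", ...) {
  if (x$terminal) {
    props <- paste(sprintf("%s=%.2f", names(x$proportions), x$proportions),
                   collapse = " ")
    cat(sprintf("%s[%d] terminal n=%d %s\n", indent, x$id, x$n, props))
  } else {
    desc <- if (x$split$type == "numeric")
      sprintf("%s <= %g", x$split$variable, x$split$point) else
      sprintf("%s in {%s}", x$split$variable,
              paste(x$split$left_levels, collapse = ","))
    cat(sprintf("%s[%d] split %s (p_adj=%.4g) n=%d\n", indent, x$id, desc,
                x$p_adj, x$n))
    print(x$children[[1]], indent = paste0(indent, "  "))
    print(x$children[[2]], indent = paste0(indent, "  "))
  }
  invisible(x)
}

#' Serialize a tree to plain lists (for JSON output)
#'
#' @param node an `hf_tree_node`.
#' @return nested list free of S3 classes.
#' @export
tree_to_list <- function(node) {
  out <- list(id = node$id, n = node$n,
              counts = as.list(node$counts),
              proportions = as.list(node$proportions),
              terminal = node$terminal)
  if (!node$terminal) {
    out$split <- node$split
    out$p_adj <- node$p_adj
    out$children <- lapply(node$children, tree_to_list)
  }
  out
}
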
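test_that("Kruskal-Wallis matches the reference implementation", {
  # identical groups: H = 0, p = 1
  r <- compare_sites_kw(c(1, 2, 3, 1, 2, 3), rep(c("A", "B"), each = 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  cases <- list(
    list(v = c(1, 2, 3, 4, 5, 6), g = rep(c("A", "B"), each = 3)),
    list(v = c(2.1, 5.3, 1.1, 0.4, 9.9, 3.3, 2.1, 2.1), g = c("A", "A", "A", "B", "B", "B", "C", "C")),
    list(v = c(rep(1, 5), rep(2, 5), 3, 4), g = rep(c("A", "B", "C"), each = 4)))
  for (cs in cases) {
    mine <- compare_sites_kw(cs$v, cs$g)
    ref <- stats::kruskal.test(cs$v, factor(cs$g))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  set.seed(5)
  for (i in 1:50) {
    v <- round(stats::rnorm(30), sample(0:1, 1))  # induce ties sometimes
    g <- sample(c("A", "B", "C"), 30, replace = TRUE)
    if (length(unique(g)) < 2) next
    mine <- compare_sites_kw(v, g)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_error(compare_sites_kw(1:5, rep("A", 5)), "2 groups")
})

test_that("Wilcoxon rank-sum matches the reference implementation", {
  r <- compare_imputed_complete(1:6, 1:6)
  expect_equal(r$p_value, 1, tolerance = 1e-10)
  expect_equal(r$direction, "none")

  cases <- list(list(x = 1:10, y = 11:20),
                list(x = c(1, 1, 2, 5), y = c(2, 3, 3, 8, 9)),
                list(x = stats::rnorm(12), y = stats::rnorm(15) + 1))
  for (cs in cases) {
    mine <- compare_imputed_complete(cs$x, cs$y)
    ref <- stats::wilcox.test(cs$x, cs$y, exact = FALSE, correct = FALSE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
  expect_equal(compare_imputed_complete(11:20, 1:10)$direction, "x_higher")
  expect_error(compare_imputed_complete(numeric(0), 1:3), "empty")
})

test_that("shifted synthetic sites are detected by the KW test", {
  # two sites with a 2-point score shift, n = 200/site: p < 0.01 nearly always
  hits <- 0L
  for (s in 1:20) {
    set.seed(s)
    v <- c(round(stats::rnorm(200, 20, 4)), round(stats::rnorm(200, 22, 4)))
    g <- rep(c("G", "H"), each = 200)
    if (compare_sites_kw(v, g)$p_value < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("permutation association has the documented conventions", {
  expect_equal(permutation_association(rep(1, 40), rep(c("A", "B"), 20),
                                       n_perm = 99), 1)
  expect_error(permutation_association(1:10, rep(c("A", "B"), 5), n_perm = 10),
               ">= 99")
  # perfectly separating feature: p = 1/(n_perm + 1)
  f <- rep(c(0, 1), each = 50)
  g <- rep(c("A", "B"), each = 50)
  expect_equal(permutation_association(f, g, n_perm = 999, seed = 4), 1 / 1000)
  # deterministic given seed
  set.seed(1); x <- stats::rnorm(60); gg <- sample(c("A", "B", "C"), 60, TRUE)
  p1 <- permutation_association(x, gg, n_perm = 199, seed = 9)
  p2 <- permutation_association(x, gg, n_perm = 199, seed = 9)
  expect_identical(p1, p2)
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(77)
  ps <- vapply(1:200, function(i) {
    x <- stats::rnorm(40)
    g <- rep(c("A", "B"), 20)
    permutation_association(x, g, n_perm = 99, seed = 1000 + i)
  }, numeric(1))
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.58)
  expect_lte(mean(ps <= 0.05), 0.05 + 2 / 100 + 0.03)
})

test_that("a fully site-determining binary feature gives the textbook tree", {
  n <- 60
  f <- rep(c(TRUE, FALSE), each = n / 2)
  site <- ifelse(f, "G", "H")
  filler <- rep(1, n)
  tr <- grow_conditional_tree(data.frame(f = f, filler = filler), site,
                              alpha = 0.05, n_perm = 199, seed = 2,
                              min_node = 10)
  expect_false(tr$terminal)
  expect_equal(tr$split$variable, "f")
  expect_lte(tr$p_adj, 0.05)
  kids <- tr$children
  expect_true(kids[[1]]$terminal && kids[[2]]$terminal)
  props <- rbind(kids[[1]]$proportions, kids[[2]]$proportions)
  expect_equal(sort(apply(props, 1, max)), c(1, 1))
  expect_equal(kids[[1]]$n + kids[[2]]$n, tr$n)
  for (k in kids) expect_equal(sum(k$proportions), 1)
})

test_that("alpha -> 0 keeps the root terminal; invalid alpha errors", {
  set.seed(3)
  feats <- data.frame(a = stats::rnorm(80), b = stats::rnorm(80))
  site <- rep(c("G", "H"), 40)
  tr <- grow_conditional_tree(feats, site, alpha = 1e-9, n_perm = 99, seed = 1)
  expect_true(tr$terminal)
  expect_error(grow_conditional_tree(feats, site, alpha = 0), "alpha")
  expect_error(grow_conditional_tree(feats, site, alpha = 1.5), "alpha")
  expect_error(grow_conditional_tree(feats, rep("G", 80)), "2 sites")
})

test_that("trees are deterministic and invariant to patient order", {
  set.seed(8)
  n <- 120
  feats <- data.frame(x = c(stats::rnorm(n / 2), stats::rnorm(n / 2, 1.5)),
                      y = stats::rnorm(n),
                      b = sample(c(TRUE, FALSE), n, TRUE))
  site <- rep(c("G", "H"), each = n / 2)
  t1 <- grow_conditional_tree(feats, site, n_perm = 199, seed = 5, min_node = 15)
  t2 <- grow_conditional_tree(feats, site, n_perm = 199, seed = 5, min_node = 15)
  expect_identical(tree_to_list(t1), tree_to_list(t2))

  perm <- sample.int(n)
  t3 <- grow_conditional_tree(feats[perm, ], site[perm], n_perm = 199,
                              seed = 5, min_node = 15)
  expect_identical(tree_to_list(t1), tree_to_list(t3))

  # structural invariants on the grown tree
  walk <- function(node) {
    expect_equal(sum(node$proportions), 1)
    if (!node$terminal) {
      expect_lte(node$p_adj, 0.05)
      expect_equal(node$children[[1]]$n + node$children[[2]]$n, node$n)
      walk(node$children[[1]]); walk(node$children[[2]])
    }
  }
  walk(t1)
})

test_that("availability counts respect enrollment and the least-item bound", {
  co <- tiny_cohort()
  h <- apply_plausibility(build_harmonized(co)$table)$table
  defs <- shipped_defs()
  sc <- compute_cohort_scores(defs, h)
  av <- availability_counts(h, sc)
  expect_true(all(av$items$count <= av$sites$enrolled[match(av$items$site, av$sites$site)]))
  # fully documented items count n
  expect_equal(av$items$count[av$items$item == "age"], 2L)
  m <- av$scores$computed[av$scores$score_id == "maggic"]
  req <- vapply(defs$maggic$variables, function(v) v$name, character(1))
  req <- intersect(req, av$items$item)
  expect_lte(m, min(av$items$count[av$items$item %in% req]))
})
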
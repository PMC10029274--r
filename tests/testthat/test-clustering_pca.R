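fake_metrics <- function(x, ids = sprintf("d%03d", seq_len(nrow(x)))) {
  data.frame(dar_id = ids,
             net_displacement = x[, 1], max_displacement = x[, 2],
             max_diameter = x[, 3], max_width = x[, 4],
             complete = stats::complete.cases(x),
             stringsAsFactors = FALSE)
}

test_that("make_matrix drops incomplete rows and z-scores the rest", {
  set.seed(1)
  x <- matrix(rexp(40), 10, 4)
  x[c(2, 7), 1] <- NA
  mm <- make_matrix(fake_metrics(x))
  expect_equal(nrow(mm$x), 8L)
  expect_equal(mm$n_dropped, 2L)
  expect_equal(unname(colMeans(mm$x)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(mm$x, 2, sd)), rep(1, 4), tolerance = 1e-9)
  # zero-variance column cannot be standardized
  x2 <- matrix(rexp(40), 10, 4); x2[, 3] <- 2
  expect_error(make_matrix(fake_metrics(x2)), "zero-variance")
})

test_that("Ward tree has monotone heights and joins separated pairs last", {
  x <- rbind(c(0, 0, 0, 0), c(0.1, 0, 0, 0),
             c(10, 10, 10, 10), c(10.1, 10, 10, 10))
  x <- x + matrix(rnorm(16, 0, 0.01), 4)
  mm <- make_matrix(fake_metrics(x))
  tree <- ward_linkage(mm)
  expect_true(all(diff(tree$height) >= -1e-12))
  lab <- cut_tree(tree, 2)
  expect_equal(unname(lab), c(1L, 1L, 2L, 2L))
  set.seed(8)
  mm2 <- make_matrix(fake_metrics(matrix(rnorm(200), 50, 4)))
  expect_true(all(diff(ward_linkage(mm2)$height) >= -1e-12))
})

test_that("cut_tree labels by first occurrence and validates k", {
  set.seed(2)
  mm <- make_matrix(fake_metrics(matrix(rnorm(80), 20, 4)))
  tree <- ward_linkage(mm)
  expect_equal(unname(cut_tree(tree, 1)), rep(1L, 20))
  expect_equal(sort(unname(cut_tree(tree, 20))), 1:20)
  lab <- cut_tree(tree, 4)
  expect_equal(unname(lab[1]), 1L)                 # first row always cluster 1
  expect_equal(sort(unique(unname(lab))), 1:4)
  # first occurrence ordering: cluster ids appear in row order
  firsts <- vapply(1:4, function(k) which(lab == k)[1], integer(1))
  expect_true(all(diff(firsts) > 0))
  expect_error(cut_tree(tree, 0), "out of range")
  expect_error(cut_tree(tree, 21), "out of range")
})

test_that("wss curve brackets and the slope heuristic follow their definitions", {
  set.seed(3)
  mm <- make_matrix(fake_metrics(matrix(rnorm(120), 30, 4)))
  tree <- ward_linkage(mm)
  cv <- wss_curve(mm, tree, k_max = 30)
  expect_equal(cv$wss[30], 0, tolerance = 1e-9)          # all singletons
  expect_equal(cv$wss[1], sum(mm$x^2), tolerance = 1e-9) # grand-centroid TSS
  expect_true(all(diff(cv$wss) <= 1e-9))                  # non-increasing

  sh <- slope_heuristic(c(100, 50, 30, 25, 22))
  expect_equal(sh$s[1:4], c(-50, -20, -5, -3))
  expect_equal(sh$f[3], 0.75)
  expect_equal(sh$f[4], 0.4)
})

test_that("suggest_k flags prominent slope changes and stays silent on linear decline", {
  lin <- slope_heuristic(seq(100, 10, by = -10))
  expect_equal(nrow(suggest_k(lin)), 0L)

  set.seed(6)
  arch <- rep(c("closed_local", "transverse", "closed_large", "wide_open"),
              each = 40)
  met <- simulate_dar_metrics(arch, seed = 6)
  mm <- make_matrix(met)
  tree <- ward_linkage(mm)
  cand <- suggest_k(wss_curve(mm, tree, k_max = 12))
  expect_true(4 %in% cand$k[1:2])   # true k among the top-2 candidates
})

test_that("PCA factors are orthonormal, sign-fixed, and reconstruct the matrix", {
  set.seed(10)
  met <- simulate_dar_metrics(scale_gradient_specs(80), seed = 10)
  mm <- make_matrix(met)
  p <- run_pca(mm)
  expect_equal(crossprod(p$loadings), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-12)
  expect_true(all(p$loadings[, 1] > 0))
  expect_equal(p$scores %*% t(p$loadings), mm$x, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(p$interpretation["PC1"]), "extent")
})

test_that("composite size is a nonnegative linear scale, rank-matching the PC1 score", {
  set.seed(11)
  met <- simulate_dar_metrics(scale_gradient_specs(60), seed = 11)
  mm <- make_matrix(met)
  p <- run_pca(mm)
  sz <- composite_size(met, p)
  expect_true(all(sz >= 0))
  zero <- fake_metrics(matrix(0, 1, 4), ids = "z")
  expect_equal(unname(composite_size(zero, p)), 0)
  expect_equal(unname(composite_size(fake_metrics(2 * as.matrix(
    met[1, c("net_displacement", "max_displacement", "max_diameter",
             "max_width")]), ids = "a"), p)),
    2 * unname(sz[1]))
  # with equal-SD columns the loading route ranks like the PC1 score route
  x <- as.matrix(met[, c("net_displacement", "max_displacement",
                         "max_diameter", "max_width")])
  xeq <- scale(x) + 5   # equal-SD columns, shifted positive
  meq <- fake_metrics(xeq)
  mmeq <- make_matrix(meq)
  peq <- run_pca(mmeq)
  s1 <- composite_size(meq, peq, method = "loading")
  s2 <- composite_size(meq, peq, method = "score")
  expect_equal(cor(s1, s2, method = "spearman"), 1)
})

test_that("cluster summaries carry openness labels, transverse flags and size ranks", {
  set.seed(13)
  arch <- rep(c("closed_local", "transverse", "wide_open"), each = 25)
  met <- simulate_dar_metrics(arch, seed = 13)
  labels <- as.integer(factor(met$archetype,
                              levels = c("closed_local", "transverse",
                                         "wide_open")))
  sm <- summarize_clusters(labels, met)
  expect_equal(sum(sm$n), nrow(met))
  expect_equal(sum(sm$percent), 100, tolerance = 1e-9)
  expect_equal(sm$openness, c("closed", "closed", "wide open"))
  expect_equal(sm$transverse, c(FALSE, TRUE, FALSE))
  expect_equal(sm$size_rank[1], 1L)  # smallest mean diameter
  one <- summarize_clusters(rep(1L, nrow(met)), met)
  expect_equal(one$percent, 100)
})

test_that("clustering is invariant to row order (ARI = 1 on shuffled rows)", {
  set.seed(14)
  arch <- rep(c("closed_local", "closed_large", "wide_open"), each = 20)
  met <- simulate_dar_metrics(arch, seed = 14)
  lab1 <- cut_tree(ward_linkage(make_matrix(met)), 3)
  met2 <- met[sample(nrow(met)), ]
  lab2 <- cut_tree(ward_linkage(make_matrix(met2)), 3)
  # align by dar_id (make_matrix sorts rows by id, so labels share order)
  expect_equal(adjusted_rand_index(lab1, lab2), 1)
  expect_equal(adjusted_rand_index(1:10, 10:1), 1)  # relabeling only
})
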
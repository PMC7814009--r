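test_that("pairwise distances satisfy the metric axioms and hand sums", {
  m <- rbind(a = c(0, 0, 3), b = c(0, 0, 0), c = c(1, 2, 0))
  d_man <- pairwise_distance(m, "manhattan")
  expect_equal(d_man["a", "b"], 3)             # total allele-count difference
  expect_equal(d_man["b", "c"], 3)
  d_euc <- pairwise_distance(m, "euclidean")
  expect_equal(d_euc["a", "b"], 3)
  expect_equal(d_euc["b", "c"], sqrt(5))

  set.seed(42)
  for (rep in 1:5) {
    mm <- matrix(sample(0:3, 8 * 30, replace = TRUE), nrow = 8)
    rownames(mm) <- paste0("s", 1:8)
    for (metric in c("euclidean", "manhattan")) {
      d <- pairwise_distance(mm, metric)
      expect_equal(d, t(d))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0))
      for (i in 1:8) for (j in 1:8) for (k in 1:8) {
        expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
      }
    }
    # manhattan dominates euclidean on integer dosage vectors
    expect_true(all(pairwise_distance(mm, "manhattan") >=
                      pairwise_distance(mm, "euclidean") - 1e-12))
  }

  # pairwise-complete missing handling: NA site dropped for that pair
  mna <- rbind(a = c(1, NA, 3), b = c(0, 2, 0), c = c(0, 2, 3))
  dna <- pairwise_distance(mna, "manhattan")
  expect_equal(dna["a", "b"], 4)
  expect_equal(dna["a", "c"], 1)
  expect_error(pairwise_distance(m[1, , drop = FALSE]), "2 samples")
})

test_that("neighbor joining recovers the additive 4-taxon tree exactly", {
  # hand-solved additive tree: A-2, B-1 | internal 4 | C-1, D-2
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 7; d["A", "D"] <- 8
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 3
  d <- d + t(d)
  tree <- nj_tree(d)
  # split AB|CD and exact branch lengths via the path metric
  cd <- ape::cophenetic.phylo(tree)
  expect_equal(cd[LETTERS[1:4], LETTERS[1:4]], d, tolerance = 1e-12)
  expected_el <- c(A = 2, B = 1, C = 1, D = 2)
  tip_el <- tree$edge.length[match(seq_len(4), tree$edge[, 2])]
  expect_equal(tip_el, unname(expected_el[tree$tip.label]))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0, 0, 1, 0, 0, 0), 3)),
               "symmetric")
})

test_that("NJ reproduces random additive trees (enumeration-scale oracle)", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (n_tips in c(4, 5, 6)) {
    for (rep in 1:5) {
      true_tree <- ape::rtree(n_tips, rooted = FALSE,
                              br = function(n) runif(n, 0.5, 2))
      d <- ape::cophenetic.phylo(true_tree)
      est <- nj_tree(d)
      expect_equal(phangorn::RF.dist(est, true_tree), 0)
      expect_equal(ape::cophenetic.phylo(est)[rownames(d), colnames(d)], d,
                   tolerance = 1e-8)
    }
  }
})

test_that("NJ clamps negative branch lengths but keeps the raw values", {
  # non-additive matrix known to induce a negative internal branch
  d <- matrix(c(0, 5, 9, 9,
                5, 0, 10, 10,
                9, 10, 0, 2,
                9, 10, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- 0.5   # strain the four-point condition
  d["b", "a"] <- 0.5
  tree <- nj_tree(d)
  raw <- attr(tree, "raw_edge_length")
  expect_true(all(tree$edge.length >= 0))
  expect_equal(pmax(raw, 0), tree$edge.length)
  expect_true(any(raw < 0))
})

test_that("three taxa give the closed-form star tree", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tree <- nj_tree(d)
  el <- setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                 tree$tip.label)
  # three-point equations: x = (d_xy + d_xz - d_yz)/2 etc.
  expect_equal(el[["x"]], 1)
  expect_equal(el[["y"]], 2)
  expect_equal(el[["z"]], 4)
})

test_that("PCA decomposes the dosage matrix and separates clusters", {
  # mirrored clusters: PC1 must separate with opposite-sign scores
  base <- matrix(rep(c(0, 3), each = 4 * 10), nrow = 8, byrow = FALSE)
  m <- rbind(matrix(0, 4, 20), matrix(3, 4, 20)) +
    matrix(rnorm(8 * 20, 0, 0.01), 8, 20)
  rownames(m) <- paste0("s", 1:8)
  p <- dosage_pca(m)
  expect_true(all(sign(p$scores[1:4, 1]) == -sign(p$scores[5:8, 1])))

  # full-rank reconstruction and variance bookkeeping
  set.seed(11)
  mm <- matrix(rnorm(6 * 5), 6, 5, dimnames = list(paste0("s", 1:6), NULL))
  pp <- dosage_pca(mm)
  expect_equal(sum(pp$variance_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(pp$variance_explained) <= 1e-9))
  recon <- pp$scores %*% t(pp$loadings) +
    matrix(pp$center, 6, 5, byrow = TRUE)
  expect_equal(unname(recon), unname(mm), tolerance = 1e-8)
  # orthogonal scores
  cross <- crossprod(pp$scores)
  expect_equal(cross[upper.tri(cross)], rep(0, sum(upper.tri(cross))),
               tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(pp$loadings))) {
    l <- pp$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
  # constant matrix warns, returns zeros
  expect_warning(z <- dosage_pca(matrix(2, 3, 4)), "constant")
  expect_true(all(z$scores == 0))
})

test_that("two synthetic geographic groups segregate on PC1", {
  w <- make_world(n_populations = 2, samples_per_population = c(10, 5),
                  n_sites = 3000, private_pop = 60, private_sample = 10,
                  shared = 40, seed = 13)
  calls <- synth_calls(w$truth, read_model(mean_depth = 60,
                                           depth_dispersion = 0), seed = 5)
  mat <- recode_dosage(apply_filters(calls, filter_config(), w$ref))
  p <- dosage_pca(mat)
  s1 <- p$scores[w$truth$groups[rownames(p$scores)] == "pop1", 1]
  s2 <- p$scores[w$truth$groups[rownames(p$scores)] == "pop2", 1]
  expect_true(all(sign(s1) == sign(s1[1])))
  expect_true(all(sign(s2) == -sign(s1[1])))
})

test_that("k-means row aggregation recovers plain site groups", {
  # two plainly separated site groups: centroids are the group means
  m <- cbind(matrix(0, 6, 15), matrix(3, 6, 10))
  m <- m + matrix(rnorm(6 * 25, 0, 0.01), 6, 25)
  rownames(m) <- paste0("s", 1:6)
  agg <- kmeans_row_aggregate(m, k = 2, seed = 3)
  expect_equal(dim(agg), c(2, 6))
  cent_lo <- agg[which.min(rowMeans(agg)), ]
  cent_hi <- agg[which.max(rowMeans(agg)), ]
  expect_equal(unname(cent_lo), unname(colMeans(t(m[, 1:15]))),
               tolerance = 0.02)
  expect_equal(unname(cent_hi), unname(colMeans(t(m[, 16:25]))),
               tolerance = 0.02)
  expect_equal(sum(attr(agg, "sizes")), 25)

  # identity aggregation at k = number of sites
  agg_id <- kmeans_row_aggregate(m, k = 25, seed = 1)
  expect_equal(dim(agg_id), c(25, 6))
  expect_equal(unname(sort(rowMeans(agg_id))), unname(sort(colMeans(m))))

  # determinism
  a1 <- kmeans_row_aggregate(m, k = 4, seed = 9)
  a2 <- kmeans_row_aggregate(m, k = 4, seed = 9)
  expect_identical(a1, a2)
  expect_error(kmeans_row_aggregate(m, k = 30), "exceeds")
})
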
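test_that("identical points merge first at height zero", {
  mat <- rbind(a = c(0, 0), b = c(0, 0), c = c(5, 5))
  hc <- hierarchical_cluster(mat)
  expect_equal(hc$height[1], 0)
  expect_equal(sort(hclust_member_sets(hc)[1]), "a\tb")
})

test_that("two tight separated triplets split at the top", {
  set.seed(10)
  mat <- rbind(matrix(rnorm(12, 0, 0.05), 3),
               matrix(rnorm(12, 10, 0.05), 3))
  rownames(mat) <- paste0("x", 1:6)
  hc <- hierarchical_cluster(mat)
  keys <- hclust_member_sets(hc)
  expect_true(paste(c("x1", "x2", "x3"), collapse = "\t") %in% keys)
  expect_true(paste(c("x4", "x5", "x6"), collapse = "\t") %in% keys)
})

test_that("missing values are rejected with a pointer to imputation", {
  mat <- matrix(c(1, NA, 2, 3), 2)
  expect_error(hierarchical_cluster(mat), "impute_missing")
})

test_that("Ward-D2 agrees with the Lance-Williams recurrence", {
  set.seed(20)
  for (rep in 1:25) {
    mat <- matrix(rnorm(20 * 5), 20)
    rownames(mat) <- sprintf("i%02d", 1:20)
    hc <- hierarchical_cluster(mat)
    ref <- ward_ref(mat)
    expect_equal(hc$height, ref$height, tolerance = 1e-10)
    expect_setequal(hclust_member_sets(hc),
                    merge_member_sets(ref$merge, rownames(mat)))
  }
})

test_that("bootstrap support is high for a 20-sd split, low on noise", {
  set.seed(1)
  mat <- rbind(matrix(rnorm(3 * 40, 0), 3), matrix(rnorm(3 * 40, 20), 3))
  rownames(mat) <- paste0("s", 1:6)
  bs <- bootstrap_support(mat, n_boot = 200, seed = 2)
  key <- paste(c("s1", "s2", "s3"), collapse = "\t")
  expect_gte(bs$bp[match(key, bs$member_sets)], 99)

  noise <- matrix(rnorm(10 * 30), 10)
  rownames(noise) <- paste0("n", 1:10)
  bn <- bootstrap_support(noise, n_boot = 100, seed = 3)
  expect_lt(mean(bn$bp[-length(bn$bp)]), 60)  # root excluded (always 100)
})

test_that("bootstrap probabilities converge in the resample count", {
  set.seed(4)
  mat <- rbind(matrix(rnorm(3 * 30, 0), 3), matrix(rnorm(3 * 30, 8), 3))
  rownames(mat) <- paste0("s", 1:6)
  b1 <- bootstrap_support(mat, n_boot = 200, seed = 5)
  b2 <- bootstrap_support(mat, n_boot = 1000, seed = 6)
  expect_lt(max(abs(b1$bp - b2$bp)), 5)
})

test_that("n_boot = 1 gives all-or-nothing support", {
  set.seed(7)
  mat <- matrix(rnorm(5 * 10), 5)
  rownames(mat) <- paste0("s", 1:5)
  b <- bootstrap_support(mat, n_boot = 1, seed = 8)
  expect_true(all(b$bp %in% c(0, 100)))
})

test_that("dendrograms serialize to Newick with support labels", {
  set.seed(9)
  mat <- matrix(rnorm(4 * 6), 4)
  rownames(mat) <- c("s1", "s2", "s3", "s4")
  bs <- bootstrap_support(mat, n_boot = 20, seed = 10)
  nwk <- dendrogram_newick(bs$hclust, bs$bp)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(mat))
  expect_equal(length(phy$node.label), 3)
})

test_that("clustermap export selects hits, z-scores rows, clusters both ways", {
  sim <- simulate_quant(sim_config(n_human = 300, n_mouse = 0,
                                   de_fraction = 0.15,
                                   log2fc_range = c(3, 6),
                                   tail_fraction = 0,
                                   dropout_midpoint = -Inf, seed = 23))
  norm <- median_ratio_normalize(sim$table)
  de <- diff_expr(norm)
  cm <- clustermap_export(de, impute_missing(norm))
  expect_equal(nrow(cm$matrix), sum(de$clustermap_hit))
  expect_equal(unname(rowMeans(cm$matrix)), rep(0, nrow(cm$matrix)),
               tolerance = 1e-10)
  # columns of one condition co-cluster: the top split separates A from I
  keys <- hclust_member_sets(cm$col_hclust)
  acols <- sort(grep("^A_", colnames(cm$matrix), value = TRUE))
  expect_true(paste(acols, collapse = "\t") %in% keys)

  de$clustermap_hit[] <- FALSE
  expect_warning(out <- clustermap_export(de, impute_missing(norm)),
                 "no clustermap hits")
  expect_null(out)
})

test_that("dendrogram is invariant under item permutation", {
  set.seed(11)
  mat <- matrix(rnorm(8 * 5), 8)
  rownames(mat) <- paste0("s", 1:8)
  perm <- sample(8)
  k1 <- sort(hclust_member_sets(hierarchical_cluster(mat)))
  k2 <- sort(hclust_member_sets(hierarchical_cluster(mat[perm, ])))
  expect_equal(k1, k2)
})
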
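test_that("median-ratio normalization has the closed-form scale", {
  labs <- full_grid_labels()[1:4]
  ref <- c(10, 20, 40, 80, 160)
  vals <- cbind(ref, ref, ref, 2 * ref)
  colnames(vals) <- labs
  qt <- quant_table(vals, sprintf("P%d", 1:5), sprintf("G%d", 1:5),
                    rep("human", 5))
  norm <- median_ratio_normalize(qt)
  expect_equal(unname(attr(norm, "scales")[4]), 0.5)
  expect_equal(unname(norm$values[, 4]), ref)
  # already-normalized table is unchanged
  again <- median_ratio_normalize(norm)
  expect_equal(unname(attr(again, "scales")), rep(1, 4))
})

test_that("normalization medians ignore missing cells (brute force)", {
  set.seed(1)
  qt <- tiny_table(20, fill = 1)
  qt$values[] <- exp(matrix(rnorm(length(qt$values), 3), 20))
  qt$values[sample(length(qt$values), 60)] <- NA
  norm <- median_ratio_normalize(qt)
  ref <- sapply(seq_len(20), function(i) {
    v <- qt$values[i, ]
    median(v[!is.na(v)])
  })
  j <- 5
  r <- qt$values[, j] / ref
  expect_equal(unname(attr(norm, "scales")[j]),
               1 / median(r[!is.na(r)]))
})

test_that("imputation fills at the low quantile and flags cells", {
  qt <- tiny_table(10, fill = 1)
  qt$values[] <- matrix(seq(10, 1000, length.out = 180), 10)
  clean <- impute_missing(qt)
  expect_identical(clean$values, qt$values)  # nothing to do
  qt$values[3, 7] <- NA
  imp <- impute_missing(qt)
  expect_false(anyNA(imp$values))
  expect_true(attr(imp, "imputed")[3, 7])
  expect_equal(sum(attr(imp, "imputed")), 1)
  present <- qt$values[-3, 7]
  expect_lte(imp$values[3, 7], quantile(present, 0.05, names = FALSE))
})

test_that("Welch test matches hand computation and handles degenerate input", {
  w0 <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(w0$t, 0)
  expect_equal(w0$p, 1)
  w <- welch_t_test(c(10, 11, 12), c(1, 2, 3))
  expect_equal(w$t, 9 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(w$df, 4)
  expect_equal(w$p, 2 * pt(-9 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_true(is.na(welch_t_test(c(1), c(1, 2, 3))$p))
})

test_that("null Welch p-values are uniform", {
  set.seed(33)
  p <- replicate(3000, welch_t_test(rnorm(3), rnorm(3))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

test_that("BH adjustment matches hand step-up computations", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.002, 0.03)), c(0.004, 0.03))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA p-values are excluded, not propagated into the correction
  expect_equal(bh_adjust(c(0.002, NA, 0.03)), c(0.004, NA, 0.03))
})

test_that("BH is invariant to input permutation", {
  set.seed(2)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
})

test_that("log fold change is log2 of the mean ratio", {
  expect_equal(log_fold_change(8, 2), 2)
  expect_equal(log_fold_change(5, 5), 0)
  expect_true(is.na(log_fold_change(NA, 2)))
})

test_that("a planted 3-log2FC protein is recovered within 0.3", {
  sim <- simulate_quant(sim_config(n_human = 60, n_mouse = 0,
                                   de_fraction = 0, tail_fraction = 0,
                                   dropout_midpoint = -Inf, seed = 6))
  qt <- sim$table
  # plant the effect explicitly on one protein
  icols <- qt$columns$condition == "I"
  qt$values[1, icols] <- qt$values[1, icols] * 2^3
  de <- diff_expr(qt)
  expect_equal(de$log2fc[1], 3, tolerance = 0.1)
  expect_equal(de$direction[1], "invasive-up")
})

test_that("hit tiers follow the gates and are nested for human", {
  base <- data.frame(protein_id = c("P1", "P2", "P3"),
                     gene_symbol = c("G1", "G2", "G3"),
                     species = "human",
                     log2fc = c(1.5, 6, 2.5),
                     padj = c(0.005, 0.02, 0.001))
  out <- flag_hits(base, pipeline_config())
  # padj 0.005, |logFC| 1.5: significant + enrichment, not clustermap
  expect_true(out$significant[1] && out$enrichment_hit[1])
  expect_false(out$clustermap_hit[1])
  # padj 0.02 fails the gate regardless of logFC 6
  expect_false(any(out$significant[2], out$enrichment_hit[2],
                   out$clustermap_hit[2]))
  expect_true(out$clustermap_hit[3])
  # mouse needs |logFC| > 5 for the clustermap tier
  base$species <- "mouse"
  outm <- flag_hits(base, pipeline_config())
  expect_false(outm$clustermap_hit[3])

  sim <- simulate_quant(sim_config(n_human = 300, n_mouse = 0, seed = 14))
  de <- diff_expr(aggregate_presence(cv_filter(sim$table)$table)$table)
  expect_true(all(de$clustermap_hit[de$species == "human"] <=
                    de$enrichment_hit[de$species == "human"]))
  expect_true(all(de$enrichment_hit <= de$significant))
})

test_that("a null simulation yields (almost) no significant calls", {
  sim <- simulate_quant(sim_config(n_human = 700, n_mouse = 0,
                                   de_fraction = 0, tail_fraction = 0,
                                   dropout_midpoint = -Inf, seed = 17))
  de <- diff_expr(sim$table)
  bound <- 0.01 + 3 * sqrt(0.01 * 0.99 / sum(!is.na(de$padj)))
  expect_lte(mean(de$padj < 0.01, na.rm = TRUE), bound)
})

test_that("direction summary counts match flag columns", {
  sim <- simulate_quant(sim_config(n_human = 250, n_mouse = 100, seed = 19))
  de <- diff_expr(aggregate_presence(cv_filter(sim$table)$table)$table)
  s <- de_summary(de)
  expect_equal(sum(s$significant), sum(de$significant & !is.na(de$direction)))
  hs <- s[s$species == "human" & s$direction == "invasive-up", ]
  expect_equal(hs$significant,
               sum(de$significant & de$species == "human" &
                     de$direction == "invasive-up", na.rm = TRUE))
})
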
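test_that("delta-Z follows the mean-difference definition with its symmetries", {
  sig <- signature_set(c("a", "b"), c("c", "d"))
  z <- c(a = 1, b = 1, c = -1, d = -1)
  expect_equal(delta_z(z, sig), 2)
  expect_equal(delta_z(setNames(rep(0, 4), names(z)), sig), 0)
  swapped <- signature_set(sig$gpc2_high, sig$gpc1_high)
  expect_equal(delta_z(z, swapped), -2)                 # antisymmetry
  expect_equal(delta_z(z + 5, sig), delta_z(z, sig))    # global shift
  expect_error(delta_z(z[1:3], sig), "missing")
  expect_error(signature_set(c("a", "b"), c("a", "x")), "disjoint")
  expect_error(signature_set(c("a"), c("b", "c")), "equal size")
})

test_that("permutation p-values are lower-bounded, reproducible, and maximal for constants", {
  sig <- small_signature(5)
  z_const <- setNames(rep(1.3, 10), c(sig$gpc1_high, sig$gpc2_high))
  expect_equal(permutation_pvalue(z_const, sig, n_perm = 99, seed = 1), 1)
  z_strong <- setNames(c(rep(10, 5), rep(-10, 5)),
                       c(sig$gpc1_high, sig$gpc2_high))
  expect_equal(permutation_pvalue(z_strong, sig, n_perm = 199, seed = 1),
               1 / 200)                                 # all permutations weaker
  set.seed(77)
  z <- setNames(rnorm(10), c(sig$gpc1_high, sig$gpc2_high))
  p1 <- permutation_pvalue(z, sig, n_perm = 200, seed = 5)
  p2 <- permutation_pvalue(z, sig, n_perm = 200, seed = 5)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 201)
  expect_error(permutation_pvalue(z, sig, n_perm = 0), "n_perm")
})

test_that("cell classification calls planted subtypes with high sensitivity and matches sign(delta-Z)", {
  sig <- signature_set(sprintf("u%03d", 1:100), sprintf("d%03d", 1:100))
  sim <- generate_single_cells(100, sig, signal = 1.5, seed = 3)
  res <- classify_cells(sim$z, sig, n_perm = 500, seed = 9)
  for (side in c("GPC1", "GPC2")) {
    truth <- sim$labels == side
    expect_gte(mean(res$call[truth] == side), 0.9)
  }
  called <- res$call != "unassigned"
  expect_true(all(res$call[called & res$delta_z > 0] == "GPC1"))
  expect_true(all(res$call[called & res$delta_z < 0] == "GPC2"))
  expect_true(all(res$p_perm >= 1 / 501))
})

test_that("signature construction balances sides, honors prefilters, and errors on shortfalls", {
  cfg <- cohort_config(n_proteins = 400, frac_informative = 0.5,
                       effect_size = 2, missing_rate = 0, seed = 14)
  b <- generate_proteome_bundle(cfg)
  sig <- build_signature(b$matrix$values, b$labels, mode = "top_n", n = 50)
  expect_length(sig$gpc1_high, 50)
  expect_length(sig$gpc2_high, 50)
  expect_length(intersect(sig$gpc1_high, sig$gpc2_high), 0)
  # the strongest planted genes are captured
  up_true <- b$informative$protein[b$informative$direction == 1]
  expect_gt(length(intersect(sig$gpc1_high, up_true)) / 50, 0.9)

  # fdr mode on null data: no gene passes
  null_b <- generate_proteome_bundle(cohort_config(effect_size = 0,
                                                   missing_rate = 0, seed = 2))
  expect_error(build_signature(null_b$matrix$values, null_b$labels,
                               mode = "fdr", fdr = 0.1), "no genes pass")

  # cell prefilter drops genes detected in < 50% of cells
  cells <- matrix(1, 400, 10, dimnames = list(rownames(b$matrix$values), NULL))
  cells[1:200, ] <- 0
  sig2 <- build_signature(b$matrix$values, b$labels, mode = "top_n", n = 20,
                          cells = cells)
  expect_false(any(c(sig2$gpc1_high, sig2$gpc2_high) %in%
                     rownames(b$matrix$values)[1:200]))
})

test_that("quantile merging equalizes sorted sample vectors to the order-statistic mean reference", {
  a <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("a1", "a2")))
  b <- matrix(c(10, 30, 50), 3, 1,
              dimnames = list(c("g1", "g2", "g3"), "b1"))
  merged <- quantile_merge(a, b)
  # hand-computed reference: means of sorted columns
  ref <- rowMeans(apply(cbind(a, b), 2, sort))
  for (j in seq_len(ncol(merged))) {
    expect_equal(unname(sort(merged[, j])), unname(ref))
  }
  expect_error(quantile_merge(a, matrix(1, 2, 1,
                                        dimnames = list(c("x", "y"), "b2"))),
               "share no genes")
})

test_that("surrogate bulk classifier is probability-thresholded and separable by construction", {
  cfg <- cohort_config(n_samples = 30, group_sizes = c(18, 12),
                       n_proteins = 300, effect_size = 2.5,
                       missing_rate = 0, seed = 19)
  b <- generate_proteome_bundle(cfg)
  train <- b$matrix$values
  set.seed(101)
  test_cohort <- train[, c(1, 2, 25, 26)] + rnorm(4 * 300, sd = 0.05)
  colnames(test_cohort) <- paste0("T", 1:4)
  res <- surrogate_bulk_classify(train, b$labels, test_cohort,
                                 top_n_genes = 50, n_tree = 200, seed = 4)
  expect_equal(res$call, c("GPC1", "GPC1", "GPC2", "GPC2"))
  expect_true(all(res$prob_win >= 0.6))
  # threshold 0 calls every sample
  res0 <- surrogate_bulk_classify(train, b$labels, test_cohort,
                                  prob_threshold = 0, top_n_genes = 50,
                                  n_tree = 100, seed = 4)
  expect_true(all(res0$call != "unassigned"))
  expect_error(surrogate_bulk_classify(train, factor(rep("GPC1", 30)),
                                       test_cohort),
               "two classes")
})
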
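test_that("extreme-group definition matches exhaustive rule application", {
  sc <- cbind(A = c(0.9, 0.1, 0.6, 0.9, 0.3, 0.1, 0.55, 0.45),
              B = c(0.1, 0.9, 0.6, 0.4, 0.1, 0.2, 0.30, 0.80))
  rownames(sc) <- sprintf("s%d", 1:8)
  a <- activity_from_scores(sc)
  r <- a$rescaled
  g <- define_extreme_groups(a, "A", "B", cutoff = 0.5)
  # enumeration oracle: high = > 0.5, low = < 0.5 (symmetric rule at 0.5)
  oracle1 <- rownames(r)[r[, "A"] > 0.5 & r[, "B"] < 0.5]
  oracle2 <- rownames(r)[r[, "A"] < 0.5 & r[, "B"] > 0.5]
  expect_setequal(g$group1, oracle1)
  expect_setequal(g$group2, oracle2)
  expect_true("s1" %in% g$group1 && "s2" %in% g$group2)
  # 0.6/0.6 fails the low condition on either side
  expect_false("s3" %in% c(g$group1, g$group2))
})

test_that("a sub-0.5 cutoff names the stricter tails under the symmetric rule", {
  sc <- cbind(A = c(0.95, 0.70, 0.10, 0.05), B = c(0.05, 0.30, 0.90, 0.95))
  rownames(sc) <- sprintf("s%d", 1:4)
  a <- activity_from_scores(sc)
  r <- a$rescaled
  g <- define_extreme_groups(a, "A", "B", cutoff = 0.2)
  oracle1 <- rownames(r)[r[, "A"] > 0.8 & r[, "B"] < 0.2]
  oracle2 <- rownames(r)[r[, "A"] < 0.2 & r[, "B"] > 0.8]
  expect_setequal(g$group1, oracle1)
  expect_setequal(g$group2, oracle2)
  # plain rule: both conditions at the cutoff itself
  gp <- define_extreme_groups(a, "A", "B", cutoff = 0.5, rule = "plain")
  expect_setequal(gp$group1, rownames(r)[r[, "A"] > 0.5 & r[, "B"] < 0.5])
  # empty group errors with sizes
  expect_error(define_extreme_groups(a, "A", "A", cutoff = 0.5), "empty")
})

test_that("the copy-number filter labels planted alterations exactly", {
  g1 <- sprintf("g1_%d", 1:5); g2 <- sprintf("g2_%d", 1:5)
  v <- matrix(0, 4, 10, dimnames = list(
    c("gain1", "shared", "null", "loss2"), c(g1, g2)))
  v["gain1", g1[1:2]] <- 0.6            # 40% of group1 only
  v["shared", c(g1[1:2], g2[1:2])] <- 0.8   # gained in both -> removed
  v["loss2", g2[1:3]] <- -0.9           # 60% of group2, loss
  v <- v + matrix(rnorm(40, 0, 0.01), 4, 10)
  gm <- genomic_matrix(v, "copy_number")
  res <- cnv_subgroup_filter(gm, g1, g2)
  status <- setNames(as.character(res$status), res$gene)
  expect_identical(status[["gain1"]], "group1_specific_gain")
  expect_identical(status[["shared"]], "removed")
  expect_identical(status[["null"]], "none")
  expect_identical(status[["loss2"]], "group2_specific_loss")
  # statuses partition the genes: exactly one per gene
  expect_equal(nrow(res), 4L)
  expect_false(anyNA(res$status))
  # gained in one group, lost in the other: treated as altered in both
  v2 <- matrix(0, 1, 10, dimnames = list("flip", c(g1, g2)))
  v2["flip", g1] <- 0.8; v2["flip", g2] <- -0.8
  expect_identical(as.character(cnv_subgroup_filter(
    genomic_matrix(v2, "copy_number"), g1, g2)$status), "removed")
  expect_error(cnv_subgroup_filter(gm, g1, c(g1[1], g2)), "disjoint")
})

test_that("a 20% within-subgroup fraction is the alteration boundary", {
  g1 <- sprintf("a%d", 1:10); g2 <- sprintf("b%d", 1:10)
  v <- matrix(0, 2, 20, dimnames = list(c("at20", "below20"), c(g1, g2)))
  v["at20", g1[1:2]] <- 0.7       # exactly 20% -> altered
  v["below20", g1[1]] <- 0.7      # 10% -> not altered
  res <- cnv_subgroup_filter(genomic_matrix(v, "copy_number"), g1, g2)
  status <- setNames(as.character(res$status), res$gene)
  expect_identical(status[["at20"]], "group1_specific_gain")
  expect_identical(status[["below20"]], "none")
})

test_that("window size 1 reduces the methylation scan to a per-probe Welch test", {
  g1 <- sprintf("s%d", 1:6); g2 <- sprintf("s%d", 7:12)
  gm <- simulate_genomic_correlates(g1, g2, n_genes = 10, n_probes = 60, seed = 55)
  res <- sliding_window_meth_test(gm$methylation, g1, g2, window_size = 1)
  oracle <- apply(gm$methylation$values, 1, function(v)
    t.test(v[g1], v[g2])$p.value)
  expect_equal(res$p, unname(oracle[res$feature]), tolerance = 1e-12)
  expect_identical(res$kept, res$p < 0.1)
})

test_that("identical group distributions give t = 0 and p = 1", {
  vals <- matrix(rep(c(0.2, 0.5, 0.8), times = 8), 3, 8,
                 dimnames = list(c("c1", "c2", "c3"), sprintf("s%d", 1:8)))
  gm <- genomic_matrix(vals, "methylation", chrom = rep("chr1", 3), pos = 1:3)
  res <- sliding_window_meth_test(gm, sprintf("s%d", 1:4), sprintf("s%d", 5:8),
                                  window_size = 3)
  expect_equal(res$t, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  expect_false(any(res$kept))
})

test_that("planted window shifts are detected and larger shifts give smaller p", {
  hits <- 0L
  for (s in 1:60) {
    g1 <- sprintf("s%d", 1:10); g2 <- sprintf("s%d", 11:20)
    gm <- simulate_genomic_correlates(
      g1, g2, n_genes = 5, n_probes = 80,
      planted_meth = list(list(probes = 11:15, group = 1, shift = 0.6)),
      seed = 700 + s)
    res <- sliding_window_meth_test(gm$methylation, g1, g2, window_size = 5)
    if (all(res$p[13] < 0.01)) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.95)
  # monotone power: bigger planted shift, smaller p at the window centre
  g1 <- sprintf("s%d", 1:10); g2 <- sprintf("s%d", 11:20)
  p_by_shift <- vapply(c(0.05, 0.15, 0.3), function(sh) {
    gm <- simulate_genomic_correlates(
      g1, g2, n_genes = 5, n_probes = 80,
      planted_meth = list(list(probes = 11:15, group = 1, shift = sh)),
      seed = 31)
    sliding_window_meth_test(gm$methylation, g1, g2, window_size = 5)$p[13]
  }, numeric(1))
  expect_true(all(diff(p_by_shift) < 0))
})

test_that("windows truncate at chromosome ends rather than crossing them", {
  set.seed(66)
  vals <- matrix(runif(10 * 6), 10, 6,
                 dimnames = list(sprintf("cg%02d", 1:10), sprintf("s%d", 1:6)))
  gm <- genomic_matrix(vals, "methylation",
                       chrom = rep(c("chr1", "chr2"), each = 5), pos = rep(1:5, 2))
  w <- pathsig:::.window_average(gm, 3)
  # first probe of chr2: window = probes 6:7 only (no spill from chr1)
  expect_equal(w[6, ], colMeans(vals[6:7, ]))
  expect_equal(w[5, ], colMeans(vals[4:5, ]))     # last probe of chr1
  expect_equal(w[2, ], colMeans(vals[1:3, ]))
  expect_warning(pathsig:::.window_average(
    genomic_matrix(vals[1:3, ], "methylation", chrom = rep("chr1", 3), pos = 1:3), 5),
    "truncated")
})

test_that("permutation FPR is calibrated on null data and reproducible", {
  g1 <- sprintf("s%d", 1:10); g2 <- sprintf("s%d", 11:20)
  gm <- simulate_genomic_correlates(g1, g2, n_genes = 5, n_probes = 1000, seed = 77)
  f1 <- permutation_false_positive_rate(gm$methylation, g1, g2, window_size = 5,
                                        alpha = 0.1, n_perm = 100, seed = 8)
  expect_lt(abs(f1$mean_fpr - 0.10), 0.03)
  f2 <- permutation_false_positive_rate(gm$methylation, g1, g2, window_size = 5,
                                        alpha = 0.1, n_perm = 100, seed = 8)
  expect_identical(f1$fractions, f2$fractions)
  # relabeling the groups leaves the estimate unchanged
  f3 <- permutation_false_positive_rate(gm$methylation, g2, g1, window_size = 5,
                                        alpha = 0.1, n_perm = 100, seed = 8)
  expect_lt(abs(f3$mean_fpr - f1$mean_fpr), 0.02)
  # alpha = 1 keeps everything in every shuffle
  f4 <- permutation_false_positive_rate(gm$methylation, g1, g2, window_size = 1,
                                        alpha = 1.0, n_perm = 5, seed = 8)
  expect_equal(f4$mean_fpr, 1.0)
  expect_error(permutation_false_positive_rate(gm$methylation, g1, g2,
                                               n_perm = 0), "n_perm")
})
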
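test_that("1.5 IQR filter matches the hand-worked type-7 example", {
  res <- iqr_outlier_filter(c(1, 2, 3, 4, 100))
  # type-7 quartiles: Q1 = 2, Q3 = 4, fences [-1, 7]
  expect_equal(res$kept, c(1, 2, 3, 4))
  expect_equal(res$removed, 100)
})

test_that("IQR filter edge cases behave", {
  expect_equal(iqr_outlier_filter(rep(7, 10))$removed, numeric(0))
  expect_warning(res <- iqr_outlier_filter(5), "fewer than 4")
  expect_equal(res$kept, 5)
  expect_error(iqr_outlier_filter(c(1, NA, 3)), "finite")
  # single pass is idempotent on its own output
  x <- c(rnorm(20), 50)
  once <- iqr_outlier_filter(x)$kept
  twice <- iqr_outlier_filter(once)$kept
  expect_equal(sort(twice), sort(iqr_outlier_filter(twice)$kept))
})

test_that("fold change is the ratio of filtered group means", {
  expect_equal(fold_change(rep(700, 4), rep(100, 4)), 7)
  x <- c(3, 4, 5, 6)
  expect_equal(fold_change(x, x), 1)
  expect_equal(fold_change(rep(25, 4), rep(100, 4)), 0.25)  # 4.0-fold drop
  # outliers in either group are removed before averaging
  expect_equal(fold_change(c(7, 7, 7, 7, 7000), c(1, 1, 1, 1)), 7)
  expect_error(fold_change(1:4, rep(0, 4)), "control mean")
})

test_that("identical groups are not called different", {
  g <- rep(c("ctrl", "a"), each = 5)
  v <- rep(c(1, 2, 3, 4, 5), 2)
  res <- compare_to_control(v, g, "ctrl")
  expect_gt(res$comparisons$p_adj, 0.99)
})

test_that("single comparison collapses to the pooled t-test", {
  set.seed(5)
  v <- c(rnorm(8, 10), rnorm(8, 11))
  g <- rep(c("ctrl", "trt"), each = 8)
  res <- compare_to_control(v, g, "ctrl")
  tt <- t.test(v[g == "trt"], v[g == "ctrl"], var.equal = TRUE)
  expect_equal(res$comparisons$p_adj, tt$p.value, tolerance = 1e-6)
})

test_that("comparisons permute under relabeling of treatment groups", {
  set.seed(8)
  v <- c(rnorm(6, 0), rnorm(6, 1), rnorm(6, 2))
  g1 <- rep(c("ctrl", "a", "b"), each = 6)
  g2 <- rep(c("ctrl", "b", "a"), each = 6)
  r1 <- compare_to_control(v, g1, "ctrl")
  r2 <- compare_to_control(v, g2, "ctrl")
  p1 <- setNames(r1$comparisons$p_adj, r1$comparisons$group)
  p2 <- setNames(r2$comparisons$p_adj, r2$comparisons$group)
  expect_equal(p1[["a"]], p2[["b"]], tolerance = 1e-4)
  expect_equal(p1[["b"]], p2[["a"]], tolerance = 1e-4)
  expect_equal(r1$anova_F, r2$anova_F)
})

test_that("compare_to_control validates its inputs", {
  expect_error(compare_to_control(1:6, rep(c("a", "b"), 3), "zzz"),
               "control label")
  expect_error(compare_to_control(1:3, c("a", "b", "b"), "a"), "n >= 2")
})

test_that("group summaries use the n-1 SD and the reporting format", {
  s <- summarize_groups(c(2, 4), c("g", "g"))
  expect_equal(s$mean, 3)
  expect_equal(s$sd, sqrt(2))
  expect_equal(s$label, "3.00 ± 1.41")
  one <- summarize_groups(4.29, "huvec")
  expect_equal(one$n, 1)
  expect_true(is.na(one$sd))
  expect_equal(one$label, "4.29")
})

test_that("significance labels follow the reporting thresholds", {
  expect_equal(significance_label(c(0.2, 0.08, 0.03, 0.005, 5e-4, 5e-5)),
               c("ns", "#", "*", "**", "***", "****"))
})
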
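# Welch's t-test, BH correction, fold changes with the not-detected rule,
# and longitudinal validation.

test_that("Welch test boundary behaviour and textbook oracle", {
  x <- c(1.2, 1.4, 1.1, 1.3)
  same <- welch_test(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # equal group sizes and exactly equal variances -> df = 2n - 2
  y <- x + 1
  eq <- welch_test(x, y)
  expect_equal(eq$df, 2 * length(x) - 2)

  hand <- welch_oracle(c(1, 2, 3, 4), c(2, 4, 6, 8))
  mine <- welch_test(c(1, 2, 3, 4), c(2, 4, 6, 8))
  expect_equal(mine$t, hand$t, tolerance = 1e-12)
  expect_equal(mine$df, hand$df, tolerance = 1e-12)
  expect_equal(mine$p, hand$p, tolerance = 1e-12)

  degen <- welch_test(c(1, 1, 1), c(1, 1, 1))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
  expect_error(welch_test(1, c(1, 2)), ">= 2")
})

test_that("BH adjustment equals the step-up procedure by hand", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(91)
  for (i in 1:5) {
    p <- runif(20)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))                 # q >= p elementwise
    expect_equal(order(q[order(p)]), seq_along(p))   # order preserved
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("fold changes apply the not-detected rule", {
  expect_equal(log10_fold_change(0.02, 0.02), 0)
  expect_equal(log10_fold_change(0.1, 0.01), 1)
  # control not detected, case mean 100 reads -> log10(100/1) = 2
  expect_equal(log10_fold_change(100 / 3000, 0, depth = 3000), 2)
  expect_equal(log10_fold_change(0, 100 / 3000, depth = 3000), -2)
  expect_true(is.finite(log10_fold_change(0, 0)))
})

test_that("diff_abundance recovers a planted shift in a count table", {
  set.seed(92)
  n_ms <- 10; n_hc <- 20
  counts <- rbind(
    rclust00001 = c(rpois(n_ms, 150), rpois(n_hc, 15)),   # 10x up in MS
    rclust00002 = c(rpois(n_ms, 60), rpois(n_hc, 60)),    # null
    unmap_OTU00001 = c(rpois(n_ms, 5), rpois(n_hc, 50)))  # down in MS
  colnames(counts) <- c(sprintf("MS_%02d", 1:n_ms), sprintf("HC_%02d", 1:n_hc))
  tab <- make_table(counts, c(rep("MS", n_ms), rep("HC", n_hc)))
  res <- diff_abundance(tab)
  expect_true(res$significant[res$cluster_id == "rclust00001"])
  expect_true(res$significant[res$cluster_id == "unmap_OTU00001"])
  expect_false(res$significant[res$cluster_id == "rclust00002"])
  expect_equal(res$log10_fc[1], 1, tolerance = 0.15)
  expect_true(all(res$q >= res$p - 1e-15))
})

test_that("longitudinal fold changes collapse to the cross-sectional one for constant controls", {
  set.seed(93)
  n_ms <- 6; n_hc <- 8
  ms <- matrix(30L, 2, n_ms)
  hc <- matrix(60L, 2, n_hc)
  counts <- cbind(ms, hc)
  rownames(counts) <- c("rclust00001", "rclust00002")
  colnames(counts) <- c(sprintf("MS_%d", 1:n_ms), sprintf("HC_%d", 1:n_hc))
  counts["rclust00002", ] <- rep(c(10L, 40L), c(n_ms, n_hc))
  counts[1, 1] <- 31L; counts[1, n_ms + 1] <- 61L  # break zero variance
  counts[2, 2] <- 11L; counts[2, n_ms + 2] <- 41L
  tab <- make_table(counts, rep(c("MS", "HC"), c(n_ms, n_hc)))
  diff <- diff_abundance(tab, alpha = 1)   # force both clusters significant

  # longitudinal controls exactly at the HC40 means, 3 subjects x 4 timepoints
  n_sub <- 3; n_tp <- 4
  long_counts <- matrix(rep(rowMeans(hc), n_sub * n_tp), 2)
  long_counts[2, ] <- mean(counts[2, (n_ms + 1):(n_ms + n_hc)])
  rownames(long_counts) <- rownames(counts)
  colnames(long_counts) <- sprintf("L%d_t%d", rep(1:n_sub, each = n_tp),
                                   rep(1:n_tp, n_sub))
  long_tab <- make_table(long_counts, rep("HC_long", n_sub * n_tp),
                         subject = sprintf("subjL_%d", rep(1:n_sub, each = n_tp)),
                         timepoint = rep(1:n_tp, n_sub))
  lv <- longitudinal_validation(diff, long_tab)
  for (cl in rownames(counts)) {
    fc_tp <- lv$per_timepoint$log10_fc[lv$per_timepoint$cluster_id == cl]
    expect_equal(fc_tp, rep(diff$log10_fc[diff$cluster_id == cl], n_tp),
                 tolerance = 0.02)
  }
  expect_equal(lv$consistency$sign_consistency, c(1, 1))
})

test_that("null species scatter around zero in longitudinal validation", {
  set.seed(94)
  n_tp <- 9
  counts <- matrix(rpois(12, 50), 1, 12,
                   dimnames = list("rclust00001",
                                   c(sprintf("MS_%d", 1:4), sprintf("HC_%d", 1:8))))
  tab <- make_table(counts, rep(c("MS", "HC"), c(4, 8)))
  diff <- diff_abundance(tab, alpha = 1)
  long_counts <- matrix(rpois(2 * n_tp, 50), 1,
                        dimnames = list("rclust00001",
                                        sprintf("L%d_t%d", rep(1:2, each = n_tp),
                                                rep(1:n_tp, 2))))
  long_tab <- make_table(long_counts, rep("HC_long", 2 * n_tp),
                         subject = rep(c("s1", "s2"), each = n_tp),
                         timepoint = rep(1:n_tp, 2))
  lv <- longitudinal_validation(diff, long_tab, clusters = "rclust00001")
  fcs <- lv$per_timepoint$log10_fc
  expect_lt(abs(mean(fcs)), 0.15)
  expect_true(any(fcs > 0) || any(fcs < 0))
})
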
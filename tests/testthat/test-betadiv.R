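# UniFrac, PCoA, ANOSIM and group-distance summaries.

# a random rooted tree with branch lengths plus random counts
random_beta_fixture <- function(n_tip = 6, n_samp = 5, seed = 71) {
  set.seed(seed)
  tree <- ape::rtree(n_tip, rooted = TRUE)
  tree$tip.label <- sprintf("rclust%05d", seq_len(n_tip))
  counts <- matrix(rpois(n_tip * n_samp, 8), n_tip, n_samp,
                   dimnames = list(tree$tip.label,
                                   sprintf("s%d", seq_len(n_samp))))
  counts[1, 1] <- 0L; counts[3, 2] <- 0L
  tab <- make_table(counts, rep(c("MS", "HC"), length.out = n_samp),
                    depth = 100L)
  list(tree = tree, tab = tab)
}

test_that("UniFrac boundary cases", {
  fx <- random_beta_fixture()
  same <- fx$tab
  same$counts[, ] <- same$counts[, 1]      # identical columns
  expect_equal(max(abs(unifrac(same, fx$tree))), 0)
  expect_equal(max(abs(unifrac(same, fx$tree, weighted = TRUE))), 0)

  # two samples on disjoint halves of a star tree share no branches
  star <- ape::stree(4, "star")
  star$edge.length <- rep(1, 4)
  star$tip.label <- sprintf("rclust%05d", 1:4)
  cts <- cbind(s1 = c(5L, 5L, 0L, 0L), s2 = c(0L, 0L, 5L, 5L))
  rownames(cts) <- star$tip.label
  tab <- make_table(cts, c("MS", "HC"), depth = 10L)
  expect_equal(unifrac(tab, star)["s1", "s2"], 1)
  expect_error(unifrac(make_table(rbind(zzz = c(1L, 1L),
                                        cts[-1, ]), c("MS", "HC")), star),
               "absent from tree")
})

test_that("UniFrac agrees with the phyloseq implementation", {
  fx <- random_beta_fixture(n_tip = 8, n_samp = 6, seed = 72)
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(fx$tab$counts, taxa_are_rows = TRUE),
    phyloseq::phy_tree(fx$tree))
  for (w in c(FALSE, TRUE)) {
    mine <- unifrac(fx$tab, fx$tree, weighted = w, normalized = TRUE)
    ref <- as.matrix(phyloseq::UniFrac(ps, weighted = w, normalized = TRUE))
    expect_equal(mine[rownames(ref), colnames(ref)], ref, tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("unweighted UniFrac satisfies the metric axioms on random instances", {
  for (seed in 73:75) {
    fx <- random_beta_fixture(n_tip = 7, n_samp = 6, seed = seed)
    d <- unifrac(fx$tab, fx$tree)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(d, t(d))
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("weighted normalized UniFrac stays in [0, 1]", {
  fx <- random_beta_fixture(n_tip = 9, n_samp = 8, seed = 76)
  d <- unifrac(fx$tab, fx$tree, weighted = TRUE, normalized = TRUE)
  expect_true(all(d >= -1e-12 & d <= 1 + 1e-12))
})

test_that("PCoA reconstructs plane geometry and matches an eigen oracle", {
  pts <- cbind(c(0, 3, 3, 0), c(0, 0, 4, 4))
  d <- as.matrix(dist(pts))
  rownames(d) <- colnames(d) <- paste0("s", 1:4)
  ord <- pcoa_ord(d)
  rec <- as.matrix(dist(ord$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)
  expect_false(ord$degenerate)
  expect_true(all(diff(ord$explained) <= 1e-12))
  expect_lte(sum(ord$explained), 1 + 1e-12)

  # eigenvalues against a direct double-centering decomposition
  set.seed(77)
  fx <- random_beta_fixture(n_tip = 6, n_samp = 10, seed = 78)
  dd <- unifrac(fx$tab, fx$tree, weighted = TRUE)
  ordu <- pcoa_ord(dd)
  n <- nrow(dd)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (dd^2) %*% J
  ev <- sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  expect_equal(sort(ordu$eig, decreasing = TRUE), ev, tolerance = 1e-8)

  zero <- matrix(0, 3, 3, dimnames = list(paste0("z", 1:3), paste0("z", 1:3)))
  zres <- pcoa_ord(zero)
  expect_true(zres$degenerate)
  expect_equal(zres$explained, 0)
  expect_error(pcoa_ord(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("ANOSIM hits its definitional extremes and matches vegan's statistic", {
  # perfectly separated groups: all between > all within -> R = 1
  pts <- c(0, 0.1, 0.2, 10, 10.1, 10.2)
  d <- as.matrix(dist(pts))
  g <- rep(c("a", "b"), each = 3)
  res <- anosim_test(d, g, n_perm = 99, seed = 1)
  expect_equal(res$R, 1)
  # with 3+3 samples only 20 distinct assignments exist, so the smallest
  # attainable permutation p is about 0.1
  expect_lte(res$p, 0.25)
  van <- vegan::anosim(as.dist(d), g, permutations = 9)
  expect_equal(res$R, unname(van$statistic), tolerance = 1e-12)

  # labels independent of distances -> R near 0 on average
  set.seed(79)
  Rs <- replicate(40, {
    dd <- as.matrix(dist(rnorm(8)))
    anosim_test(dd, sample(rep(c("a", "b"), each = 4)), n_perm = 1,
                seed = 1)$R
  })
  expect_lt(abs(mean(Rs)), 0.15)
  expect_error(anosim_test(d, rep("a", 6)), "2 groups")
})

test_that("exact ANOSIM p equals the exhaustive-permutation oracle", {
  set.seed(80)
  d <- as.matrix(dist(c(rnorm(3), rnorm(3, 2))))
  rownames(d) <- colnames(d) <- paste0("s", 1:6)
  g <- rep(c("a", "b"), each = 3)
  mine <- anosim_test(d, g, exact = TRUE)
  orac <- anosim_oracle(d, g)
  expect_equal(mine$R, orac$R, tolerance = 1e-12)
  expect_equal(mine$p, orac$p, tolerance = 1e-12)
  expect_equal(mine$n_perm, choose(6, 3))
})

test_that("group distance summaries partition pairs and detect dispersion", {
  # study-sized label sets: 40 + 20 -> 780 / 800 / 190 pairs
  g <- c(rep("HC", 40), rep("MS", 20))
  d <- matrix(0, 60, 60)
  gs <- group_distance_summary(d, g, n_perm = 9)
  np <- stats::setNames(gs$summary$n_pairs, gs$summary$pair_set)
  expect_equal(unname(np[c("HC-HC", "HC-MS", "MS-MS")]), c(780L, 800L, 190L))
  expect_equal(gs$summary$mean, rep(0, 3))

  # planted higher dispersion in one group is detected
  set.seed(81)
  x <- c(rnorm(12, sd = 0.2), rnorm(12, sd = 3))
  dd <- as.matrix(dist(x))
  g2 <- rep(c("HC", "MS"), each = 12)
  gs2 <- group_distance_summary(dd, g2, n_perm = 500, seed = 4)
  sm <- stats::setNames(gs2$summary$mean, gs2$summary$pair_set)
  expect_gt(sm[["MS-MS"]], sm[["HC-HC"]])
  tst <- gs2$tests
  expect_lt(tst$p[tst$contrast == "MS-MS vs HC-HC"], 0.05)
})
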
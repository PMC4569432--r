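# Neighbor joining, the center-star alignment, and bootstrap support.

test_that("pairwise identity hits the constructed values", {
  set.seed(101)
  s <- rand_seq(100)
  m <- pairwise_identity(c(a = s, b = mutate_k(s, 4)))
  expect_equal(m["a", "a"], 1)
  expect_equal(m["a", "b"], 0.96)
  expect_error(pairwise_identity(c(a = "ACGT")), "two sequences")
  expect_error(pairwise_identity(c(a = "ACGT", b = "")), "empty")
})

test_that("NJ recovers small trees exactly", {
  # two taxa: single split of the distance
  d2 <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  t2 <- nj_tree(d2)
  expect_equal(sum(t2$edge.length), 0.4)
  expect_setequal(t2$tip.label, c("a", "b"))

  # three taxa: the three-point formulas
  dab <- 0.3; dac <- 0.5; dbc <- 0.6
  d3 <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  d3["a", "b"] <- d3["b", "a"] <- dab
  d3["a", "c"] <- d3["c", "a"] <- dac
  d3["b", "c"] <- d3["c", "b"] <- dbc
  t3 <- nj_tree(d3)
  el <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(unname(el["a"]), (dab + dac - dbc) / 2, tolerance = 1e-12)
  expect_equal(unname(el["b"]), (dab + dbc - dac) / 2, tolerance = 1e-12)
  expect_equal(unname(el["c"]), (dac + dbc - dab) / 2, tolerance = 1e-12)

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(nj_tree(matrix(c(0, NA, NA, 0), 2, 2)), "NA")
})

test_that("NJ is exact on additive matrices up to 12 taxa", {
  set.seed(102)
  for (n in c(5, 8, 12)) {
    true <- ape::rtree(n)
    true$edge.length <- true$edge.length + 0.05   # safely positive
    d <- ape::cophenetic.phylo(true)
    d <- d[sort(rownames(d)), sort(colnames(d))]
    fit <- nj_tree(d)
    expect_equal(attr(fit, "clamped"), 0)
    # identical topology and branch lengths <=> identical path distances
    dd <- ape::cophenetic.phylo(fit)[rownames(d), colnames(d)]
    expect_equal(dd, d, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(true), fit), 0,
                 ignore_attr = TRUE)
  }
})

test_that("center-star alignment reproduces indel-free inputs and degaps correctly", {
  set.seed(103)
  base <- rand_seq(80)
  seqs <- c(a = base, b = mutate_k(base, 5), c = mutate_k(base, 10))
  aln <- msa_center_star(seqs)
  expect_equal(dim(aln), c(3L, 80L))
  for (nm in names(seqs))
    expect_equal(paste(aln[nm, ], collapse = ""), seqs[[nm]])

  # a deletion relative to the center shows up as a gap, not lost bases
  seqs2 <- c(long = base, short = paste0(substr(base, 1, 30),
                                         substr(base, 41, 80)))
  aln2 <- msa_center_star(seqs2)
  degap <- function(x) gsub("-", "", paste(x, collapse = ""))
  expect_equal(degap(aln2["long", ]), seqs2[["long"]])
  expect_equal(degap(aln2["short", ]), seqs2[["short"]])
  expect_equal(sum(aln2["short", ] == "-"), 10L)
})

test_that("Newick serialisation round-trips", {
  set.seed(104)
  tree <- ape::rtree(7)
  nwk <- ape::write.tree(tree)
  back <- ape::read.tree(text = nwk)
  expect_identical(ape::write.tree(back), nwk)
})

test_that("bootstrap gives full support to cleanly separated clades", {
  # two 4-taxon clades separated by many fixed columns
  set.seed(105)
  blockA <- rand_seq(60); blockB <- mutate_k(blockA, 30)
  seqs <- c(vapply(1:4, function(i) mutate_k(blockA, 1), character(1)),
            vapply(1:4, function(i) mutate_k(blockB, 1), character(1)))
  names(seqs) <- c(paste0("a", 1:4), paste0("b", 1:4))
  bs <- bootstrap_support(seqs, n_reps = 100, seed = 5)
  sup <- attr(bs, "support")
  key_ab <- paste(sort(paste0("b", 1:4)), collapse = "|")
  expect_equal(sup$count[sup$bipartition == key_ab], 100L)
  expect_equal(attr(bs, "n_reps"), 100L)

  # determinism under a fixed seed
  bs2 <- bootstrap_support(seqs, n_reps = 100, seed = 5)
  expect_identical(attr(bs, "support"), attr(bs2, "support"))
  bs3 <- bootstrap_support(seqs, n_reps = 100, seed = 6)
  expect_identical(attr(bs3, "support")$bipartition, sup$bipartition)
})

test_that("bipartition supports are invariant to leaf order", {
  set.seed(106)
  base <- rand_seq(50)
  seqs <- stats::setNames(vapply(c(1, 2, 8, 9, 16, 17), function(k)
    mutate_k(base, k), character(1)), paste0("t", 1:6))
  bs1 <- attr(bootstrap_support(seqs, n_reps = 50, seed = 3), "support")
  perm <- seqs[c(4, 1, 6, 2, 5, 3)]
  bs2 <- attr(bootstrap_support(perm, n_reps = 50, seed = 3), "support")
  m1 <- stats::setNames(bs1$count, bs1$bipartition)
  m2 <- stats::setNames(bs2$count, bs2$bipartition)
  shared <- intersect(names(m1), names(m2))
  expect_setequal(names(m1), names(m2))
  expect_equal(m1[shared], m2[shared])
})

test_that("midpoint-rooted NJ from sequences recovers planted clades", {
  set.seed(107)
  blockA <- rand_seq(120); blockB <- mutate_k(blockA, 60)
  seqs <- c(a1 = mutate_k(blockA, 2), a2 = mutate_k(blockA, 2),
            b1 = mutate_k(blockB, 2), b2 = mutate_k(blockB, 2))
  tr <- nj_tree_from_seqs(seqs)
  expect_true(ape::is.rooted(tr))
  expect_true(ape::is.monophyletic(tr, c("a1", "a2")))
  expect_true(ape::is.monophyletic(tr, c("b1", "b2")))
})
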
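# Read mapping, cluster construction and the abundance filter.

test_that("exact substrings map at identity 1 and divergent reads fall out", {
  set.seed(31)
  refs <- stats::setNames(replicate(3, rand_seq(800)), c("refA", "refB", "refC"))
  reads <- make_reads(c(substr(refs[["refB"]], 101, 400),
                        mutate_k(substr(refs[["refC"]], 1, 300), 30)))
  mp <- map_reads(reads, refs)
  expect_equal(mp$hits$read_id, "r0001")
  expect_equal(mp$hits$ref_id, "refB")
  expect_equal(mp$hits$identity, 1)
  expect_equal(mp$unmapped, "r0002")  # 10% diverged -> below 96%
  expect_error(map_reads(reads, character(0)), "empty reference")
})

test_that("default mapping equals exhaustive mode and the alignment oracle", {
  set.seed(32)
  refs <- stats::setNames(replicate(15, rand_seq(700)), sprintf("R%02d", 1:15))
  src <- sample(15, 100, replace = TRUE)
  reads <- make_reads(vapply(src, function(s) {
    start <- sample(1:300, 1)
    mutate_k(substr(refs[[s]], start, start + 299), sample(0:20, 1))
  }, character(1)))
  fast <- map_reads(reads, refs)
  slow <- map_reads(reads, refs, exhaustive = TRUE)
  expect_identical(fast$hits, slow$hits)
  expect_identical(fast$unmapped, slow$unmapped)
  orac <- map_oracle(reads, refs)
  refs_sorted <- sort(names(refs))
  mapped_oracle <- !is.na(orac[, "ref"])
  expect_setequal(fast$hits$read_id, reads$id[mapped_oracle])
  idx <- match(fast$hits$read_id, reads$id)
  expect_equal(fast$hits$ref_id, refs_sorted[orac[idx, "ref"]])
  expect_equal(fast$hits$identity, unname(orac[idx, "identity"]),
               tolerance = 1e-12)
})

test_that("raising the identity threshold never grows the mapped set", {
  set.seed(33)
  refs <- stats::setNames(replicate(5, rand_seq(600)), sprintf("R%d", 1:5))
  reads <- make_reads(vapply(sample(5, 60, replace = TRUE), function(s)
    mutate_k(substr(refs[[s]], 51, 350), sample(0:25, 1)), character(1)))
  prev <- reads$id
  for (thr in c(0.90, 0.94, 0.96, 0.99)) {
    mapped <- map_reads(reads, refs, min_identity = thr)$hits$read_id
    expect_true(all(mapped %in% prev))
    prev <- mapped
  }
})

test_that("rclust construction groups hit references at 97%", {
  set.seed(34)
  a <- rand_seq(1500)
  refs <- c(a1 = a, a2 = mutate_k(a, 30),        # 98% pair -> one cluster
            b = mutate_k(a, 150))                # 90% -> its own cluster
  hits <- data.frame(read_id = c("x1", "x2", "x3"),
                     ref_id = c("a1", "a2", "b"),
                     identity = 1, coverage = 1, stringsAsFactors = FALSE)
  rcl <- build_rclust(hits, refs)
  expect_equal(nrow(rcl$clusters), 2L)
  cl_of <- stats::setNames(rcl$members$cluster_id, rcl$members$member_id)
  expect_equal(unname(cl_of["a1"]), unname(cl_of["a2"]))
  expect_false(cl_of[["a1"]] == cl_of[["b"]])
  # reads inherit their best-hit reference's cluster
  rc <- stats::setNames(rcl$read_clusters$cluster_id, rcl$read_clusters$read_id)
  expect_equal(unname(rc["x1"]), unname(cl_of["a1"]))
  expect_equal(unname(rc["x3"]), unname(cl_of["b"]))
  # only hit references are clustered
  hits2 <- hits[hits$ref_id != "b", ]
  expect_equal(nrow(build_rclust(hits2, refs)$clusters), 1L)
})

test_that("de-novo clustering of unmapped reads recovers planted species", {
  expect_equal(nrow(cluster_unmapped(make_reads(character(0)))$clusters), 0L)
  k_same <- make_reads(rep(strrep("ACGT", 75), 7))
  one <- cluster_unmapped(k_same)
  expect_equal(nrow(one$clusters), 1L)
  expect_equal(one$clusters$n_members, 7L)
  set.seed(35)
  species <- replicate(3, rand_seq(300))     # ~75% pairwise identity
  reads <- make_reads(unlist(lapply(1:3, function(s)
    replicate(10, mutate_k(species[s], 2)))))
  reads$true <- rep(1:3, each = 10)
  ucl <- cluster_unmapped(reads)
  expect_equal(nrow(ucl$clusters), 3L)
  got <- stats::setNames(ucl$read_clusters$cluster_id, ucl$read_clusters$read_id)
  expect_equal(length(unique(paste(reads$true, got[reads$id]))), 3L)
})

test_that("abundance filter keeps clusters reaching 0.1% in either group", {
  counts <- rbind(
    rclust00001 = c(9, 9, 0, 0),      # 0.3% in MS only -> retained
    rclust00002 = c(0, 0, 3, 3),      # exactly 0.1% in HC -> retained
    rclust00003 = c(2, 2, 2, 2),      # below in both -> removed
    unmap_OTU00001 = c(0, 0, 0, 0))   # all-zero -> removed
  colnames(counts) <- c("MS_1", "MS_2", "HC_1", "HC_2")
  tab <- make_table(counts, c("MS", "MS", "HC", "HC"))
  flt <- abundance_filter(tab)
  expect_setequal(rownames(flt$counts), c("rclust00001", "rclust00002"))
  rc <- attr(flt, "removal_counts")
  expect_equal(rc$removed[rc$kind == "rclust"], 1L)
  expect_equal(rc$removed[rc$kind == "unmap_OTU"], 1L)
  expect_error(abundance_filter(tab, groups = c("MS", "XX")), "XX")
})

test_that("abundance tables conserve reads per sample", {
  rc <- data.frame(read_id = sprintf("r%02d", 1:12),
                   cluster_id = rep(c("rclust00001", "unmap_OTU00001"), 6),
                   stringsAsFactors = FALSE)
  rs <- stats::setNames(rep(c("s1", "s2"), each = 6), rc$read_id)
  sheet <- data.frame(sample_id = c("s1", "s2"), subject_id = c("a", "b"),
                      group = c("MS", "HC"), timepoint = NA_integer_)
  tab <- make_abundance_table(rc, rs, sheet, depth = 6L)
  expect_equal(unname(colSums(tab$counts)), c(6L, 6L))
  expect_equal(dim(tab$counts), c(2L, 2L))
  expect_equal(unname(relative_abundance(tab)["rclust00001", "s1"]), 0.5)
})
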
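# Quality filtering, subsampling and primer trimming.

qual_str <- function(scores) intToUtf8(33 + scores)

test_that("mean-quality filter uses a strict threshold", {
  reads <- data.frame(id = c("q25", "q26"),
                      sequence = c("ACGT", "ACGT"),
                      quality = c(qual_str(rep(25, 4)), qual_str(rep(26, 4))),
                      stringsAsFactors = FALSE)
  kept <- quality_filter(reads)
  expect_equal(kept$id, "q26")
})

test_that("filter matches direct recomputation and is idempotent", {
  set.seed(21)
  n <- 100
  reads <- data.frame(
    id = sprintf("r%03d", 1:n), sequence = strrep("A", 50),
    quality = vapply(1:n, function(i)
      qual_str(sample(15:40, 50, replace = TRUE)), character(1)),
    stringsAsFactors = FALSE)
  direct <- vapply(reads$quality, function(q)
    mean(utf8ToInt(q) - 33), numeric(1))
  kept <- quality_filter(reads)
  expect_setequal(kept$id, reads$id[direct > 25])
  expect_identical(quality_filter(kept), kept)
})

test_that("malformed qualities raise a named error", {
  bad <- data.frame(id = "x", sequence = "ACGT", quality = "",
                    stringsAsFactors = FALSE)
  expect_error(quality_filter(bad), "x")
})

test_that("subsampling is exact, deterministic and content-preserving", {
  set.seed(22)
  reads <- make_reads(replicate(50, rand_seq(30)))
  expect_identical(subsample_reads(reads, depth = 50L), reads)  # n = depth
  s1 <- subsample_reads(reads, depth = 20L, seed = 9, sample_id = "A")
  s2 <- subsample_reads(reads, depth = 20L, seed = 9, sample_id = "A")
  expect_identical(s1, s2)
  expect_true(all(s1$id %in% reads$id))
  expect_identical(s1$sequence,
                   reads$sequence[match(s1$id, reads$id)])
  s3 <- subsample_reads(reads, depth = 20L, seed = 10, sample_id = "A")
  expect_false(identical(s1$id, s3$id))
  expect_error(subsample_reads(reads, depth = 60L, sample_id = "S9"), "S9")
})

test_that("primer trimming recovers the insert from the exact construction", {
  fwd <- v1v2_primers[["fwd"]]; rev <- v1v2_primers[["rev"]]
  fwd_site <- "AGAGTTTGATCCTGGCTCAG"   # matches the degenerate forward primer
  insert <- "TTTTGGGGCCCCAAAA"
  read <- paste0(fwd_site, insert, revcomp(rev))
  reads <- make_reads(read)
  tr <- trim_primers(reads)
  expect_equal(tr$reads$sequence, insert)
  expect_equal(nchar(tr$reads$quality), nchar(insert))
  # degenerate positions: 'a' under primer 'r' counts as a match
  read2 <- paste0("AGGGTTTGATTATGGCTCAG", insert, revcomp(rev))
  expect_equal(trim_primers(make_reads(read2))$reads$sequence, insert)
})

test_that("rejections follow the brute-force IUPAC mismatch scan", {
  set.seed(23)
  fwd_site <- "AGAGTTTGATCCTGGCTCAG"
  n <- 1000
  mm_planted <- sample(0:4, n, replace = TRUE)
  reads <- make_reads(vapply(mm_planted, function(k)
    paste0(mutate_k(fwd_site, k), rand_seq(60)), character(1)))
  tr <- trim_primers(reads, max_mismatch_fwd = 2L)
  # oracle: IUPAC-aware Hamming distance of the primer against the 5' end
  masks <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L, W = 9L,
             K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)
  pr <- strsplit(toupper(v1v2_primers[["fwd"]]), "")[[1]]
  mm_true <- vapply(reads$sequence, function(s) {
    sv <- strsplit(substr(s, 1, length(pr)), "")[[1]]
    sum(bitwAnd(masks[pr], masks[sv]) == 0L)
  }, numeric(1))
  expect_setequal(tr$reads$id, reads$id[mm_true <= 2])
  expect_setequal(tr$rejected$id, reads$id[mm_true > 2])
})

test_that("trimming never lengthens reads and keeps qualities aligned", {
  set.seed(24)
  fwd_site <- "AGAGTTTGATCCTGGCTCAG"
  reads <- make_reads(vapply(1:20, function(i)
    paste0(fwd_site, rand_seq(sample(40:80, 1))), character(1)))
  tr <- trim_primers(reads)
  expect_true(all(nchar(tr$reads$sequence) <=
                  nchar(reads$sequence[match(tr$reads$id, reads$id)])))
  expect_equal(nchar(tr$reads$sequence), nchar(tr$reads$quality))
})
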
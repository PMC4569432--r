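# The synthetic-community generator: determinism, planted defects,
# planted effects, and read-level ground truth.

small_config <- function(seed = 201, effects = NULL) {
  sim_config(seed = seed, n_ref_species = 24, n_novel_species = 3,
             n_community_species = 20,
             defect_counts = c(short = 3L, ambiguous = 2L, eukaryote = 1L),
             planted_effects = effects,
             n_case_samples = 3, n_control_samples = 3,
             n_longitudinal_subjects = 2, n_timepoints = 2)
}

test_that("configuration invariants are enforced", {
  expect_error(sim_config(reads_per_sample = 1000), ">= 3000")
  expect_error(sim_config(defect_counts = c(short = -1L, ambiguous = 0L,
                                            eukaryote = 0L)), "non-negative")
  expect_error(small_config(effects = data.frame(log10_fc = rep(-1, 5),
                                                 novel = rep(TRUE, 5))),
               "novel")
  expect_error(simulate_ref_metadata(10, c(short = 8L, ambiguous = 2L,
                                           eukaryote = 1L)), "exceed")
})

test_that("the same seed gives byte-identical outputs", {
  cfg <- small_config()
  t1 <- simulate_species_backbone(cfg)
  t2 <- simulate_species_backbone(cfg)
  expect_identical(t1$fl_seqs, t2$fl_seqs)
  expect_identical(t1$composition, t2$composition)
  r1 <- generate_reference_db(cfg, t1)$records
  r2 <- generate_reference_db(cfg, t2)$records
  expect_identical(r1, r2)
  p <- stats::setNames(t1$composition$control, t1$composition$species)
  s1 <- generate_sample_reads(cfg, t1, "HC_01", p)
  s2 <- generate_sample_reads(cfg, t1, "HC_01", p)
  expect_identical(s1, s2)
  s3 <- generate_sample_reads(cfg, t1, "HC_02", p)
  expect_false(identical(s1$sequence, s3$sequence))
  # FASTA bytes round-trip identically
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_fasta(t1$fl_seqs, f1); write_fasta(t2$fl_seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted reference defects are exact, disjoint and ordered", {
  cfg <- small_config()
  rec <- generate_reference_db(cfg)$records
  expect_equal(sum(rec$source == "short"), 3L)
  expect_equal(sum(rec$source == "ambiguous"), 2L)
  expect_equal(sum(rec$source == "eukaryote"), 1L)
  expect_true(all(rec$length[rec$source == "short"] < 1400))
  expect_true(all(rec$ambiguous_count[rec$source == "ambiguous"] >= 4))
  expect_true(all(rec$length[rec$source == "ambiguous"] >= 1400))
  expect_true(all(rec$eukaryote_flag[rec$source == "eukaryote"]))
  clean <- rec[rec$source == "clean", ]
  expect_true(all(clean$length >= 1400 & clean$ambiguous_count <= 3 &
                  !clean$eukaryote_flag))
  flt <- filter_references(rec)
  expect_equal(nrow(flt$retained), nrow(clean))
  expect_equal(unname(flt$removal_counts), c(3L, 2L, 1L))
})

test_that("reference redundancy copies stay within the dereplication radius", {
  cfg <- small_config()
  ref <- generate_reference_db(cfg)
  rec <- ref$records[ref$records$source == "clean", ]
  for (sp in unique(rec$species)[1:5]) {
    copies <- rec$sequence[rec$species == sp]
    if (length(copies) < 2) next
    idm <- pairwise_identity(stats::setNames(copies, seq_along(copies)))
    expect_true(all(idm[upper.tri(idm)] >= 0.998))
  }
})

test_that("planted effects shift case proportions exactly", {
  eff <- data.frame(log10_fc = c(-1, 0.4), novel = c(FALSE, TRUE))
  cfg <- small_config(effects = eff)
  truth <- simulate_species_backbone(cfg)
  comp <- truth$composition
  e <- truth$effects
  down <- e$species[e$log10_fc == -1]
  up <- e$species[e$log10_fc == 0.4]
  expect_equal(comp$case[comp$species == down],
               0.1 * comp$control[comp$species == down], tolerance = 1e-12)
  expect_equal(comp$case[comp$species == up],
               10^0.4 * comp$control[comp$species == up], tolerance = 1e-12)
  expect_equal(sum(comp$case), 1, tolerance = 1e-12)
  expect_equal(sum(comp$control), 1, tolerance = 1e-12)
  # novel planted species are absent from the reference database
  expect_false(any(truth$species$in_db[truth$species$id == up]))
})

test_that("noiseless reads are exact amplicon substrings and trace to their species", {
  cfg <- small_config()
  cfg$error_rate <- 0
  truth <- simulate_species_backbone(cfg)
  one <- truth$composition$species[1]
  p <- stats::setNames(rep(0, nrow(truth$composition)),
                       truth$composition$species)
  p[one] <- 1
  reads <- generate_sample_reads(cfg, truth, "S1", p, conc = 1e9, n_raw = 50)
  expect_true(all(reads$species == one))
  expect_true(all(reads$sequence == truth$amplicons[[one]]))
  trm <- trim_primers(reads)
  expect_true(all(trm$reads$sequence == truth$cores[[one]]))
})

test_that("read counts follow the composition within multinomial tolerance", {
  cfg <- small_config()
  truth <- simulate_species_backbone(cfg)
  p <- stats::setNames(truth$composition$control, truth$composition$species)
  n <- 6000
  reads <- generate_sample_reads(cfg, truth, "S2", p, conc = 1e9, n_raw = n)
  got <- table(factor(reads$species, levels = names(p)))
  expected <- n * p
  sdv <- sqrt(n * p * (1 - p))
  dev <- abs(got - expected) / pmax(sdv, 1)
  expect_true(all(dev < 5))
})

test_that("metadata-scale reference profiles honour the planted category counts", {
  md <- simulate_ref_metadata(5000, c(short = 700L, ambiguous = 150L,
                                      eukaryote = 50L), seed = 9)
  expect_equal(nrow(md), 5000L)
  flt <- filter_references(md)
  expect_equal(unname(flt$removal_counts), c(700L, 150L, 50L))
  expect_equal(nrow(flt$retained), 5000L - 900L)
  md2 <- simulate_ref_metadata(5000, c(short = 700L, ambiguous = 150L,
                                       eukaryote = 50L), seed = 9)
  expect_identical(md, md2)
})

test_that("the sample sheet matches the study design", {
  cfg <- sim_config(seed = 1)
  sheet <- sample_sheet(cfg)
  expect_equal(sum(sheet$group == "MS"), 20L)
  expect_equal(sum(sheet$group == "HC"), 40L)
  expect_equal(sum(sheet$group == "HC_long"), 18L * 9L)
  expect_equal(length(unique(sheet$subject_id[sheet$group == "HC_long"])), 18L)
  expect_false(any(duplicated(sheet$sample_id)))
})
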
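# Synthetic reference collections: full-sequence databases with planted
# redundancy and defective records, plus a metadata-only generator for
# database-scale filter accounting where materialising hundreds of thousands
# of full-length sequences would add nothing.

#' Generate a raw reference 16S collection with planted defects
#'
#' Produces the unfiltered reference collection the database-construction
#' stage consumes: for every database species, 1 or more near-identical
#' copies (>= 99.8% mutual identity), plus the configured numbers of
#' defective records - short (< 1,400 bp), ambiguous (>= 4 non-ACGT bases)
#' and putatively eukaryotic ones.  Defect categories are disjoint.
#'
#' @param config a [sim_config()].
#' @param truth a `sim_truth` from [simulate_species_backbone()]; generated
#'   from `config` when omitted.
#' @return list with `records` (data.frame: `id`, `sequence`, `length`,
#'   `ambiguous_count`, `eukaryote_flag`, `source`, `species`) and `truth`.
#' @export
generate_reference_db <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(truth)) truth <- simulate_species_backbone(config)
  set.seed(derive_seed(config$seed, "refdb"))

  db_sp <- truth$species$id[truth$species$in_db]
  ncopy <- sample(config$redundancy, length(db_sp), replace = TRUE)
  ids <- character(0); seqs <- character(0); species <- character(0)
  for (k in seq_along(db_sp)) {
    sp <- db_sp[k]
    base <- truth$fl_seqs[[sp]]
    for (c in seq_len(ncopy[k])) {
      s <- base
      if (c > 1) s <- point_mutate(s, n_subs = sample(0:2, 1))
      ids <- c(ids, sprintf("%s_copy%d", sp, c))
      seqs <- c(seqs, s)
      species <- c(species, sp)
    }
  }
  n_clean <- length(ids)

  dc <- config$defect_counts
  def_ids <- character(0); def_seqs <- character(0); def_src <- character(0)
  def_euk <- logical(0)
  if (dc[["short"]] > 0) {
    src <- sample(db_sp, dc[["short"]], replace = TRUE)
    lens <- sample(900:1399, dc[["short"]], replace = TRUE)
    def_seqs <- c(def_seqs, substr(truth$fl_seqs[src], 1, lens))
    def_ids <- c(def_ids, sprintf("DEFECT_short_%03d", seq_len(dc[["short"]])))
    def_src <- c(def_src, rep("short", dc[["short"]]))
    def_euk <- c(def_euk, rep(FALSE, dc[["short"]]))
  }
  if (dc[["ambiguous"]] > 0) {
    src <- sample(db_sp, dc[["ambiguous"]], replace = TRUE)
    sq <- vapply(truth$fl_seqs[src], function(s) {
      pos <- sample(nchar(s), sample(4:8, 1))
      for (p in pos) substr(s, p, p) <- "N"
      s
    }, character(1), USE.NAMES = FALSE)
    def_seqs <- c(def_seqs, sq)
    def_ids <- c(def_ids, sprintf("DEFECT_ambig_%03d", seq_len(dc[["ambiguous"]])))
    def_src <- c(def_src, rep("ambiguous", dc[["ambiguous"]]))
    def_euk <- c(def_euk, rep(FALSE, dc[["ambiguous"]]))
  }
  if (dc[["eukaryote"]] > 0) {
    sq <- random_dna(dc[["eukaryote"]], 1500)
    def_seqs <- c(def_seqs, sq)
    def_ids <- c(def_ids, sprintf("DEFECT_euk_%03d", seq_len(dc[["eukaryote"]])))
    def_src <- c(def_src, rep("eukaryote", dc[["eukaryote"]]))
    def_euk <- c(def_euk, rep(TRUE, dc[["eukaryote"]]))
  }

  all_ids <- c(ids, def_ids)
  all_seqs <- c(seqs, def_seqs)
  records <- data.frame(
    id = all_ids, sequence = unname(all_seqs),
    length = nchar(all_seqs),
    ambiguous_count = count_ambiguous(all_seqs),
    eukaryote_flag = c(rep(FALSE, n_clean), def_euk),
    source = c(rep("clean", n_clean), def_src),
    species = c(species, rep(NA_character_, length(def_ids))),
    stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

point_mutate <- function(s, n_subs) {
  if (n_subs == 0) return(s)
  pos <- sample(nchar(s), n_subs)
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(bases, cur), 1)
  }
  s
}

#' Metadata-only reference collection for filter accounting
#'
#' Builds a record table with realistic lengths, ambiguous-base counts and
#' eukaryote flags but no sequence strings (`sequence` is `NA`), sized for
#' database-scale accounting checks of the quality filter.  Defect
#' categories are disjoint and applied in the documented filter order:
#' `short` records are < 1,400 bp regardless of other fields, `ambiguous`
#' records are full-length with >= 4 ambiguous bases, `eukaryote` records
#' are full-length, low-ambiguity and flagged.
#'
#' @param n_total total number of records.
#' @param defect_counts named vector `short`, `ambiguous`, `eukaryote`.
#' @param seed integer seed.
#' @return data.frame shaped like the `records` element of
#'   [generate_reference_db()].
#' @export
simulate_ref_metadata <- function(n_total,
                                  defect_counts = c(short = 0L, ambiguous = 0L,
                                                    eukaryote = 0L),
                                  seed = 1L) {
  dc <- defect_counts
  if (sum(dc) > n_total) stop("defects exceed the total record count")
  set.seed(derive_seed(seed, "ref-metadata"))
  n_clean <- n_total - sum(dc)
  cat_lab <- rep(c("clean", "short", "ambiguous", "eukaryote"),
                 c(n_clean, dc[["short"]], dc[["ambiguous"]], dc[["eukaryote"]]))
  len <- integer(n_total)
  amb <- integer(n_total)
  euk <- logical(n_total)
  is_clean <- cat_lab == "clean"
  is_short <- cat_lab == "short"
  is_amb <- cat_lab == "ambiguous"
  is_euk <- cat_lab == "eukaryote"
  len[is_clean | is_amb | is_euk] <-
    1400L + stats::rbinom(sum(!is_short), 200, 0.5)
  len[is_short] <- sample(600:1399, sum(is_short), replace = TRUE)
  amb[is_clean | is_euk] <- sample(0:3, sum(is_clean) + sum(is_euk),
                                   replace = TRUE, prob = c(.85, .09, .04, .02))
  amb[is_short] <- sample(0:6, sum(is_short), replace = TRUE)
  amb[is_amb] <- 4L + stats::rbinom(sum(is_amb), 6, 0.3)
  euk[is_euk] <- TRUE
  ord <- sample(n_total)
  data.frame(id = sprintf("REF_%06d", seq_len(n_total)),
             sequence = NA_character_, length = len[ord],
             ambiguous_count = amb[ord], eukaryote_flag = euk[ord],
             source = cat_lab[ord], species = NA_character_,
             stringsAsFactors = FALSE)
}
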
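# End-to-end orchestration: reference database -> read prep -> mapping ->
# cluster construction -> abundance filtering -> taxonomy -> diversity ->
# differential abundance -> longitudinal validation -> phylogeny, with a
# read-accounting report.

#' Read-accounting percentages
#'
#' The bookkeeping the pipeline reports: overall mapped percentage and
#' per-group unmapped percentages, rounded to one decimal.
#'
#' @param mapped named integer vector of mapped read counts per group.
#' @param unmapped named integer vector (same names) of unmapped counts.
#' @return list with `total`, `mapped_total`, `unmapped_total`,
#'   `mapped_percent` (overall, one decimal), `unmapped_percent` (per
#'   group), `mapped`, `unmapped`.
#' @export
read_accounting <- function(mapped, unmapped) {
  stopifnot(identical(sort(names(mapped)), sort(names(unmapped))))
  unmapped <- unmapped[names(mapped)]
  tot <- mapped + unmapped
  list(total = sum(tot), mapped_total = sum(mapped),
       unmapped_total = sum(unmapped),
       mapped_percent = round(100 * sum(mapped) / sum(tot), 1),
       unmapped_percent = round(100 * unmapped / tot, 1),
       mapped = mapped, unmapped = unmapped)
}

#' Pipeline thresholds
#'
#' Every identity/abundance threshold of the pipeline in one place.
#'
#' @param min_len,max_ambiguous,derep_id reference database construction.
#' @param depth,min_mean_q read preparation.
#' @param map_id,map_cov read mapping acceptance.
#' @param rclust_id,denovo_id,otu_id clustering thresholds.
#' @param min_abund minimum group-mean relative abundance.
#' @param alpha significance level.
#' @return named list.
#' @export
pipeline_params <- function(min_len = 1400L, max_ambiguous = 3L,
                            derep_id = 0.998, depth = 3000L, min_mean_q = 25,
                            map_id = 0.96, map_cov = 0.90, rclust_id = 0.97,
                            denovo_id = 0.96, otu_id = 0.96,
                            min_abund = 0.001, alpha = 0.05) {
  as.list(environment())
}

#' Run the full analysis on a synthetic study
#'
#' Generates the study inputs from `config`, executes every stage in order
#' and returns the stage outputs plus a read-accounting report.  Reads are
#' generated, quality-filtered, subsampled and trimmed one sample at a time
#' so memory stays flat at full scale.
#'
#' @param config a [sim_config()].
#' @param params a [pipeline_params()].
#' @param longitudinal simulate and validate the longitudinal series.
#' @param do_alpha compute per-sample alpha diversity (the costliest
#'   optional stage).
#' @param do_beta compute the cluster tree, UniFrac, PCoA and ANOSIM.
#' @param n_perm permutations for ANOSIM.
#' @param verbose print per-stage progress.
#' @return list with `truth`, `refdb`, `prep_counts`, `accounting`,
#'   `clusters`, `table_all`, `table` (filtered, cross-sectional),
#'   `long_table`, `taxonomy`, `alpha`, `beta`, `diff`, `longitudinal`,
#'   `params`, `config`.
#' @export
run_synthetic_study <- function(config, params = pipeline_params(),
                                longitudinal = TRUE, do_alpha = FALSE,
                                do_beta = TRUE, n_perm = 2000L,
                                verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  stopifnot(inherits(config, "sim_config"))

  say("simulating backbone + reference collection")
  ref <- generate_reference_db(config)
  truth <- ref$truth
  say("building reference database")
  db <- build_refdb(ref$records, params$min_len, params$max_ambiguous,
                    params$derep_id)

  say("generating and preparing samples")
  prepped <- list()
  prep_counts <- list()
  gen <- generate_samples(config, truth, longitudinal = longitudinal,
                          callback = function(sid, reads) {
                            pr <- prep_sample(reads, sid, params$depth,
                                              params$min_mean_q, config$seed)
                            prepped[[sid]] <<- pr$reads
                            prep_counts[[sid]] <<- pr$counts
                          })
  sheet <- gen$sheet
  prep_counts <- do.call(rbind, prep_counts[sheet$sample_id])

  cross_ids <- sheet$sample_id[sheet$group %in% c("MS", "HC")]
  long_ids <- sheet$sample_id[sheet$group == "HC_long"]

  say("mapping reads")
  all_reads <- do.call(rbind, lapply(sheet$sample_id, function(sid) {
    r <- prepped[[sid]]
    r$sample_id <- sid
    r[, c("id", "sequence", "sample_id")]
  }))
  mp <- map_reads(all_reads, db$db, params$map_id, params$map_cov)
  read_sample <- stats::setNames(all_reads$sample_id, all_reads$id)

  say("building species-level clusters")
  cross_reads <- read_sample[mp$hits$read_id] %in% cross_ids
  rcl <- build_rclust(mp$hits[cross_reads, , drop = FALSE], db$db,
                      params$rclust_id)
  # longitudinal mapped reads inherit the rclust of their best-hit reference
  ref2cl <- stats::setNames(rcl$members$cluster_id, rcl$members$member_id)
  long_hits <- mp$hits[!cross_reads, , drop = FALSE]
  long_rc <- data.frame(read_id = long_hits$read_id,
                        cluster_id = unname(ref2cl[long_hits$ref_id]),
                        stringsAsFactors = FALSE)
  long_rc <- long_rc[!is.na(long_rc$cluster_id), , drop = FALSE]

  unmapped_reads <- all_reads[all_reads$id %in% mp$unmapped, , drop = FALSE]
  un_cross <- unmapped_reads[unmapped_reads$sample_id %in% cross_ids, ,
                             drop = FALSE]
  ucl <- cluster_unmapped(un_cross, params$denovo_id)
  # longitudinal unmapped reads are quantified against the OTUs the
  # cross-sectional study defined
  un_long <- unmapped_reads[unmapped_reads$sample_id %in% long_ids, ,
                            drop = FALSE]
  long_uc <- data.frame(read_id = character(0), cluster_id = character(0))
  if (nrow(un_long) > 0 && nrow(ucl$clusters) > 0) {
    reps <- stats::setNames(ucl$clusters$representative_seq,
                            ucl$clusters$cluster_id)
    mm <- map_reads(un_long[, c("id", "sequence")], reps, params$denovo_id,
                    params$map_cov)
    long_uc <- data.frame(read_id = mm$hits$read_id,
                          cluster_id = mm$hits$ref_id,
                          stringsAsFactors = FALSE)
  }

  read_clusters <- rbind(rcl$read_clusters, ucl$read_clusters, long_rc, long_uc)
  clusters <- merge_cluster_tables(rcl$clusters, ucl$clusters, db$db)

  say("assembling abundance tables")
  tab_all <- make_abundance_table(read_clusters, read_sample, sheet,
                                  params$depth)
  cross_tab <- subset_abundance(tab_all, samples = cross_ids)
  say("abundance filter")
  tab <- abundance_filter(cross_tab, params$min_abund, groups = c("MS", "HC"))
  long_tab <- if (longitudinal && length(long_ids))
    subset_abundance(tab_all, samples = long_ids,
                     clusters = rownames(tab$counts)) else NULL

  mapped_by_group <- tapply_count(mp$hits$read_id, read_sample, sheet)
  unmapped_by_group <- tapply_count(mp$unmapped, read_sample, sheet)
  accounting <- list(
    cross = read_accounting(mapped_by_group$cross, unmapped_by_group$cross),
    clusters_total = c(rclust = nrow(rcl$clusters),
                       unmap_OTU = nrow(ucl$clusters)),
    clusters_retained = c(rclust = sum(tab$kind == "rclust"),
                          unmap_OTU = sum(tab$kind == "unmap_OTU")),
    prep = prep_counts)

  say("taxonomy")
  lineage <- truth_lineage(truth, ref$records)
  retained <- clusters[clusters$cluster_id %in% rownames(tab$counts), ,
                       drop = FALSE]
  taxa <- assign_clusters(retained, db$db, lineage)

  alpha <- NULL
  if (do_alpha) {
    say("alpha diversity")
    alpha <- alpha_diversity(prepped[cross_ids], params$otu_id, params$depth)
    alpha$group <- sheet$group[match(alpha$sample_id, sheet$sample_id)]
  }

  say("differential abundance")
  diff <- diff_abundance(tab, "MS", "HC", params$alpha)
  long_val <- if (!is.null(long_tab) && any(diff$significant))
    longitudinal_validation(diff, long_tab) else NULL

  beta <- NULL
  if (do_beta) {
    say("beta diversity")
    rep_seqs <- cluster_rep_v1v2(retained, truth, db$db)
    tree <- nj_tree_from_seqs(rep_seqs)
    duf <- unifrac(tab, tree, weighted = FALSE)
    wuf <- unifrac(tab, tree, weighted = TRUE, normalized = TRUE)
    grp <- tab$sheet$group[match(colnames(tab$counts), tab$sheet$sample_id)]
    beta <- list(
      tree = tree,
      unweighted = list(d = duf, pcoa = pcoa_ord(duf),
                        anosim = anosim_test(duf, grp, n_perm, config$seed),
                        groups = group_distance_summary(duf, grp,
                                                        seed = config$seed)),
      weighted = list(d = wuf, pcoa = pcoa_ord(wuf),
                      anosim = anosim_test(wuf, grp, n_perm, config$seed),
                      groups = group_distance_summary(wuf, grp,
                                                      seed = config$seed)))
  }

  list(truth = truth, refdb = db, prep_counts = prep_counts,
       accounting = accounting, clusters = clusters, table_all = tab_all,
       table = tab, long_table = long_tab, taxonomy = taxa, alpha = alpha,
       beta = beta, diff = diff, longitudinal = long_val, params = params,
       config = config)
}

# per-group mapped/unmapped counts for the cross-sectional samples
tapply_count <- function(read_ids, read_sample, sheet) {
  grp <- sheet$group[match(read_sample[read_ids], sheet$sample_id)]
  cross <- grp %in% c("MS", "HC")
  cnt <- table(factor(grp[cross], levels = c("HC", "MS")))
  list(cross = stats::setNames(as.integer(cnt), names(cnt)))
}

# unified cluster table with V1-V2 representative sequences available
merge_cluster_tables <- function(rclusters, uclusters, db) {
  empty <- data.frame(cluster_id = character(0), kind = character(0),
                      representative_id = character(0),
                      n_members = integer(0),
                      representative_seq = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(rclusters) || nrow(rclusters) == 0) rclusters <- empty
  if (is.null(uclusters) || nrow(uclusters) == 0) uclusters <- empty
  if (nrow(rclusters) > 0) {
    rclusters$representative_seq <- NA_character_
    cols <- c("cluster_id", "kind", "representative_id", "n_members",
              "representative_seq")
    rclusters <- rclusters[, cols]
  }
  if (nrow(uclusters) > 0) {
    uclusters <- uclusters[, c("cluster_id", "kind", "representative_id",
                               "n_members", "representative_seq")]
  }
  out <- rbind(rclusters, uclusters)
  rownames(out) <- NULL
  out
}

# lineage table for the synthetic reference database
truth_lineage <- function(truth, records) {
  sp <- truth$species
  rec <- records[records$source == "clean", ]
  data.frame(ref_id = rec$id,
             species = rec$species,
             genus = sp$genus[match(rec$species, sp$id)],
             phylum = sp$phylum[match(rec$species, sp$id)],
             stringsAsFactors = FALSE)
}

# V1-V2 representative sequence per retained cluster: the trimmed amplicon
# core of the rclust representative's species, or the representative read
cluster_rep_v1v2 <- function(clusters, truth, db) {
  out <- character(nrow(clusters))
  for (i in seq_len(nrow(clusters))) {
    if (clusters$kind[i] == "rclust") {
      ref_seq <- db[[clusters$representative_id[i]]]
      out[i] <- extract_v1v2(ref_seq)
    } else {
      out[i] <- clusters$representative_seq[i]
    }
  }
  stats::setNames(out, clusters$cluster_id)
}

# locate the primer sites on a full-length sequence and return the insert
extract_v1v2 <- function(seq, fwd = v1v2_primers[["fwd"]],
                         rev = v1v2_primers[["rev"]]) {
  al_f <- align_overlap(toupper(fwd), seq)
  rc <- revcomp(toupper(rev))
  al_r <- align_overlap(rc, seq)
  if (al_f$identity < 0.8 || al_r$identity < 0.8 || al_r$b_start <= al_f$b_end)
    stop("primer sites not found on reference sequence")
  substr(seq, al_f$b_end + 1, al_r$b_start - 1)
}
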
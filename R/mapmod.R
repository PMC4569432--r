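# Core profiling engine: best-hit mapping of reads to the reference
# database, species-level clustering of mapped references ("rclust"),
# de-novo clustering of unmapped reads ("unmap_OTU"), and abundance-table
# assembly with the minimum-abundance filter.

#' Map reads to a reference database
#'
#' Each read receives its best reference hit (highest identity, then highest
#' coverage, then smallest reference id) when some hit passes both the
#' identity and coverage thresholds; otherwise it is reported unmapped.
#' Candidate references are ranked by shared 8-mers and aligned with the
#' banded semi-global kernel; `exhaustive = TRUE` disables all pruning and
#' aligns every reference with the full dynamic program (used by the oracle
#' tests; identical results are asserted there on small instances).
#'
#' @param reads data.frame with `id`, `sequence`.
#' @param refdb named character vector of reference sequences.
#' @param min_identity,min_coverage acceptance thresholds (defaults 0.96 and
#'   0.90).
#' @param top_n candidates aligned per read; `band` alignment band
#'   half-width; `stop_after` early-stop after this many non-improving
#'   candidates.
#' @param exhaustive disable the k-mer prefilter, band and early stop.
#' @return list with `hits` (data.frame `read_id`, `ref_id`, `identity`,
#'   `coverage`), `unmapped` (read ids) and `best_below` (best sub-threshold
#'   hit per unmapped read, where one exists).
#' @export
map_reads <- function(reads, refdb, min_identity = 0.96, min_coverage = 0.90,
                      top_n = 50L, band = 16L, stop_after = 6L,
                      exhaustive = FALSE) {
  if (length(refdb) == 0) stop("empty reference database")
  if (is.null(names(refdb))) stop("reference database must be named")
  refdb <- refdb[order(names(refdb))]
  if (exhaustive) {
    top_n <- length(refdb); band <- -1L; stop_after <- length(refdb) + 1L
  }
  res <- cpp_map_reads(reads$sequence, unname(refdb), min_identity,
                       min_coverage, k = 8L, top_n = top_n, band = band,
                       stop_after = stop_after, prune = !exhaustive)
  mapped <- !is.na(res$ref) & res$ref > 0
  below <- !is.na(res$ref) & res$ref < 0
  hits <- data.frame(read_id = reads$id[mapped],
                     ref_id = names(refdb)[res$ref[mapped]],
                     identity = res$identity[mapped],
                     coverage = res$coverage[mapped],
                     stringsAsFactors = FALSE)
  best_below <- data.frame(read_id = reads$id[below],
                           ref_id = names(refdb)[-res$ref[below]],
                           identity = res$identity[below],
                           coverage = res$coverage[below],
                           stringsAsFactors = FALSE)
  list(hits = hits, unmapped = reads$id[!mapped], best_below = best_below)
}

#' Cluster mapped references into species-level units
#'
#' Only references that received at least one read are clustered (greedy,
#' full-length, 97% identity by default); each read's count transfers to
#' the cluster containing its best-hit reference.
#'
#' @param hits hit table from [map_reads()].
#' @param refdb named reference sequences.
#' @param threshold full-length clustering identity (default 0.97).
#' @param band alignment band half-width (see [dereplicate()]).
#' @return list with `clusters` (data.frame `cluster_id`, `kind`,
#'   `representative_id`, `n_members`), `members` (`cluster_id`,
#'   `member_id`), `read_clusters` (`read_id`, `cluster_id`).
#' @export
build_rclust <- function(hits, refdb, threshold = 0.97, band = 64L) {
  if (nrow(hits) == 0)
    return(list(clusters = data.frame(), members = data.frame(),
                read_clusters = data.frame(read_id = character(0),
                                           cluster_id = character(0))))
  hit_refs <- sort(unique(hits$ref_id))
  cl <- greedy_cluster(refdb[hit_refs], threshold, band = band)
  ids <- sprintf("rclust%05d", cl$cluster)
  ref2cl <- stats::setNames(ids, cl$id)
  cent <- attr(cl, "centroids")
  clusters <- data.frame(cluster_id = sprintf("rclust%05d", seq_along(cent)),
                         kind = "rclust", representative_id = cent,
                         n_members = as.integer(table(cl$cluster)),
                         stringsAsFactors = FALSE)
  list(clusters = clusters,
       members = data.frame(cluster_id = unname(ref2cl[cl$id]),
                            member_id = cl$id, stringsAsFactors = FALSE),
       read_clusters = data.frame(read_id = hits$read_id,
                                  cluster_id = unname(ref2cl[hits$ref_id]),
                                  stringsAsFactors = FALSE))
}

#' Cluster unmapped reads de novo
#'
#' Greedy clustering of the unmapped reads themselves (96% identity by
#' default); one de-novo OTU per cluster, represented by its founding read.
#'
#' @param reads data.frame of unmapped reads (`id`, `sequence`).
#' @param threshold identity threshold (default 0.96).
#' @param band alignment band half-width for read-vs-read comparisons.
#' @return same shape as [build_rclust()]; cluster ids `unmap_OTU...`; the
#'   `clusters` table carries the representative read sequence in
#'   `representative_seq`.
#' @export
cluster_unmapped <- function(reads, threshold = 0.96, band = 24L) {
  if (nrow(reads) == 0)
    return(list(clusters = data.frame(cluster_id = character(0),
                                      kind = character(0),
                                      representative_id = character(0),
                                      n_members = integer(0),
                                      representative_seq = character(0),
                                      stringsAsFactors = FALSE),
                members = data.frame(),
                read_clusters = data.frame(read_id = character(0),
                                           cluster_id = character(0))))
  seqs <- stats::setNames(reads$sequence, reads$id)
  cl <- greedy_cluster(seqs, threshold, band = band)
  cent <- attr(cl, "centroids")
  ids <- sprintf("unmap_OTU%05d", seq_along(cent))
  clusters <- data.frame(cluster_id = ids, kind = "unmap_OTU",
                         representative_id = cent,
                         n_members = as.integer(table(cl$cluster)),
                         representative_seq = unname(seqs[cent]),
                         stringsAsFactors = FALSE)
  list(clusters = clusters,
       members = data.frame(cluster_id = ids[cl$cluster], member_id = cl$id,
                            stringsAsFactors = FALSE),
       read_clusters = data.frame(read_id = cl$id,
                                  cluster_id = ids[cl$cluster],
                                  stringsAsFactors = FALSE))
}

#' Assemble the cluster-by-sample abundance table
#'
#' @param read_clusters data.frame `read_id`, `cluster_id`.
#' @param read_samples named character vector read id -> sample id.
#' @param sheet sample sheet (defines the column set and groups).
#' @param depth fixed per-sample profiling depth.
#' @return object of class `abundance_table`: list with `counts` (clusters x
#'   samples integer matrix), `depth`, `sheet`, `kind` (per-cluster).
#' @export
make_abundance_table <- function(read_clusters, read_samples, sheet,
                                 depth = 3000L) {
  samp <- read_samples[read_clusters$read_id]
  if (anyNA(samp)) stop("reads without sample assignment")
  cl_ids <- sort(unique(read_clusters$cluster_id))
  counts <- matrix(0L, nrow = length(cl_ids), ncol = nrow(sheet),
                   dimnames = list(cl_ids, sheet$sample_id))
  tab <- table(read_clusters$cluster_id, factor(samp, levels = sheet$sample_id))
  counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  out <- list(counts = counts, depth = as.integer(depth), sheet = sheet,
              kind = ifelse(grepl("^rclust", cl_ids), "rclust", "unmap_OTU"))
  class(out) <- "abundance_table"
  out
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d clusters (%d rclust, %d unmap_OTU) x %d samples, depth %d\n",
              nrow(x$counts), sum(x$kind == "rclust"),
              sum(x$kind == "unmap_OTU"), ncol(x$counts), x$depth))
  invisible(x)
}

#' Relative abundances
#' @param tab an `abundance_table`.
#' @return matrix of counts / depth.
#' @export
relative_abundance <- function(tab) {
  stopifnot(inherits(tab, "abundance_table"))
  tab$counts / tab$depth
}

#' Subset an abundance table by samples and/or clusters
#' @param tab an `abundance_table`.
#' @param samples sample ids to keep (default all).
#' @param clusters cluster ids to keep (default all).
#' @export
subset_abundance <- function(tab, samples = NULL, clusters = NULL) {
  stopifnot(inherits(tab, "abundance_table"))
  if (is.null(samples)) samples <- colnames(tab$counts)
  if (is.null(clusters)) clusters <- rownames(tab$counts)
  keep_r <- rownames(tab$counts) %in% clusters
  out <- list(counts = tab$counts[keep_r, samples, drop = FALSE],
              depth = tab$depth,
              sheet = tab$sheet[tab$sheet$sample_id %in% samples, , drop = FALSE],
              kind = tab$kind[keep_r])
  class(out) <- "abundance_table"
  out
}

#' Filter clusters by mean relative abundance
#'
#' A cluster is retained iff its mean relative abundance reaches
#' `min_mean_rel` (default 0.1%) in at least one of the two groups.
#'
#' @param tab an `abundance_table` containing the cross-sectional samples.
#' @param min_mean_rel threshold on the group-mean relative abundance.
#' @param groups the two group labels compared (must each have samples).
#' @return filtered `abundance_table`; attribute `removal_counts` reports
#'   removed/retained per cluster kind.
#' @export
abundance_filter <- function(tab, min_mean_rel = 0.001,
                             groups = c("MS", "HC")) {
  stopifnot(inherits(tab, "abundance_table"))
  grp <- tab$sheet$group[match(colnames(tab$counts), tab$sheet$sample_id)]
  if (any(!groups %in% grp))
    stop("group with 0 samples: ", paste(setdiff(groups, grp), collapse = ", "))
  rel <- relative_abundance(tab)
  gmeans <- sapply(groups, function(g) rowMeans(rel[, grp == g, drop = FALSE]))
  gmeans <- matrix(gmeans, nrow = nrow(rel))
  keep <- apply(gmeans >= min_mean_rel, 1, any)
  out <- list(counts = tab$counts[keep, , drop = FALSE], depth = tab$depth,
              sheet = tab$sheet, kind = tab$kind[keep])
  class(out) <- "abundance_table"
  rc <- data.frame(kind = c("rclust", "unmap_OTU"),
                   total = c(sum(tab$kind == "rclust"),
                             sum(tab$kind == "unmap_OTU")),
                   retained = c(sum(out$kind == "rclust"),
                                sum(out$kind == "unmap_OTU")))
  rc$removed <- rc$total - rc$retained
  attr(out, "removal_counts") <- rc
  out
}
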
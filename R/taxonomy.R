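# Hierarchical taxonomic assignment from best-hit identity: species at
# >= 96%, genus at [94%, 96%), phylum at [70%, 94%), else unassigned.
# Names always come from the best hit's lineage; the level only says how
# deep that lineage is trusted.

#' Assign clusters to taxa by best-hit identity
#'
#' Each cluster's representative sequence is searched against the lineage-
#' labelled references; the best hit supplies the name at the level implied
#' by its identity.  Near-ties (identity within 0.3 percentage points of the
#' best, different species) are reported as `secondary_hit`.
#'
#' @param clusters cluster table with `cluster_id`, `kind` and a
#'   representative sequence column `representative_seq` (for de-novo OTUs)
#'   or `representative_id` resolving into `refdb` (for rclust).
#' @param refdb named reference sequences.
#' @param lineage data.frame `ref_id`, `species`, `genus`, `phylum`.
#' @param species_threshold,genus_threshold,phylum_threshold level bounds.
#' @param tie_margin identity margin (fraction) for secondary hits.
#' @return data.frame `cluster_id`, `level`, `name`, `genus`, `phylum`,
#'   `best_hit_identity`, `secondary_name`, `secondary_identity`.
#' @export
assign_clusters <- function(clusters, refdb, lineage,
                            species_threshold = 0.96, genus_threshold = 0.94,
                            phylum_threshold = 0.70, tie_margin = 0.003) {
  if (!all(c("ref_id", "species", "genus", "phylum") %in% names(lineage)))
    stop("lineage must label ref_id, species, genus, phylum")
  miss <- setdiff(names(refdb), lineage$ref_id)
  if (length(miss))
    stop("unlabeled references: ", paste(utils::head(miss, 3), collapse = ", "))
  refdb <- refdb[order(names(refdb))]
  lin <- lineage[match(names(refdb), lineage$ref_id), ]

  rep_seq <- ifelse(clusters$kind == "rclust",
                    unname(refdb[clusters$representative_id]),
                    clusters$representative_seq)
  if (anyNA(rep_seq)) stop("representative sequence missing for some cluster")

  out <- lapply(seq_len(nrow(clusters)), function(i) {
    ids <- best_two_hits(rep_seq[i], refdb, lin)
    best <- ids$best
    level <- if (is.na(best$identity)) "unassigned"
      else if (best$identity >= species_threshold) "species"
      else if (best$identity >= genus_threshold) "genus"
      else if (best$identity >= phylum_threshold) "phylum"
      else "unassigned"
    name <- switch(level, species = best$species, genus = best$genus,
                   phylum = best$phylum, unassigned = NA_character_)
    sec <- ids$secondary
    has_sec <- !is.null(sec) && !is.na(sec$identity) &&
      best$identity - sec$identity <= tie_margin
    data.frame(cluster_id = clusters$cluster_id[i], level = level,
               name = name,
               genus = if (level == "unassigned") NA_character_ else best$genus,
               phylum = if (level == "unassigned") NA_character_ else best$phylum,
               best_hit_species = best$species,
               best_hit_identity = best$identity,
               secondary_name = if (has_sec) sec$species else NA_character_,
               secondary_identity = if (has_sec) sec$identity else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# best and second-best species hits of one sequence against the database.
# Full-length queries (no expected offset against the references) use a
# generous band around the main diagonal; short queries run the full DP.
best_two_hits <- function(seq, refdb, lin) {
  full_length <- nchar(seq) >= 0.8 * stats::median(nchar(refdb))
  idents <- vapply(seq_along(refdb), function(j) {
    if (full_length)
      cpp_align(seq, unname(refdb)[j], band = 64L, diag = 0L)$global_identity
    else
      cpp_align(seq, unname(refdb)[j])$global_identity
  }, numeric(1))
  # best hit per species (the runner-up must be a different species)
  sp <- lin$species
  ord <- order(-idents, names(refdb))
  best_j <- ord[1]
  best <- data.frame(species = sp[best_j], genus = lin$genus[best_j],
                     phylum = lin$phylum[best_j], identity = idents[best_j],
                     stringsAsFactors = FALSE)
  sec_j <- ord[which(sp[ord] != sp[best_j])[1]]
  secondary <- if (length(sec_j) && !is.na(sec_j))
    data.frame(species = sp[sec_j], genus = lin$genus[sec_j],
               phylum = lin$phylum[sec_j], identity = idents[sec_j],
               stringsAsFactors = FALSE) else NULL
  list(best = best, secondary = secondary)
}

#' Aggregate an abundance table to a taxonomic level
#'
#' Counts are summed within each label at the requested level; clusters
#' whose assignment does not reach that level are pooled into
#' `"unclassified"`, so column totals are conserved.
#'
#' @param tab an `abundance_table`.
#' @param assignments output of [assign_clusters()] covering all clusters.
#' @param level `"genus"` or `"phylum"`.
#' @return `abundance_table` with one row per label.
#' @export
aggregate_levels <- function(tab, assignments, level = c("phylum", "genus")) {
  level <- match.arg(level)
  stopifnot(inherits(tab, "abundance_table"))
  idx <- match(rownames(tab$counts), assignments$cluster_id)
  if (anyNA(idx)) stop("assignments do not cover all clusters")
  lvl_rank <- c(unassigned = 0, phylum = 1, genus = 2, species = 3)
  need <- lvl_rank[[level]]
  lab <- ifelse(lvl_rank[assignments$level[idx]] >= need,
                assignments[[level]][idx], "unclassified")
  lab[is.na(lab)] <- "unclassified"
  agg <- rowsum(tab$counts, lab)
  out <- list(counts = agg, depth = tab$depth, sheet = tab$sheet,
              kind = rep(level, nrow(agg)))
  class(out) <- "abundance_table"
  out
}
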
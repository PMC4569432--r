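# Reference database construction: quality filtering of full-length 16S
# records and 99.8%-identity dereplication into non-redundant groups.

#' Build a reference record table from sequences
#'
#' @param seqs named character vector of reference sequences.
#' @param eukaryote_flag logical vector (recycled) flagging putatively
#'   eukaryotic records; detection is an input, not a classifier.
#' @param source optional character tag.
#' @return data.frame with `id`, `sequence`, `length`, `ambiguous_count`,
#'   `eukaryote_flag`, `source`.
#' @export
ref_records <- function(seqs, eukaryote_flag = FALSE, source = "user") {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    stop("reference sequences must be named")
  data.frame(id = names(seqs), sequence = unname(seqs),
             length = nchar(seqs),
             ambiguous_count = count_ambiguous(unname(seqs)),
             eukaryote_flag = rep_len(eukaryote_flag, length(seqs)),
             source = rep_len(source, length(seqs)),
             stringsAsFactors = FALSE)
}

#' Quality-filter full-length reference records
#'
#' Removal rules, applied sequentially so the per-rule counts are disjoint:
#' first records shorter than `min_len` (default 1,400 bp), then records
#' with `max_ambiguous + 1` or more ambiguous bases (default: >= 4 removed,
#' i.e. N <= 3 retained), then records flagged eukaryotic.
#'
#' @param records data.frame as from [ref_records()] (sequence strings may
#'   be NA as long as `length`, `ambiguous_count` and `eukaryote_flag` are
#'   populated).
#' @param min_len minimum retained length in bp.
#' @param max_ambiguous maximum retained ambiguous-base count.
#' @return list with `retained` (filtered records) and `removal_counts`
#'   (named integer vector: `short`, `ambiguous`, `eukaryote`).
#' @export
filter_references <- function(records, min_len = 1400L, max_ambiguous = 3L) {
  required <- c("id", "length", "ambiguous_count", "eukaryote_flag")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(is.na(records$length) | is.na(records$ambiguous_count))
  if (length(bad))
    stop("malformed record: ", records$id[bad[1]])

  short <- records$length < min_len
  ambig <- !short & records$ambiguous_count > max_ambiguous
  euk <- !short & !ambig & records$eukaryote_flag
  retained <- records[!(short | ambig | euk), , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       removal_counts = c(short = sum(short), ambiguous = sum(ambig),
                          eukaryote = sum(euk)))
}

#' Dereplicate near-identical references
#'
#' Greedy centroid clustering at the given identity threshold (default
#' 99.8%): records are processed in descending length (ties broken by id)
#' and each joins the first existing centroid it matches at or above the
#' threshold, else founds a new one.  Identity comes from the package's
#' semi-global alignment kernel with IUPAC codes matching on non-empty
#' intersection.
#'
#' @param records filtered record data.frame (with sequences).
#' @param threshold identity fraction in (0, 1].
#' @param band alignment band half-width for the full-length comparisons
#'   (full-length 16S records are nearly indel-free, so a generous band is
#'   exact in practice; pass `-1` for the unbanded dynamic program).
#' @return data.frame with `representative_id`, `member_id`; attribute
#'   `representatives` holds the named representative sequences.
#' @export
dereplicate <- function(records, threshold = 0.998, band = 64L) {
  if (threshold <= 0 || threshold > 1) stop("threshold outside (0,1]")
  if (nrow(records) == 0) {
    out <- data.frame(representative_id = character(0),
                      member_id = character(0), stringsAsFactors = FALSE)
    attr(out, "representatives") <- character(0)
    return(out)
  }
  if (anyNA(records$sequence)) stop("dereplicate needs sequence strings")
  ord <- order(-records$length, records$id)
  rec <- records[ord, ]
  assign <- cpp_greedy_cluster(rec$sequence, threshold, band = band)
  rep_idx <- vapply(seq_len(max(assign)), function(c) which(assign == c)[1],
                    integer(1))
  out <- data.frame(representative_id = rec$id[rep_idx][assign],
                    member_id = rec$id, stringsAsFactors = FALSE)
  attr(out, "representatives") <-
    stats::setNames(rec$sequence[rep_idx], rec$id[rep_idx])
  out
}

#' Build a non-redundant reference database
#'
#' Convenience wrapper: filter, dereplicate, and return the database the
#' mapping stage consumes.
#'
#' @inheritParams filter_references
#' @inheritParams dereplicate
#' @return list with `db` (named representative sequences sorted by id),
#'   `cluster_map`, `removal_counts`, `retained_records`.
#' @export
build_refdb <- function(records, min_len = 1400L, max_ambiguous = 3L,
                        threshold = 0.998, band = 64L) {
  flt <- filter_references(records, min_len, max_ambiguous)
  derep <- dereplicate(flt$retained, threshold, band)
  reps <- attr(derep, "representatives")
  reps <- reps[order(names(reps))]
  list(db = reps, cluster_map = derep, removal_counts = flt$removal_counts,
       retained_records = flt$retained)
}
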
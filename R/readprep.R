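# Per-sample read preparation: mean-quality filtering, fixed-depth random
# subsampling, and IUPAC-aware primer trimming.

#' Filter reads by mean base quality
#'
#' A read is retained iff the arithmetic mean of its Phred scores is
#' strictly greater than `min_mean_q` (default 25).
#'
#' @param reads data.frame with `id`, `sequence`, `quality` (Phred+33).
#' @param min_mean_q threshold on the mean quality value.
#' @return the retained rows.
#' @export
quality_filter <- function(reads, min_mean_q = 25) {
  if (nrow(reads) == 0) return(reads)
  if (any(!nzchar(reads$quality)))
    stop("malformed record (empty qualities): ",
         reads$id[which(!nzchar(reads$quality))[1]])
  if (any(nchar(reads$quality) != nchar(reads$sequence)))
    stop("malformed record (quality/sequence length mismatch): ",
         reads$id[which(nchar(reads$quality) != nchar(reads$sequence))[1]])
  mq <- cpp_mean_quality(reads$quality)
  out <- reads[mq > min_mean_q, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample reads to a fixed depth
#'
#' Uniform sampling without replacement to exactly `depth` reads,
#' deterministic given the seed and sample id (the per-sample substream is
#' derived by hashing the id).
#'
#' @param reads data.frame of reads.
#' @param depth target depth (default 3000).
#' @param seed integer seed.
#' @param sample_id sample identifier used to derive the substream.
#' @return data.frame of exactly `depth` reads, in original relative order.
#' @export
subsample_reads <- function(reads, depth = 3000L, seed = 1L,
                            sample_id = "sample") {
  n <- nrow(reads)
  if (n < depth)
    stop(sprintf("sample %s has %d filter-passed reads, fewer than depth %d",
                 sample_id, n, depth))
  if (n == depth) return(reads)
  set.seed(derive_seed(seed, paste0("subsample:", sample_id)))
  keep <- sort(sample.int(n, depth))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Trim amplification primers
#'
#' The forward primer must match the 5' end within `max_mismatch_fwd`
#' IUPAC-aware mismatches, else the read is rejected.  The
#' reverse-complemented reverse primer is searched in a 3' window and
#' trimmed when present (454-style reads need not reach it).  Qualities are
#' trimmed alongside bases.
#'
#' @param reads data.frame of reads.
#' @param fwd,rev primer sequences (IUPAC; defaults: the V1-V2 pair).
#' @param max_mismatch_fwd,max_mismatch_rev mismatch tolerances.
#' @return list with `reads` (trimmed, accepted) and `rejected`
#'   (data.frame `id`, `reason`).
#' @export
trim_primers <- function(reads, fwd = v1v2_primers[["fwd"]],
                         rev = v1v2_primers[["rev"]],
                         max_mismatch_fwd = 2L, max_mismatch_rev = 2L) {
  if (!grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$", fwd) ||
      !grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$", rev))
    stop("primers must be IUPAC DNA")
  if (nrow(reads) == 0)
    return(list(reads = reads,
                rejected = data.frame(id = character(0), reason = character(0))))
  tr <- cpp_trim_primers(reads$sequence, reads$quality, toupper(fwd),
                         revcomp(toupper(rev)), max_mismatch_fwd,
                         max_mismatch_rev)
  ok <- tr$status == 0L
  out <- reads
  out$sequence <- tr$sequence
  out$quality <- tr$quality
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  reasons <- c("ok", "no forward primer match", "empty after trimming")
  rejected <- data.frame(id = reads$id[!ok],
                         reason = reasons[tr$status[!ok] + 1L],
                         stringsAsFactors = FALSE)
  list(reads = out, rejected = rejected)
}

#' Prepare one sample: filter, trim, subsample
#'
#' Primer-trimming rejects count as filter failures, so the subsample is
#' drawn from reads that are both high-quality and trimmable and every
#' prepared sample holds exactly `depth` reads (the rarefaction contract
#' the per-sample OTU clustering relies on).
#'
#' @param reads raw reads of one sample.
#' @param sample_id sample identifier.
#' @param depth subsampling depth.
#' @param min_mean_q mean-quality threshold.
#' @param seed integer seed.
#' @return list with `reads` (prepared) and `counts` (named vector: `raw`,
#'   `filter_passed`, `trimmed`, `subsampled`).
#' @export
prep_sample <- function(reads, sample_id, depth = 3000L, min_mean_q = 25,
                        seed = 1L) {
  flt <- quality_filter(reads, min_mean_q)
  trm <- trim_primers(flt)
  sub <- subsample_reads(trm$reads, depth, seed, sample_id)
  list(reads = sub,
       counts = c(raw = nrow(reads), filter_passed = nrow(flt),
                  trimmed = nrow(trm$reads), subsampled = nrow(sub)))
}
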
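# R surface over the alignment kernel.

#' Semi-global pairwise alignment
#'
#' Overlap alignment with free end gaps on both sequences, affine gap costs
#' (a gap of length L costs `gap_open + gap_ext * L`), match +1 and mismatch
#' -2 by default.  Identity is matched columns over alignment columns within
#' the aligned span; coverage is the aligned fraction of the first (query)
#' sequence.  IUPAC ambiguity codes match when their base sets intersect.
#'
#' @param a query sequence.
#' @param b reference sequence.
#' @param match,mismatch,gap_open,gap_ext scoring parameters.
#' @param band half-width of an optional alignment band around diagonal
#'   `diag`; `band < 0` (default) runs the full dynamic program.
#' @param diag band centre as offset of `b` relative to `a`.
#' @return list with `score`, `identity` (matches over path columns),
#'   `global_identity` (matches over path columns plus unaligned query
#'   bases; penalises degenerate short overlaps and is the definition used
#'   for clustering), `coverage`, `matches`, `columns`, span coordinates
#'   and the aligned strings `a_aln`, `b_aln`.
#' @export
align_overlap <- function(a, b, match = 1L, mismatch = -2L, gap_open = 5L,
                          gap_ext = 2L, band = -1L, diag = 0L) {
  if (nchar(a) == 0 || nchar(b) == 0) stop("empty sequence")
  cpp_align(a, b, match, mismatch, gap_open, gap_ext, band, diag)
}

#' All-pairs identity matrix
#'
#' Uses the clustering identity (`global_identity` of [align_overlap()]):
#' matches over alignment columns plus any unaligned query overhang.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @param band optional band half-width (full alignment by default).
#' @return symmetric matrix of identity fractions with unit diagonal.
#' @export
pairwise_identity <- function(seqs, band = -1L) {
  if (length(seqs) < 2) stop("need at least two sequences")
  if (any(nchar(seqs) == 0)) stop("empty sequence")
  m <- cpp_identity_matrix(seqs, band)
  dimnames(m) <- list(names(seqs), names(seqs))
  m
}

#' Greedy centroid clustering
#'
#' Processes sequences in descending length (ties by id); each sequence
#' joins the first centroid whose identity is at or above the threshold,
#' else founds a new centroid.  Centroid ids are renumbered in founding
#' order.
#'
#' @param seqs named character vector.
#' @param threshold identity fraction in (0, 1].
#' @param band optional alignment band half-width (sequence-length scale);
#'   the default full alignment is exact.
#' @return data.frame `id`, `cluster` (integer), `is_centroid`; attribute
#'   `centroids` maps cluster -> centroid id.
#' @export
greedy_cluster <- function(seqs, threshold, band = -1L) {
  if (threshold <= 0 || threshold > 1) stop("threshold outside (0,1]")
  if (length(seqs) == 0)
    return(data.frame(id = character(0), cluster = integer(0),
                      is_centroid = logical(0)))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%05d", seq_along(seqs))
  ord <- order(-nchar(seqs), names(seqs))
  s <- seqs[ord]
  assign <- cpp_greedy_cluster(unname(s), threshold, band = band)
  cent <- vapply(seq_len(max(assign)), function(c) names(s)[assign == c][1],
                 character(1))
  out <- data.frame(id = names(s), cluster = assign,
                    is_centroid = names(s) == cent[assign],
                    stringsAsFactors = FALSE)
  attr(out, "centroids") <- cent
  out
}
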
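# Phylogeny over species-level units: p-distances from the pairwise
# alignment kernel, neighbor-joining trees, a center-star multiple
# alignment, and bootstrap support by column resampling.

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a symmetric distance matrix.  Negative
#' branch lengths (an NJ artefact) are clamped to zero; the total clamped
#' length is recorded in the `clamped` attribute.  Two taxa yield a single
#' edge of the given length.
#'
#' @param d symmetric distance matrix with labels (>= 2 taxa).
#' @return `phylo` object (unrooted for >= 3 taxa).
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  n <- nrow(d)
  if (n < 2) stop("need >= 2 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                 edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
                 tip.label = rownames(d), Nnode = 1L)
    class(tree) <- "phylo"
    attr(tree, "clamped") <- 0
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  neg <- tree$edge.length < 0
  clamped <- -sum(tree$edge.length[neg])
  tree$edge.length[neg] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Midpoint-rooted NJ tree from sequences
#'
#' Distance = p-distance on aligned columns (no substitution-model
#' correction), then neighbor joining and midpoint rooting.  By default
#' the sequences are multiple-aligned (center-star) and distances use
#' pairwise deletion, which stays well behaved for deeply diverged pairs;
#' `method = "pairwise"` instead takes 1 - pairwise clustering identity
#' from the raw kernel (adequate when all pairs are closely related).
#'
#' @param seqs named character vector (>= 2).
#' @param method `"alignment"` (default) or `"pairwise"`.
#' @return rooted `phylo`.
#' @export
nj_tree_from_seqs <- function(seqs, method = c("alignment", "pairwise")) {
  method <- match.arg(method)
  d <- if (method == "alignment") {
    pdist_from_alignment(msa_center_star(seqs))
  } else {
    1 - pairwise_identity(seqs)
  }
  phangorn::midpoint(nj_tree(d))
}

#' Center-star multiple alignment
#'
#' Aligns every sequence to the longest one (ties by name) with the
#' pairwise kernel and merges the pairwise gap patterns ("once a gap,
#' always a gap").  Adequate for the narrowly diverged, indel-free
#' amplicon sets this package profiles; not a general-purpose aligner.
#'
#' @param seqs named character vector.
#' @return character matrix (taxa x columns) of single characters, gaps as
#'   `"-"`.
#' @export
msa_center_star <- function(seqs) {
  if (length(seqs) < 2) stop("need >= 2 sequences")
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  center_i <- order(-nchar(seqs), names(seqs))[1]
  center <- seqs[[center_i]]
  Lc <- nchar(center)
  others <- setdiff(seq_along(seqs), center_i)

  alns <- lapply(others, function(i) align_to_center(seqs[[i]], center))
  # insertion slot s (1..Lc+1): columns before center position s
  # (s = Lc + 1: after the last position)
  master_ins <- rep(0L, Lc + 1)
  for (a in alns)
    master_ins <- pmax(master_ins, vapply(a$ins, length, integer(1)))

  ncols <- Lc + sum(master_ins)
  col_of <- cumsum(master_ins[seq_len(Lc)]) + seq_len(Lc)  # center pos j column
  rows <- matrix("-", length(seqs), ncols)
  rownames(rows) <- names(seqs)
  rows[center_i, col_of] <- strsplit(center, "")[[1]]
  slot_cols <- function(s) {
    prev_end <- if (s == 1) 0L else col_of[s - 1]
    prev_end + seq_len(master_ins[s])
  }
  for (k in seq_along(others)) {
    a <- alns[[k]]
    row <- rep("-", ncols)
    row[col_of][!is.na(a$at)] <- a$at[!is.na(a$at)]
    for (s in which(vapply(a$ins, length, integer(1)) > 0)) {
      cs <- a$ins[[s]]
      cols <- slot_cols(s)
      row[utils::tail(cols, length(cs))] <- cs
    }
    rows[others[k], ] <- row
  }
  rows
}

# align one sequence to the center: `at[j]` is the character placed at
# center position j (NA for a gap), `ins[[s]]` the characters inserted
# before center position s (s = Lc + 1: after the end).  Global alignment
# (end gaps charged) is the right primitive here: the free-end-gap overlap
# optimum collapses to a degenerate span once sequences diverge past the
# point where the expected per-column score goes negative.
align_to_center <- function(seq, center) {
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(seq, center, type = "global",
                                      substitutionMatrix = sm,
                                      gapOpening = 5, gapExtension = 2)
  a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  Lc <- nchar(center)
  at <- rep(NA_character_, Lc)
  ins <- rep(list(character(0)), Lc + 1)
  j <- 0  # last center position consumed
  for (k in seq_along(a)) {
    if (b[k] == "-") {
      ins[[min(j + 1, Lc + 1)]] <- c(ins[[min(j + 1, Lc + 1)]], a[k])
    } else {
      j <- j + 1
      if (a[k] != "-") at[j] <- a[k]
    }
  }
  list(at = at, ins = ins)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Canonical keys (the side not containing the first tip, sorted and
#' pasted) for every internal edge.
#'
#' @param tree `phylo`.
#' @return character vector of bipartition keys.
#' @export
bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- min(labs)   # leaf-order independent canonicalisation
  keys <- vapply(pp, function(ix) {
    side <- labs[ix]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > ntip - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, recomputes the p-distance
#' and NJ tree per replicate, and counts, for each internal edge of the
#' reference tree, the replicates containing the same bipartition.
#' Distances use pairwise deletion: columns with a gap in either sequence
#' of a pair are skipped; IUPAC codes match on intersection.
#'
#' @param alignment character matrix (taxa x columns) or named equal-length
#'   character vector.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return the reference NJ tree (from the full alignment) with
#'   `node.label` holding support counts for internal nodes and an attribute
#'   `support` (data.frame `bipartition`, `count`).
#' @export
bootstrap_support <- function(alignment, n_reps = 1000L, seed = 1L) {
  aln <- as_alignment_matrix(alignment)
  # canonical taxon order makes supports independent of input leaf order
  # (neighbor joining breaks ties by position)
  if (!is.null(rownames(aln))) aln <- aln[order(rownames(aln)), , drop = FALSE]
  L <- ncol(aln)
  if (L < 2) stop("alignment must have >= 2 columns")
  ref_d <- pdist_from_alignment(aln)
  ref_tree <- nj_tree(ref_d)
  ref_bip <- bipartitions(ref_tree)
  counts <- stats::setNames(integer(length(ref_bip)), ref_bip)

  set.seed(derive_seed(seed, "bootstrap"))
  pre <- precompute_pair_mismatch(aln)
  for (b in seq_len(n_reps)) {
    idx <- sample.int(L, L, replace = TRUE)
    d <- pdist_from_precomputed(pre, idx, nrow(aln))
    if (anyNA(d)) next  # a pair with no usable columns in this replicate
    rownames(d) <- colnames(d) <- rownames(aln)
    bt <- nj_tree(d)
    bip <- bipartitions(bt)
    hit <- ref_bip %in% bip
    counts[hit] <- counts[hit] + 1L
  }

  support <- data.frame(bipartition = ref_bip, count = as.integer(counts),
                        stringsAsFactors = FALSE)
  ref_tree$node.label <- node_support_labels(ref_tree, support)
  attr(ref_tree, "support") <- support
  attr(ref_tree, "n_reps") <- n_reps
  ref_tree
}

as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (length(unique(nchar(alignment))) != 1)
    stop("sequences differ in length; align them first")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

# p-distance with pairwise deletion over an alignment matrix
pdist_from_alignment <- function(aln) {
  pre <- precompute_pair_mismatch(aln)
  d <- pdist_from_precomputed(pre, seq_len(ncol(aln)), nrow(aln))
  rownames(d) <- colnames(d) <- rownames(aln)
  d
}

# per-pair per-column mismatch (1), match (0) or unusable (NA)
precompute_pair_mismatch <- function(aln) {
  n <- nrow(aln)
  pairs <- utils::combn(n, 2)
  mm <- matrix(NA_real_, ncol(aln), ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- aln[pairs[1, k], ]; b <- aln[pairs[2, k], ]
    usable <- a != "-" & b != "-"
    mm[usable, k] <- as.numeric(!iupac_compatible(a[usable], b[usable]))
  }
  list(mm = mm, pairs = pairs)
}

pdist_from_precomputed <- function(pre, idx, n) {
  sub <- pre$mm[idx, , drop = FALSE]
  pd <- colMeans(sub, na.rm = TRUE)
  used <- colSums(!is.na(sub))
  pd[used == 0] <- NA_real_
  d <- matrix(0, n, n)
  d[t(pre$pairs)] <- pd
  d[t(pre$pairs[2:1, , drop = FALSE])] <- pd
  d
}

iupac_masks <- local({
  m <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, R = 5L, Y = 10L, S = 6L,
         W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L, N = 15L)
  m
})

iupac_compatible <- function(a, b) {
  ma <- iupac_masks[a]; mb <- iupac_masks[b]
  ma[is.na(ma)] <- 0L; mb[is.na(mb)] <- 0L
  bitwAnd(ma, mb) > 0L
}

# map bipartition supports onto internal node labels of the tree
node_support_labels <- function(tree, support) {
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  anchor <- min(labs)
  keys <- vapply(pp, function(ix) {
    side <- labs[ix]
    if (anchor %in% side) side <- setdiff(labs, side)
    if (length(side) < 2 || length(side) > ntip - 2) return(NA_character_)
    paste(sort(side), collapse = "|")
  }, character(1))
  out <- rep("", tree$Nnode)
  m <- match(keys, support$bipartition)
  out[!is.na(m)] <- as.character(support$count[m[!is.na(m)]])
  out
}
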
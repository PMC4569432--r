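# Beta diversity: UniFrac distances over the cluster phylogeny, principal
# coordinates, ANOSIM, and within/between-group distance summaries.

#' UniFrac distances between samples
#'
#' Unweighted UniFrac between two samples is the branch length unique to
#' either sample's taxa divided by the total branch length spanned by their
#' union.  Weighted UniFrac is `sum_b l_b |A_b - B_b|` over branches, with
#' `A_b`, `B_b` the fraction of each sample's reads descending from branch
#' `b`; the normalized variant divides by the maximum attainable value
#' `sum_j (p_Aj + p_Bj) d_j` over leaves `j` at depth `d_j` from the root.
#'
#' @param tab an `abundance_table` whose clusters are the tree's leaves.
#' @param tree rooted `phylo` with non-negative branch lengths.
#' @param weighted abundance-weighted variant.
#' @param normalized divide weighted distances by their pairwise maximum
#'   (ignored for unweighted, which is normalized by construction).
#' @return symmetric distance matrix (zero diagonal) over samples.
#' @export
unifrac <- function(tab, tree, weighted = FALSE, normalized = TRUE) {
  stopifnot(inherits(tab, "abundance_table"), inherits(tree, "phylo"))
  absent <- setdiff(rownames(tab$counts), tree$tip.label)
  if (length(absent))
    stop("clusters absent from tree: ", paste(utils::head(absent, 3), collapse = ", "))
  if (any(tree$edge.length < 0)) stop("negative branch lengths")

  ntip <- length(tree$tip.label)
  # per-edge leaf descendants (postorder accumulation)
  nodes <- ntip + tree$Nnode
  below <- matrix(FALSE, nodes, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in ape::postorder(tree)) {  # children before parents
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    below[p, ] <- below[p, ] | below[ch, ]
  }
  edge_leaves <- below[tree$edge[, 2], , drop = FALSE]

  p <- relative_abundance(tab)
  p <- p[tree$tip.label[tree$tip.label %in% rownames(p)], , drop = FALSE]
  full <- matrix(0, ntip, ncol(p), dimnames = list(tree$tip.label, colnames(p)))
  full[rownames(p), ] <- p
  csum <- colSums(full)
  if (any(csum == 0)) stop("sample with zero total abundance")
  full <- sweep(full, 2, csum, "/")

  # per-edge descending fraction per sample
  edge_frac <- edge_leaves %*% full            # edges x samples
  el <- tree$edge.length
  ns <- ncol(full)
  d <- matrix(0, ns, ns, dimnames = list(colnames(full), colnames(full)))
  if (weighted && normalized) {
    depths <- ape::node.depth.edgelength(tree)[seq_len(ntip)]
  }
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    a <- edge_frac[, i]; b <- edge_frac[, j]
    if (weighted) {
      num <- sum(el * abs(a - b))
      if (normalized) {
        den <- sum((full[, i] + full[, j]) * depths)
        d[i, j] <- if (den > 0) num / den else 0
      } else d[i, j] <- num
    } else {
      pa <- a > 0; pb <- b > 0
      union_len <- sum(el[pa | pb])
      uniq_len <- sum(el[xor(pa, pb)])
      d[i, j] <- if (union_len > 0) uniq_len / union_len else 0
    }
    d[j, i] <- d[i, j]
  }
  d
}

#' Principal coordinates analysis
#'
#' Classical scaling: double-centre `-d^2 / 2`, eigendecompose, keep axes
#' with positive eigenvalues; explained fractions are eigenvalues over the
#' positive-eigenvalue total.  Negative eigenvalues are dropped and
#' reported in the `eig` attribute.
#'
#' @param d symmetric distance matrix.
#' @return list with `coordinates` (samples x axes), `explained`
#'   (fractions), `eig` (all eigenvalues), `degenerate` flag.
#' @export
pcoa_ord <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix not symmetric")
  n <- nrow(d)
  # cmdscale warns when fewer than k eigenvalues are positive; the positive
  # set is handled explicitly below, so the warning is redundant here
  cs <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = n - 1,
                                         eig = TRUE))
  eig <- cs$eig
  pos <- eig > max(eig, 0) * 1e-12
  if (!any(pos))
    return(list(coordinates = matrix(0, n, 1, dimnames = list(rownames(d), "PC1")),
                explained = 0, eig = eig, degenerate = TRUE))
  coords <- cs$points[, seq_len(sum(pos)), drop = FALSE]
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  list(coordinates = coords, explained = eig[pos] / sum(eig[pos]), eig = eig,
       degenerate = FALSE)
}

#' ANOSIM
#'
#' `R = (mean between-group rank - mean within-group rank) / (M / 2)` over
#' the ranked pairwise distances (`M = n (n - 1) / 2`); significance by
#' label permutation, `p = (1 + #{R_perm >= R_obs}) / (1 + n_perm)`, or by
#' exhaustive enumeration of the distinct two-group assignments when
#' `exact = TRUE`.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each >= 2 samples).
#' @param n_perm permutation count (default 10000).
#' @param seed integer seed for the permutations.
#' @param exact enumerate all assignments (two groups only).
#' @return list with `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(d, groups, n_perm = 10000L, seed = 1L, exact = FALSE) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  if (length(unique(groups)) < 2 || any(table(groups) < 2))
    stop("need >= 2 groups with >= 2 samples each")
  if (!exact && n_perm < 1) stop("n_perm must be >= 1")
  n <- nrow(d)
  pair_idx <- which(upper.tri(d))
  r <- rank(d[pair_idx])
  M <- length(r)
  same <- function(g) {
    outer(g, g, "==")[pair_idx]
  }
  stat <- function(g) {
    w <- same(g)
    (mean(r[!w]) - mean(r[w])) / (M / 2)
  }
  R_obs <- stat(groups)
  if (exact) {
    if (length(unique(groups)) != 2) stop("exact enumeration needs 2 groups")
    g1 <- unique(groups)[1]
    n1 <- sum(groups == g1)
    sets <- utils::combn(n, n1)
    Rs <- apply(sets, 2, function(ix) {
      g <- rep("b", n); g[ix] <- "a"; stat(g)
    })
    p <- mean(Rs >= R_obs - 1e-12)
    return(list(R = R_obs, p = p, n_perm = ncol(sets)))
  }
  set.seed(derive_seed(seed, "anosim"))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (stat(sample(groups)) >= R_obs - 1e-12) exceed <- exceed + 1L
  }
  list(R = R_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm)
}

#' Within/between-group distance summary
#'
#' Means and standard deviations of the pairwise distances within and
#' between two groups, with label-permutation tests on the differences of
#' pair-set means (pairs sharing a sample are dependent, so a permutation
#' test is used rather than a t-test on pairs).
#'
#' @param d symmetric distance matrix.
#' @param groups label per sample (two groups).
#' @param n_perm permutations for the pairwise tests.
#' @param seed integer seed.
#' @return list with `summary` (data.frame `pair_set`, `n_pairs`, `mean`,
#'   `sd`) and `tests` (data.frame of pair-set contrasts with permutation
#'   p-values).
#' @export
group_distance_summary <- function(d, groups, n_perm = 2000L, seed = 1L) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  gs <- sort(unique(groups))
  if (length(gs) != 2) stop("exactly two groups expected")
  lab <- function(g) {
    o <- outer(g, g, function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-"))
    o[upper.tri(o)]
  }
  dv <- d[upper.tri(d)]
  set_lab <- lab(groups)
  sets <- sort(unique(set_lab))
  summary <- data.frame(
    pair_set = sets,
    n_pairs = as.integer(table(set_lab)[sets]),
    mean = vapply(sets, function(s) mean(dv[set_lab == s]), numeric(1)),
    sd = vapply(sets, function(s) stats::sd(dv[set_lab == s]), numeric(1)),
    stringsAsFactors = FALSE)
  contrasts <- utils::combn(sets, 2)
  set.seed(derive_seed(seed, "group-distances"))
  tests <- apply(contrasts, 2, function(cp) {
    obs <- mean(dv[set_lab == cp[2]]) - mean(dv[set_lab == cp[1]])
    null <- replicate(n_perm, {
      g <- sample(groups)
      sl <- lab(g)
      mean(dv[sl == cp[2]]) - mean(dv[sl == cp[1]])
    })
    data.frame(contrast = paste(cp[2], "vs", cp[1]), difference = obs,
               p = (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (1 + n_perm),
               stringsAsFactors = FALSE)
  })
  list(summary = summary, tests = do.call(rbind, tests))
}
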
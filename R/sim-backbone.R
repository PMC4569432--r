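# Synthetic species backbone: a birth-death phylogeny along which full-length
# 16S-like genes are evolved by substitution.  The gene is assembled from a
# conserved head, the forward-primer site, a fast-evolving V1-V2 core, the
# reverse-primer site and a slowly evolving conserved tail, so that the
# amplicon between the primer sites carries most of the species signal while
# full-length identities stay in a realistic 90-95% band.

FWD_SITE <- "AGAGTTTGATCCTGGCTCAG"   # concrete 27F-region sequence (matches 27Fmod)
REV_SITE <- "ACTCCTACGGGAGGCAGCA"    # plus-strand 338R site (= revcomp of 338R)

#' Simulate the species backbone and ground truth
#'
#' Evolves candidate species along a random birth-death tree (substitution
#' only), prunes species pairs whose V1-V2 cores exceed 93.5% identity so
#' that every retained species is recoverable as its own unit at the 96%/97%
#' thresholds, designates the novel (database-absent) species as those with
#' the closest database relatives, and assigns a phylum/genus lineage by
#' cutting the generating tree.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_truth`: list with `species` (data.frame:
#'   `id`, `in_db`, `novel`, `phylum`, `genus`), `fl_seqs`, `amplicons`,
#'   `cores` (named character vectors), `tree` (ape phylo over species ids),
#'   `composition` (data.frame of per-group expected proportions),
#'   `effects` (planted effects with species ids), and `config`.
#' @export
simulate_species_backbone <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "backbone"))
  n_need <- config$n_ref_species + config$n_novel_species
  n_gen <- ceiling(n_need * 1.4)

  tree <- ape::rphylo(n_gen, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree)[seq_len(n_gen)])
  tree$edge.length <- tree$edge.length / depth
  # a minimum terminal branch keeps sister species apart: every pair ends
  # below ~90% core identity, so species stay separable at 96%/97%
  terminal <- tree$edge[, 2] <= n_gen
  tree$edge.length[terminal] <- tree$edge.length[terminal] + 0.45

  core <- toupper(as.character(phangorn::simSeq(
    tree, l = config$core_len, type = "DNA", rate = 0.12)))
  tail_ <- toupper(as.character(phangorn::simSeq(
    tree, l = config$tail_len, type = "DNA", rate = 0.026)))
  core <- core[tree$tip.label, , drop = FALSE]
  tail_ <- tail_[tree$tip.label, , drop = FALSE]

  idm <- hamming_identity(core)
  keep <- prune_close_pairs(idm, max_identity = 0.935)
  if (length(keep) < n_need)
    stop("backbone pruning left too few species; increase the candidate pool")

  idm <- idm[keep, keep]
  # novel species: closest surviving relatives, nearest neighbour kept in DB
  nn <- apply(idm - diag(nrow(idm)), 1, max)
  ord <- order(nn, decreasing = TRUE)
  novel_idx <- integer(0)
  for (i in ord) {
    if (length(novel_idx) >= config$n_novel_species) break
    j <- which.max(idm[i, ] - (seq_len(nrow(idm)) == i))
    if (!(j %in% novel_idx) && !(i %in% novel_idx)) novel_idx <- c(novel_idx, i)
  }
  db_idx <- setdiff(seq_along(keep), novel_idx)[seq_len(config$n_ref_species)]
  sel <- sort(c(db_idx, novel_idx))
  keep <- keep[sel]
  is_novel <- seq_along(keep) %in% match(novel_idx, sel)

  ids <- sprintf("Species_%03d", seq_along(keep))
  head_seq <- random_dna(1, config$head_len)
  cores <- apply(core[keep, , drop = FALSE], 1, paste, collapse = "")
  tails <- apply(tail_[keep, , drop = FALSE], 1, paste, collapse = "")
  amplicons <- stats::setNames(paste0(FWD_SITE, cores, REV_SITE), ids)
  fl <- stats::setNames(paste0(head_seq, FWD_SITE, cores, REV_SITE, tails), ids)
  cores <- stats::setNames(cores, ids)

  gtree <- ape::keep.tip(tree, tree$tip.label[keep])
  gtree$tip.label <- ids[match(gtree$tip.label, tree$tip.label[keep])]

  lineage <- cut_lineage(gtree, ids)
  species <- data.frame(id = ids, in_db = !is_novel, novel = is_novel,
                        phylum = lineage$phylum[ids], genus = lineage$genus[ids],
                        stringsAsFactors = FALSE)

  truth <- list(species = species, fl_seqs = fl, amplicons = amplicons,
                cores = cores, tree = gtree, head_seq = head_seq,
                config = config)
  truth$composition <- build_composition(config, truth)
  truth$effects <- attr(truth$composition, "effects")
  class(truth) <- "sim_truth"
  truth
}

# identity via shared columns of an already-aligned character matrix
hamming_identity <- function(mat) {
  m <- matrix(match(tolower(mat), c("a", "c", "g", "t")), nrow = nrow(mat))
  L <- ncol(m)
  acc <- matrix(0, nrow(m), nrow(m))
  for (b in 1:4) {
    ind <- (m == b) * 1
    acc <- acc + tcrossprod(ind)
  }
  idm <- acc / L
  rownames(idm) <- colnames(idm) <- rownames(mat)
  diag(idm) <- 1
  idm
}

# drop the later member of any pair above max_identity; returns kept indices
prune_close_pairs <- function(idm, max_identity) {
  n <- nrow(idm)
  keep <- rep(TRUE, n)
  for (i in seq_len(n - 1)) {
    if (!keep[i]) next
    too_close <- which(keep & idm[i, ] > max_identity)
    too_close <- too_close[too_close > i]
    keep[too_close] <- FALSE
  }
  which(keep)
}

# phylum/genus labels by cutting the generating tree's cophenetic distances
cut_lineage <- function(tree, ids) {
  d <- stats::as.dist(ape::cophenetic.phylo(tree))
  hc <- stats::hclust(d, method = "average")
  phy_k <- min(4L, length(ids))
  phy_raw <- stats::cutree(hc, k = phy_k)
  phy_names <- c("Firmicutes", "Bacteroidetes", "Actinobacteria",
                 "Proteobacteria")
  sizes <- sort(table(phy_raw), decreasing = TRUE)
  phy_map <- stats::setNames(phy_names[seq_along(sizes)], names(sizes))
  phylum <- stats::setNames(phy_map[as.character(phy_raw)], names(phy_raw))
  gen_k <- max(2L, min(length(ids) - 1L, round(length(ids) / 5)))
  gen_raw <- stats::cutree(hc, k = gen_k)
  genus <- stats::setNames(sprintf("Genus_%02d", gen_raw), names(gen_raw))
  list(phylum = phylum[ids], genus = genus[ids])
}

# expected per-group proportions with planted effects applied to the case
# group before multinomial sampling; non-planted species absorb the
# difference by proportional renormalisation
build_composition <- function(config, truth) {
  set.seed(derive_seed(config$seed, "composition"))
  sp <- truth$species
  n_comm <- config$n_community_species
  n_novel <- sum(sp$novel)
  db_ids <- sp$id[sp$in_db]
  novel_ids <- sp$id[sp$novel]
  comm_db <- sample(db_ids, n_comm - n_novel)
  comm <- c(comm_db, novel_ids)

  p <- exp(-0.045 * seq_len(n_comm))
  p <- p / sum(p)
  pe <- config$planted_effects
  n_eff <- if (is.null(pe)) 0L else nrow(pe)
  planted_db_n <- if (n_eff) sum(!pe$novel) else 0L
  need <- planted_db_n + n_novel
  # hosts for planted + novel species sit at moderate baselines: preferably
  # [0.4%, 3%], extended towards the rarest ranks still >= 0.4% when the
  # community is small enough that every species exceeds 3%
  window <- which(p >= 0.004 & p <= 0.03)
  if (length(window) < need)
    window <- utils::tail(which(p >= 0.004), max(need, length(window)))
  if (need > length(window))
    stop("abundance window too small for planted + novel species")

  ord <- sample(n_comm)                      # random rank assignment
  ranks <- stats::setNames(ord, comm)
  # force planted/novel species into the window by swapping ranks
  hosts <- c(if (planted_db_n) sample(comm_db, planted_db_n) else character(0),
             novel_ids)
  slots <- sample(window, length(hosts))
  for (k in seq_along(hosts)) {
    h <- hosts[k]; s <- slots[k]
    cur <- names(ranks)[match(s, ranks)]
    ranks[cur] <- ranks[h]
    ranks[h] <- s
  }
  base <- stats::setNames(p[ranks], names(ranks))

  effects <- NULL
  case <- base
  if (n_eff) {
    planted_ids <- c(hosts[seq_len(planted_db_n)], novel_ids[seq_len(sum(pe$novel))])
    fc <- c(pe$log10_fc[!pe$novel], pe$log10_fc[pe$novel])
    effects <- data.frame(species = planted_ids, log10_fc = fc,
                          novel = c(rep(FALSE, planted_db_n),
                                    rep(TRUE, sum(pe$novel))),
                          baseline = base[planted_ids],
                          stringsAsFactors = FALSE)
    shifted <- base[planted_ids] * 10^fc
    rest <- setdiff(names(base), planted_ids)
    scale <- (1 - sum(shifted)) / sum(base[rest])
    if (scale <= 0) stop("planted enrichments exceed the whole community")
    case[planted_ids] <- shifted
    case[rest] <- base[rest] * scale
  }
  out <- data.frame(species = names(base), control = unname(base),
                    case = unname(case), stringsAsFactors = FALSE)
  attr(out, "effects") <- effects
  out
}
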
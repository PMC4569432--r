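#!/usr/bin/env Rscript
# Stage 7 - phylogeny of the significantly shifted species.
#
# Pairwise V1-V2 similarity among the significant clusters' representative
# sequences, a midpoint-rooted neighbor-joining tree, and bootstrap
# support from 1,000 column resamples of the center-star alignment.

library(ampliprof)

study <- readRDS("results/cache/03_study.rds")

sig_ids <- study$diff$cluster_id[study$diff$significant]
retained <- study$clusters[study$clusters$cluster_id %in% sig_ids, ]
seqs <- ampliprof:::cluster_rep_v1v2(retained, study$truth, study$refdb$db)
cat(sprintf("building the tree over %d significant clusters\n", length(seqs)))

aln <- msa_center_star(seqs)
# similarity from matching non-gap alignment columns (robust for the
# deeply diverged cross-phylum pairs in this set)
sim <- 1 - ampliprof:::pdist_from_alignment(aln)
write.table(round(100 * sim, 1), "results/tables/v1v2_similarity.tsv",
            sep = "\t", quote = FALSE, col.names = NA)
off <- sim[upper.tri(sim)]
cat(sprintf("pairwise V1-V2 similarity: %.1f%% median (range %.1f-%.1f%%)\n",
            100 * median(off), 100 * min(off), 100 * max(off)))
boot <- bootstrap_support(aln, n_reps = 1000L, seed = study$config$seed)
boot_rooted <- phangorn::midpoint(boot)
ape::write.tree(boot, "results/tables/significant_species_nj.nwk")
sup <- attr(boot, "support")
cat(sprintf("bootstrap (1,000 replicates): %d/%d internal edges with >= 700 support\n",
            sum(sup$count >= 700), nrow(sup)))

pdf("results/figures/significant_species_tree.pdf", width = 6, height = 7)
plot(boot_rooted, cex = 0.7, main = "NJ tree of significant clusters")
if (!is.null(boot_rooted$node.label))
  ape::nodelabels(boot_rooted$node.label, cex = 0.55, frame = "none",
                  adj = c(1.1, -0.3))
dev.off()
cat("stage 7 done\n")
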
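#!/usr/bin/env Rscript
# Stage 5 - community structure: UniFrac, PCoA, ANOSIM, group distances.
#
# The cluster tree is a midpoint-rooted NJ over the retained clusters'
# V1-V2 representative sequences; unweighted and normalized weighted
# UniFrac distances are ordinated by classical PCoA and tested by ANOSIM
# with label permutations.

library(ampliprof)

study <- readRDS("results/cache/03_study.rds")
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

for (variant in c("unweighted", "weighted")) {
  b <- study$beta[[variant]]
  cat(sprintf("\n%s UniFrac:\n", variant))
  cat(sprintf("  ANOSIM R = %.3f, P = %.4g (%d permutations)\n",
              b$anosim$R, b$anosim$p, b$anosim$n_perm))
  expl <- b$pcoa$explained
  cat(sprintf("  PCoA axes 1-2 explain %.2f%% and %.2f%% of the variance\n",
              100 * expl[1], 100 * expl[2]))
  print(b$groups$summary, row.names = FALSE)
  print(b$groups$tests, row.names = FALSE)

  write.table(round(b$d, 6),
              sprintf("results/tables/unifrac_%s.tsv", variant),
              sep = "\t", quote = FALSE, col.names = NA)
  ords <- data.frame(sample_id = rownames(b$pcoa$coordinates),
                     b$pcoa$coordinates[, 1:2],
                     group = study$table$sheet$group[
                       match(rownames(b$pcoa$coordinates),
                             study$table$sheet$sample_id)])
  write.table(ords, sprintf("results/tables/pcoa_%s.tsv", variant),
              sep = "\t", quote = FALSE, row.names = FALSE)

  pdf(sprintf("results/figures/pcoa_%s.pdf", variant), width = 5, height = 5)
  plot(ords$PC1, ords$PC2, pch = ifelse(ords$group == "MS", 19, 1),
       xlab = sprintf("PC1 (%.2f%%)", 100 * expl[1]),
       ylab = sprintf("PC2 (%.2f%%)", 100 * expl[2]),
       main = sprintf("%s UniFrac PCoA (ANOSIM R = %.3f)", variant,
                      b$anosim$R))
  legend("topright", legend = c("HC", "MS"), pch = c(1, 19), bty = "n")
  dev.off()
}
ape::write.tree(study$beta$tree, "results/tables/cluster_tree.nwk")
cat("\nstage 5 done\n")
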
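#!/usr/bin/env Rscript
# Stage 6 - species-level differential abundance and longitudinal
# validation.
#
# Welch's t-test per retained cluster on relative abundances, BH-adjusted
# q-values, log10 case/control fold changes under the not-detected -> 1
# read rule, and per-timepoint fold changes against the longitudinal
# control series.  Recovery of the planted effects is summarised at the
# end.

library(ampliprof)

study <- readRDS("results/cache/03_study.rds")

diff <- study$diff
tax <- study$taxonomy
table1 <- merge(diff, tax[, c("cluster_id", "best_hit_species",
                              "best_hit_identity", "secondary_name",
                              "secondary_identity")], by = "cluster_id")
table1 <- table1[order(-table1$log10_fc), ]
write.table(table1, "results/tables/differential_abundance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- table1[table1$significant, ]
cat(sprintf("%d of %d species-level clusters differ at p < 0.05 (%d at q < 0.05)\n",
            nrow(sig), nrow(table1), sum(table1$q < 0.05)))
cat(sprintf("  %d enriched and %d depleted in the case group\n",
            sum(sig$log10_fc > 0), sum(sig$log10_fc < 0)))
print(sig[, c("cluster_id", "kind", "best_hit_species", "best_hit_identity",
              "log10_fc", "p", "q")], row.names = FALSE, digits = 3)

lv <- study$longitudinal
write.table(lv$per_timepoint, "results/tables/longitudinal_fold_changes.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(lv$consistency, "results/tables/longitudinal_consistency.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("\nlongitudinal validation: %d/%d significant clusters keep their fold-change sign\nin the majority of the %d timepoints\n",
            sum(lv$consistency$sign_consistency > 0.5),
            nrow(lv$consistency), study$config$n_timepoints))

# planted-effect recovery
truth <- study$truth
eff <- truth$effects
rep_sp <- sub("_copy\\d+$", "", study$clusters$representative_id)
cl_by_sp <- stats::setNames(study$clusters$cluster_id, rep_sp)
un <- study$clusters[study$clusters$kind == "unmap_OTU", ]
novel_cl <- vapply(eff$species[eff$novel], function(sp) {
  ident <- vapply(un$representative_seq, function(rr)
    align_overlap(rr, truth$cores[[sp]])$global_identity, numeric(1))
  un$cluster_id[which.max(ident)]
}, character(1))
matched <- c(stats::setNames(unname(cl_by_sp[eff$species[!eff$novel]]),
                             eff$species[!eff$novel]), novel_cl)
fc_planted <- c(eff$log10_fc[!eff$novel], eff$log10_fc[eff$novel])
sig_by <- stats::setNames(diff$significant, diff$cluster_id)
est_by <- stats::setNames(diff$log10_fc, diff$cluster_id)
hit <- sig_by[matched] & sign(est_by[matched]) == sign(fc_planted)
hit[is.na(hit)] <- FALSE
recovery <- data.frame(species = names(matched), cluster = unname(matched),
                       planted_fc = fc_planted,
                       estimated_fc = unname(est_by[matched]),
                       detected = unname(hit))
write.table(recovery, "results/tables/planted_recovery.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("\nplanted-effect sensitivity: %.2f (%d of %d recovered)\n",
            mean(hit), sum(hit), length(hit)))

pdf("results/figures/fold_changes.pdf", width = 6, height = 5)
ord <- order(recovery$planted_fc)
plot(recovery$planted_fc[ord], type = "b", pch = 19, ylim = range(
  c(recovery$planted_fc, recovery$estimated_fc)),
  xlab = "planted effect (ranked)", ylab = "log10 fold change (case/control)")
points(recovery$estimated_fc[ord], pch = 1, col = "red", type = "b")
abline(h = 0, lty = 3)
legend("topleft", c("planted", "estimated"), pch = c(19, 1),
       col = c("black", "red"), bty = "n")
dev.off()
cat("stage 6 done\n")
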
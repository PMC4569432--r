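#!/usr/bin/env Rscript
# Stage 1 - simulate the study inputs.
#
# Builds the synthetic cohort this analysis profiles: a species backbone
# evolved along a birth-death tree, a reference collection with planted
# defects and redundancy, and the cross-sectional (20 case / 40 control)
# plus longitudinal (18 subjects x 9 timepoints) sampling design with 21
# planted case/control effects.  Reads themselves are generated on the fly
# in stage 3 (they are large and fully determined by the seed).

library(ampliprof)

seed <- 1L
dir.create("results/cache", recursive = TRUE, showWarnings = FALSE)
dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
print(cfg)

truth <- simulate_species_backbone(cfg)
ref <- generate_reference_db(cfg, truth)

cat(sprintf("species backbone: %d species (%d in the database, %d novel)\n",
            nrow(truth$species), sum(truth$species$in_db),
            sum(truth$species$novel)))
cat(sprintf("reference collection: %d records (%d clean, %d planted defects)\n",
            nrow(ref$records), sum(ref$records$source == "clean"),
            sum(ref$records$source != "clean")))
cat(sprintf("planted effects: %d (%d enriched, %d depleted; %d on novel species)\n",
            nrow(truth$effects), sum(truth$effects$log10_fc > 0),
            sum(truth$effects$log10_fc < 0), sum(truth$effects$novel)))

write.table(truth$composition, "results/tables/true_composition.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(truth$effects, "results/tables/planted_effects.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(sample_sheet(cfg), "results/tables/sample_sheet.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
ape::write.tree(truth$tree, "results/tables/generating_tree.nwk")
jsonlite::write_json(
  list(seed = seed,
       species = truth$species,
       effects = truth$effects),
  "results/tables/ground_truth.json", auto_unbox = TRUE, digits = NA)

saveRDS(list(cfg = cfg, truth = truth, ref = ref), "results/cache/01_inputs.rds")
cat("stage 1 done: inputs cached under results/cache/\n")
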
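#!/usr/bin/env Rscript
# Stage 4 — segmentation into groups N1/N2/N3.
#
# Pairs with global RMSD > 2 A are N1 (globally different); globally
# similar pairs whose largest window RMSD exceeds 2 A are N2 (local
# rearrangement at the site); the rest are N3. The modification site's
# secondary-structure context (helix / strand / coil middle or edge) is
# read from the generator's ground truth via the dihedral heuristic.

library(ptmlocal)

candidates <- load_candidates("results/cohort/manifest.tsv")
cur <- curate_pairs(candidates)
geometry <- read.delim("results/window_metrics.tsv")
geoms <- lapply(cur$records, function(r)
  geometry[geometry$pair_id == r$pair_id, ])

segments <- segment_pairs(cur$records, geoms, threshold = 2.0,
                          ss_source = "dihedral")
write.table(segments, "results/groups.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

truth <- read.delim("results/cohort/truth.tsv")
merged <- merge(segments, truth, by = "uniprot_id")
cat("Group sizes:\n")
print(table(segments$label))
cat(sprintf("Agreement with generator truth: %.0f%%\n",
            100 * mean(merged$label == merged$expected_label)))
cat("Site secondary-structure context by group:\n")
print(context_table(segments))
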
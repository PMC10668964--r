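#!/usr/bin/env Rscript
# Stage 5 — distribution summaries.
#
# Per-group, per-neighborhood medians of window RMSD, dRg and dSASA,
# and Gaussian KDE curves (Scott bandwidth, 500 grid points) of the
# window RMSD distributions. Figures are regenerated from the backing
# tables, never the other way round.

library(ptmlocal)

geometry <- read.delim("results/window_metrics.tsv")
segments <- read.delim("results/groups.tsv")
geometry$label <- segments$label[match(geometry$pair_id, segments$pair_id)]

medians <- do.call(rbind, lapply(intersect(c("N2", "N3"), geometry$label),
  function(gr) {
    do.call(rbind, lapply(c("rmsd_window", "delta_rg_percent",
                            "delta_sasa_per_residue"), function(m) {
      cbind(label = gr, metric = m, group_medians(geometry, m, gr))
    }))
  }))
write.table(medians, "results/group_medians.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

kde <- kde_table(geometry, "rmsd_window")
write.table(kde, "results/kde_rmsd_window.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Median window RMSD by group and neighborhood (A):\n")
print(reshape(medians[medians$metric == "rmsd_window",
                      c("label", "k", "median")],
              direction = "wide", idvar = "label", timevar = "k"),
      digits = 3)

dir.create("results/figures", showWarnings = FALSE)
pdf("results/figures/rmsd_kde.pdf", width = 7, height = 5)
cols <- c(N1 = "firebrick", N2 = "darkorange", N3 = "steelblue")
plot(NA, xlim = range(kde$grid), ylim = range(kde$density),
     xlab = "window RMSD (A)", ylab = "density",
     main = "Window RMSD distributions by group (k = 3..15)")
for (lab in unique(kde$label)) for (k in unique(kde$k)) {
  cur <- kde[kde$label == lab & kde$k == k, ]
  if (nrow(cur)) lines(cur$grid, cur$density, col = cols[[lab]])
}
legend("topright", legend = names(cols), col = cols, lty = 1, bty = "n")
dev.off()
cat("Figure written to results/figures/rmsd_kde.pdf\n")
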
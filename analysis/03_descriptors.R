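#!/usr/bin/env Rscript
# Stage 3: per-gene distribution descriptors and summary figures.
#
# Quartiles, half-widths (Q3 - Q1) and medians per gene and coordinate on
# the pooled cells; ECDF overlays with per-organ curves and the
# quartile-ellipse comparison panel.

suppressPackageStartupMessages(library(olfzones))

cells <- read_normalized("results/normalized_cells.tsv")
descriptors <- summarize_distributions(cells)
write_descriptors(descriptors, "results/descriptors.tsv")

lam <- descriptors[descriptors$coordinate == "laminar" &
                     descriptors$gene %in% sparse_genes(), ]
cat("Laminar medians of the sparse receptors:\n")
print(lam[order(lam$median), c("gene", "median", "half_width", "n")],
      row.names = FALSE)
cat(sprintf("Median spread (most apical - most basal): %.1f%% of epithelial height\n",
            median_spread(descriptors, sparse_genes())))

rad <- descriptors[descriptors$coordinate == "radial" &
                     descriptors$gene %in% sparse_genes(), ]
cat(sprintf("Radial half-widths: %.3f-%.3f of lamellar length\n",
            min(rad$half_width), max(rad$half_width)))

lam_D <- distance_range(coordinate_samples(cells, "laminar",
                                           sparse_genes()))
cat(sprintf("Laminar maximal vertical distances: %.1f%%-%.1f%% of cells\n",
            lam_D[["min"]], lam_D[["max"]]))

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)
for (co in c("laminar", "radial", "z")) {
  p <- plot_ecdfs(cells, co, genes = c(sparse_genes(), "c1"))
  ggplot2::ggsave(sprintf("results/figures/ecdf_%s.pdf", co), p,
                  width = 8, height = 6)
}
pe <- plot_quartile_ellipses(descriptors)
ggplot2::ggsave("results/figures/quartile_ellipses.pdf", pe,
                width = 6, height = 6)
cat("Descriptors written to results/descriptors.tsv; figures under results/figures/\n")
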
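#!/usr/bin/env Rscript
# Stage 1: generate the reference organ set.
#
# Five synthetic cup-shaped olfactory organs per gene, 40-60 horizontal
# sections each, with labeled-cell counts and positions drawn from the
# packaged per-gene calibration (six sparse OlfC receptors, the broadly
# expressed co-receptor c1, and the markers omp and trpc2).

suppressPackageStartupMessages(library(olfzones))

seed <- 1L
dir.create("results", showWarnings = FALSE)

profiles <- default_gene_profiles()
raw <- simulate_cells(profiles, n_organs = 5, seed = seed)
write_raw_cells(raw, "results/raw_cells.tsv")

counts <- table(raw$gene)
cat("Simulated", nrow(raw), "labeled cells (seed", seed, ")\n")
cat("Cells per gene:\n")
print(counts)
sparse_counts <- counts[sparse_genes()]
cat(sprintf("Sparse genes: %d-%d cells pooled over 5 organs (%.0f-%.0f per organ)\n",
            min(sparse_counts), max(sparse_counts),
            min(sparse_counts) / 5, max(sparse_counts) / 5))
cat("Raw table written to results/raw_cells.tsv\n")
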
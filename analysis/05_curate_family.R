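#!/usr/bin/env Rscript
# Stage 5: receptor-family curation filter chain on a synthetic candidate set.
#
# Demonstrates the acceptance filters for bona fide family members on a
# fully synthetic 20-candidate family with planted outcomes: two allelic
# pairs (>98% amino-acid identity), one genomic overlap conflict, and one
# interloper attached inside the family clade via a low-support node.

suppressPackageStartupMessages(library(olfzones))

fam <- synthetic_family(seed = 1)
res <- curate_family(fam$alignment, fam$loci, fam$tree, fam$anchors,
                     gap_fraction_threshold = 0.90,
                     identity_threshold = 98, min_support = 80)

cat("Candidates:", nrow(res$report), " accepted:", length(res$accepted), "\n\n")
print(res$report[c("candidate", "is_representative", "overlap_pass",
                   "support_status", "accepted", "reason")],
      row.names = FALSE)

ok <- identical(res$accepted, fam$truth$accepted)
cat("\nPlanted truth recovered exactly:", ok, "\n")

dir.create("results", showWarnings = FALSE)
utils::write.table(res$report, "results/curation_report.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Report written to results/curation_report.tsv\n")
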
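#!/usr/bin/env Rscript

# Stage 1 - simulate the full input bundle with planted ground truth.
#
# Generates, under one master seed, everything the cascade consumes: four
# case/control miRNA expression studies (planted SMD 2.85), a tumor/normal
# matrix over 1200 genes (10% planted DE, |log2FC| 3), 12-database target
# votes, a confidence-weighted interaction network with a 15-gene near-clique
# module, 25 pathway gene sets with a 9-pathway crosstalk cluster (3
# designated pathways holding the 3 anchor genes), 3'UTRs with planted seed
# sites, a clinical table, and 9 validation cohorts. Writes the bundle as
# plain-text fixtures plus a truth sidecar.

suppressMessages(library(mirkey))

seed <- 106L
outdir <- "scratch/fixtures"
cfg <- synthetic_config(seed = seed)
bundle <- make_fixtures(cfg, outdir)

cat("Simulated input bundle (seed", seed, ") written to", outdir, "\n")
cat("  gene universe:", cfg$n_genes, "genes;",
    length(bundle$truth$de_genes), "planted DE\n")
cat("  anchors (ground-truth key genes):",
    paste(bundle$truth$anchors, collapse = ", "), "\n")
cat("  designated (ground-truth crucial) pathways:",
    paste(bundle$truth$designated_pathways, collapse = ", "), "\n")
cat("  planted seed sites:", nrow(bundle$truth$site_offsets), "\n")
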
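#!/usr/bin/env Rscript

# Stage 3 - candidate screening and clinical association battery.
#
# DEGs by Welch t + BH at |log2FC| > 1 & FDR < 0.05; predicted targets by
# the >=5-of-12 database vote rule; candidates = intersection. The clinical
# battery relates marker expression to each covariate with the test
# matched to its type (Kruskal-Wallis / Spearman / Wilcoxon / Cox), BH
# across the battery.

suppressMessages(library(mirkey))

cfg <- synthetic_config(seed = 106L)
bundle <- make_bundle(cfg)

degs <- de_test(bundle$tumor_normal)
predicted <- vote_filter(bundle$votes)
screen <- intersect_candidates(degs, predicted)
clin <- clinical_assoc(attr(bundle$clinical, "marker"), bundle$clinical)

dir.create("results", showWarnings = FALSE)
write.table(degs, "results/deg_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(screen$candidates, "results/candidate_genes.txt")
write.table(clin, "results/clinical_assoc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("DEGs: %d selected (%d up, %d down) of %d genes\n",
            sum(degs$selected), sum(degs$direction == "up"),
            sum(degs$direction == "down"), nrow(degs)))
cat(sprintf("Predicted targets (>=5 of %d databases): %d\n",
            cfg$n_databases, length(predicted)))
cat(sprintf("Candidates (DEG x predicted): %d  [recovered %d of %d planted DE]\n",
            screen$n_both,
            sum(bundle$truth$de_genes %in% screen$candidates),
            length(bundle$truth$de_genes)))
cat("Clinical battery (sorted by p):\n")
print(clin, digits = 3)
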
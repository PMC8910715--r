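#!/usr/bin/env Rscript
# Stage 5: association of candidate intervals with expression.
#
# Intersects the called intervals with the gene models, tallies DEG
# direction inside the intervals, reports the summary percentages, and
# runs a generic hypergeometric over-representation test of the interval
# DEGs against chromosome-level gene sets.

suppressPackageStartupMessages(library(bsarna))

intervals <- read.delim("results/bsa/intervals.tsv")
genes <- read_gene_models("results/synthetic/genes.bed")
de <- read.delim("results/expression/deg_table.tsv")

assoc <- intersect_genes_intervals(genes, intervals)
tal <- tally_direction(de, assoc)

cat("Candidate intervals hold", tal$overall$genes, "genes;",
    tal$overall$degs, "are DEGs (",
    percent(tal$overall$degs, tal$overall$genes), "% )\n")
cat("Direction within intervals:", tal$overall$up, "up /",
    tal$overall$down, "down; up share =", tal$overall$up_percent, "%\n")

dir.create("results/association", recursive = TRUE, showWarnings = FALSE)
write.table(tal$per_interval, "results/association/per_interval.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(tal$overall, "results/association/overall.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

# over-representation of interval DEGs among chromosome gene sets
universe <- de$gene_id[de$status != "filtered"]
degs <- intersect(de$gene_id[de$status %in% c("up", "down")], universe)
in_iv <- intersect(assoc$genes, universe)
sets <- split(genes$gene_id, genes$chrom)
sets <- lapply(sets, intersect, universe)
enr <- hypergeometric_enrichment(intersect(degs, in_iv), sets, universe)
cat("Chromosome-set enrichment of interval DEGs:\n")
print(enr, digits = 3)
write.table(enr, "results/association/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
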
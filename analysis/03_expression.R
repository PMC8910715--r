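#!/usr/bin/env Rscript
# Stage 3: differential expression, clustering and qPCR concordance.
#
# FPKM quantification, median-of-ratios normalisation, NB Wald test with
# BH adjustment, DEG classification (|log2FC| >= 1, padj <= 0.05, FPKM
# filter), K-means (k = 6) clustering of DEG z-profiles, and 2^-ddCt
# concordance of the 12 qPCR validation genes.

suppressPackageStartupMessages(library(bsarna))

cm <- read_count_matrix("results/synthetic/counts.tsv")
groups <- ifelse(grepl("^Tall", colnames(cm$counts)), "tall", "dwarf")
cat("Count matrix:", nrow(cm$counts), "genes x", ncol(cm$counts), "samples\n")

res <- run_de_pipeline(cm$counts, cm$gene_length, groups)
tab <- table(res$de$status)
cat("DEG classification:\n")
print(tab)
n_up <- sum(res$de$status == "up"); n_down <- sum(res$de$status == "down")
cat(n_up + n_down, "DEGs (", n_up, "up,", n_down, "down in dwarf )\n")

dir.create("results/expression", recursive = TRUE, showWarnings = FALSE)
write.table(res$de, "results/expression/deg_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

degs <- res$de$gene_id[res$de$status %in% c("up", "down")]
prof <- zscore_profiles(res$fpkm, degs)
cl <- kmeans_cluster(prof, groups, k = 6, seed = 303, restarts = 10)
cat("K-means cluster sizes (1..6, decreasing dwarf-vs-tall contrast):\n")
print(cl$sizes)
cat("Sum of cluster sizes:", sum(cl$sizes), "of", length(degs), "DEGs\n")
write.table(data.frame(gene_id = names(cl$cluster), cluster = cl$cluster),
            "results/expression/clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ct <- read_qpcr_csv("results/synthetic/qpcr.csv")
qp <- qpcr_log2fc(ct)
rna <- res$de$log2fc[match(qp$gene, res$de$gene_id)]
r2 <- qpcr_concordance(qp$log2fc, rna)
cat("qPCR vs RNA-seq concordance over", nrow(qp), "genes: R^2 =",
    round(r2, 4), "\n")
write.table(data.frame(qp, rnaseq_log2fc = rna),
            "results/expression/qpcr_concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
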
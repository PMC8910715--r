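#!/usr/bin/env Rscript
# Stage 1: generate the synthetic BC8 study.
#
# One BC8 pedigree (dwarf recurrent parent x tall donor, eight backcrosses
# with carrier selection), 965 plants, bulks of 36 tall / 40 dwarf pooled
# to ~46x/57x; a 3-vs-3 RNA count matrix over 2000 gene models with a
# strong up-in-dwarf skew inside the A01 candidate region; hormone panels
# (IAA x1.5 up, GA x0.6, ABA x0.7 down in dwarf) and a 12-gene qPCR table.
# All downstream stages read only the files written here.

suppressPackageStartupMessages(library(bsarna))

out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 101)
genome <- default_genome()

cat("Simulating BC", cfg$generations, " population (n = ", cfg$n_plants,
    ") ...\n", sep = "")
ex <- simulate_bsa_experiment(cfg, genome)
write_allele_depths(ex$snps, file.path(out, "allele_depths.tsv"))
write_allele_vcf(ex$snps, file.path(out, "bulks.vcf"))
writeLines(sprintf("%s\t%d", ex$truth$chrom, ex$truth$pos),
           file.path(out, "causal_locus.tsv"))
cat("  causal locus:", ex$truth$chrom, ex$truth$pos, "\n")
cat("  phenotypes:", sum(ex$population$phenotype == "tall"), "tall /",
    sum(ex$population$phenotype == "dwarf"), "dwarf\n")

cat("Simulating RNA-seq counts ...\n")
sc <- simulate_counts(cfg, default_gene_models(genome, cfg$n_genes))
write_count_matrix(sc$counts, sc$gene_models$length,
                   file.path(out, "counts.tsv"))
write_gene_bed(sc$gene_models, file.path(out, "genes.bed"))
write.table(sc$truth, file.path(out, "de_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("  ", nrow(sc$counts), "genes,", sum(sc$truth$is_de), "truly DE\n")

cat("Simulating hormone panel and qPCR ...\n")
panel <- simulate_hormones(cfg)
assay <- hormone_assay_tables(panel, seed = cfg$seed)
write.csv(assay$standards, file.path(out, "hormone_standards.csv"),
          row.names = FALSE)
write.csv(assay$samples, file.path(out, "hormone_samples.csv"),
          row.names = FALSE)
ct <- simulate_qpcr(sc$truth, cfg)
write.csv(ct, file.path(out, "qpcr.csv"), row.names = FALSE)
write.table(attr(ct, "truth"), file.path(out, "qpcr_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Done. Inputs for stages 02-05 are under", out, "\n")
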
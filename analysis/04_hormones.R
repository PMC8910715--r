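#!/usr/bin/env Rscript
# Stage 4: hormone quantification and group comparison.
#
# Fits per-compound calibration curves from the standards, quantifies
# sample concentrations from peak areas, aggregates per hormone class and
# compares dwarf vs tall with Welch t-tests and significance stars.

suppressPackageStartupMessages(library(bsarna))

standards <- read_hormone_standards("results/synthetic/hormone_standards.csv")
samples <- read_hormone_samples("results/synthetic/hormone_samples.csv")

panel <- do.call(rbind, lapply(split(samples, samples$compound), function(s) {
  std <- standards[standards$compound == s$compound[1], ]
  curve <- fit_calibration(std$concentration, std$response,
                           compound = s$compound[1])
  q <- quantify_hormone(curve, s$peak_area)
  data.frame(compound = s$compound, class = s$class, group = s$group,
             replicate = s$replicate, concentration = q$concentration)
}))
cat("Quantified", length(unique(panel$compound)), "compounds in",
    length(unique(panel$class)), "classes\n")

report <- hormone_class_report(panel)
dir.create("results/hormones", recursive = TRUE, showWarnings = FALSE)
write.table(report, "results/hormones/class_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(report, digits = 3)

iaa <- report[report$class == "IAA", ]
cat(sprintf("IAA is %.2f- to %.2f-fold %s in dwarf plants (p = %.3g%s)\n",
            iaa$fold_min, iaa$fold_max,
            if (iaa$fold_min >= 1) "higher" else "changed",
            iaa$p, iaa$stars))
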
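Package: bsarna
Title: Bulked-Segregant QTL-seq Mapping with Companion Expression and
    Hormone Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combined bulked-segregant analysis (BSA-Seq) and expression
    profiling for mapping a recessive locus in a backcross population.
    Computes SNP-index and delta(SNP-index) tracks from pooled allele
    depths, smooths them by loess over physical position, derives null
    thresholds by simulation under the BC(n) segregation model, and calls
    candidate intervals. A companion transcriptomics stage quantifies
    FPKM, tests differential expression with a self-contained negative
    binomial Wald test, clusters DEG profiles, and checks qPCR
    concordance via 2^-ddCt. Hormone panels are quantified from
    calibration curves and compared between groups. Candidate intervals
    are intersected with gene models and differential-expression calls.
    A synthetic-data module generates a full BC8 backcross cohort
    (meiosis under the Haldane map function, pooled short-read allele
    sampling, negative binomial counts, hormone and qPCR replicates) so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
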
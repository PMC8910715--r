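#' Simulate a hormone replicate panel
#'
#' Generates per-compound concentrations (ng/g) for 3 tall and 3 dwarf
#' replicates. The compound roster mirrors a typical LC-MS phytohormone
#' screen of this crop: 12 auxin (IAA) forms dominating the totals
#' (class total in the low thousands of ng/g), 4 gibberellins, 8
#' cytokinins and 5 brassinosteroids at trace level (< 15 ng/g class
#' totals), plus single ABA, SL and ETH compounds. Replicate values are
#' lognormal around each compound's base level; dwarf replicates are
#' additionally scaled by the class-level ratio in
#' `config$hormone_ratios`, so with `hormone_sdlog = 0` every
#' dwarf/tall replicate ratio equals the configured class ratio exactly.
#'
#' @param config a [sim_config()].
#' @return data.frame with `compound`, `class`, `group`, `replicate`,
#'   `concentration`.
#' @export
simulate_hormones <- function(config) {
  set.seed(config$seed + 2000L)
  roster <- data.frame(
    class = rep(c("IAA", "GA", "CK", "BR", "ABA", "SL", "ETH"),
                times = c(12L, 4L, 8L, 5L, 1L, 1L, 1L)),
    base = c(stats::rlnorm(12, log(210), 0.6),   # IAA forms, total ~2500
             stats::rlnorm(4, log(3), 0.4),
             stats::rlnorm(8, log(1.2), 0.4),
             stats::rlnorm(5, log(1.6), 0.4),
             150, 5, 2)
  )
  roster$compound <- paste0(roster$class, "_", stats::ave(
    seq_len(nrow(roster)), roster$class, FUN = seq_along))
  nrep <- config$rna_replicates
  rows <- expand.grid(replicate = seq_len(nrep), group = c("tall", "dwarf"),
                      i = seq_len(nrow(roster)), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  ratio <- config$hormone_ratios[roster$class[rows$i]]
  scale <- ifelse(rows$group == "dwarf", ratio, 1)
  conc <- roster$base[rows$i] * scale *
    exp(stats::rnorm(nrow(rows), 0, config$hormone_sdlog))
  data.frame(compound = roster$compound[rows$i],
             class = roster$class[rows$i],
             group = rows$group, replicate = rows$replicate,
             concentration = conc)
}

#' Derive LC-MS assay tables from a hormone panel
#'
#' Turns a concentration panel into the raw inputs the quantification
#' stage consumes: per-compound calibration standards (5 levels spanning
#' the observed range, exact linear response) and sample peak areas on
#' those lines. Useful for exercising calibration fitting and
#' quantification end to end; with exact lines the quantified
#' concentrations reproduce the panel.
#'
#' @param panel output of [simulate_hormones()].
#' @param seed integer seed for the per-compound slopes/intercepts.
#' @return List with `standards` (compound, concentration, response) and
#'   `samples` (compound, class, group, replicate, peak_area).
#' @export
hormone_assay_tables <- function(panel, seed = 1L) {
  set.seed(seed)
  comps <- unique(panel[, c("compound", "class")])
  comps$slope <- stats::runif(nrow(comps), 50, 500)
  comps$intercept <- stats::runif(nrow(comps), 0, 100)
  standards <- do.call(rbind, lapply(seq_len(nrow(comps)), function(i) {
    cc <- panel$concentration[panel$compound == comps$compound[i]]
    conc <- seq(0, max(cc) * 1.2, length.out = 5)
    data.frame(compound = comps$compound[i], concentration = conc,
               response = comps$slope[i] * conc + comps$intercept[i])
  }))
  j <- match(panel$compound, comps$compound)
  samples <- data.frame(compound = panel$compound, class = panel$class,
                        group = panel$group, replicate = panel$replicate,
                        peak_area = comps$slope[j] * panel$concentration +
                          comps$intercept[j])
  list(standards = standards, samples = samples)
}

#' Simulate qPCR Ct tables for validation genes
#'
#' Picks `n_genes` differentially expressed genes from a count-simulation
#' truth table and generates target/reference Ct values consistent with the
#' 2^-ddCt model: the reference gene amplifies at a fixed Ct in every
#' sample, and the target's Ct in dwarf is shifted by -log2FC relative to
#' tall (higher expression, earlier amplification). Gaussian noise
#' (`config$qpcr_noise_sd`) is added to each replicate Ct; with zero noise
#' the 2^-ddCt estimate recovers the simulated fold change exactly.
#'
#' @param truth truth data.frame from [simulate_counts()] (`$truth`).
#' @param config a [sim_config()].
#' @param n_genes number of validation genes (default 12).
#' @return data.frame `gene`, `group`, `replicate`, `ct_target`,
#'   `ct_reference`, with the selected genes' true log2FC attached as
#'   attribute `truth` (data.frame gene, log2fc).
#' @export
simulate_qpcr <- function(truth, config, n_genes = 12L) {
  set.seed(config$seed + 3000L)
  de <- truth[truth$is_de, ]
  if (nrow(de) < n_genes) stop("fewer DE genes than requested for qPCR")
  picked <- de[sample.int(nrow(de), n_genes), ]
  nrep <- config$rna_replicates
  ref_ct <- 20
  base_ct <- stats::runif(n_genes, 22, 28)    # tall-group target Ct
  rows <- expand.grid(replicate = seq_len(nrep), group = c("tall", "dwarf"),
                      i = seq_len(n_genes), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  ct_t <- base_ct[rows$i] -
    ifelse(rows$group == "dwarf", picked$log2fc[rows$i], 0)
  noise <- function(n) stats::rnorm(n, 0, config$qpcr_noise_sd)
  out <- data.frame(gene = picked$gene_id[rows$i], group = rows$group,
                    replicate = rows$replicate,
                    ct_target = ct_t + noise(nrow(rows)),
                    ct_reference = ref_ct + noise(nrow(rows)))
  attr(out, "truth") <- data.frame(gene = picked$gene_id,
                                   log2fc = picked$log2fc)
  out
}
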
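#' Simulation configuration
#'
#' Bundles every tunable of the synthetic BC8 study in one validated object.
#' Defaults reproduce the design of the mapping experiment the package
#' emulates: a BC8 population of 965 plants from a dwarf recurrent parent,
#' bulks of 36 tall and 40 dwarf individuals resequenced to roughly 46x and
#' 57x, a 3-vs-3 replicate RNA count matrix, and hormone class shifts in the
#' dwarf group (IAA up 1.5x, GA down to 0.6x, ABA down to 0.7x).
#'
#' @param generations backcross generation (BC_n), default 8.
#' @param n_plants size of the final backcross population, default 965.
#' @param n_tall,n_dwarf bulk sizes, default 36 and 40.
#' @param depth_tall,depth_dwarf mean pooled sequencing depth per bulk,
#'   default 46 and 57.
#' @param rna_replicates biological replicates per group, default 3.
#' @param n_genes number of gene models, default 2000.
#' @param library_size expected mapped fragments per RNA sample, default 1e6.
#' @param dispersion negative binomial dispersion alpha in
#'   var = mu + alpha * mu^2, default 0.05.
#' @param de_fraction fraction of genes differentially expressed, default 0.1.
#' @param lfc_min,lfc_max |log2 fold-change| of DE genes is drawn uniformly
#'   from this range, defaults 1 and 3.
#' @param region_up_prob probability that a DE gene inside the candidate
#'   region is up-regulated in dwarf, default 0.99 (the direction skew the
#'   association stage is expected to recover).
#' @param hormone_ratios named vector of dwarf/tall class-level concentration
#'   ratios; defaults IAA 1.5, GA 0.6, ABA 0.7, others 1.
#' @param hormone_sdlog lognormal replicate noise (sd on the log scale),
#'   default 0.15; 0 gives noiseless panels.
#' @param qpcr_noise_sd Gaussian Ct noise, default 0.3; 0 gives exact
#'   2^-ddCt recovery.
#' @param seed integer seed; mandatory, every generator derives its stream
#'   from it.
#'
#' @return A classed list (`sim_config`).
#' @export
sim_config <- function(generations = 8L,
                       n_plants = 965L,
                       n_tall = 36L,
                       n_dwarf = 40L,
                       depth_tall = 46,
                       depth_dwarf = 57,
                       rna_replicates = 3L,
                       n_genes = 2000L,
                       library_size = 1e6,
                       dispersion = 0.05,
                       de_fraction = 0.1,
                       lfc_min = 1,
                       lfc_max = 3,
                       region_up_prob = 0.99,
                       hormone_ratios = c(IAA = 1.5, GA = 0.6, ABA = 0.7,
                                          SL = 1, CK = 1, ETH = 1, BR = 1),
                       hormone_sdlog = 0.15,
                       qpcr_noise_sd = 0.3,
                       seed = NULL) {
  if (is.null(seed)) stop("a seed is mandatory for reproducible simulation")
  cfg <- list(generations = as.integer(generations),
              n_plants = as.integer(n_plants),
              n_tall = as.integer(n_tall), n_dwarf = as.integer(n_dwarf),
              depth_tall = depth_tall, depth_dwarf = depth_dwarf,
              rna_replicates = as.integer(rna_replicates),
              n_genes = as.integer(n_genes),
              library_size = library_size, dispersion = dispersion,
              de_fraction = de_fraction,
              lfc_min = lfc_min, lfc_max = lfc_max,
              region_up_prob = region_up_prob,
              hormone_ratios = hormone_ratios,
              hormone_sdlog = hormone_sdlog,
              qpcr_noise_sd = qpcr_noise_sd,
              seed = as.integer(seed))
  counts <- c(cfg$generations, cfg$n_plants, cfg$n_tall, cfg$n_dwarf,
              cfg$rna_replicates, cfg$n_genes)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$dispersion < 0) stop("dispersion must be non-negative")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> BC", x$generations, ", n = ", x$n_plants,
      "; bulks ", x$n_tall, "/", x$n_dwarf,
      " at ", x$depth_tall, "x/", x$depth_dwarf, "x; seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Analysis run configuration
#'
#' Thresholds and tuning parameters of the mapping and expression stages,
#' validated against the documented defaults; unknown keys are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param ... named overrides of the defaults listed below.
#'
#' @section Defaults:
#' \describe{
#'   \item{min_depth, max_depth}{per-bulk depth bounds for informative SNPs:
#'     10, 200.}
#'   \item{span}{loess span as a fraction of per-chromosome SNPs: 0.1.}
#'   \item{confidence}{confidence level of the null threshold: 0.95.}
#'   \item{threshold_reps}{null-simulation replicates per depth: 2000.}
#'   \item{min_snps}{minimum SNPs supporting a candidate interval: 10.}
#'   \item{merge_gap}{bp gap under which adjacent intervals merge: 1e5.}
#'   \item{lfc_cutoff, padj_cutoff}{DEG thresholds: 1, 0.05.}
#'   \item{fpkm_min}{FPKM filter floor: 1.}
#'   \item{fpkm_filter_rule}{"any" (exclude if any sample < fpkm_min) or
#'     "all".}
#'   \item{k}{K-means cluster count: 6.}
#'   \item{kmeans_restarts}{k-means++ restarts: 10.}
#' }
#' @return A classed list (`run_config`).
#' @export
run_config <- function(...) {
  defaults <- list(min_depth = 10, max_depth = 200,
                   span = 0.1, confidence = 0.95, threshold_reps = 2000L,
                   min_snps = 10L, merge_gap = 1e5,
                   lfc_cutoff = 1, padj_cutoff = 0.05,
                   fpkm_min = 1, fpkm_filter_rule = "any",
                   k = 6L, kmeans_restarts = 10L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop("unknown run_config keys: ", paste(unknown, collapse = ", "))
  defaults[names(overrides)] <- overrides
  if (defaults$min_depth > defaults$max_depth) stop("min_depth > max_depth")
  if (!defaults$fpkm_filter_rule %in% c("any", "all")) {
    stop("fpkm_filter_rule must be 'any' or 'all'")
  }
  structure(defaults, class = "run_config")
}
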
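#' Synthetic gene models
#'
#' Places `n_genes` non-overlapping-ish gene bodies uniformly along the
#' genome (count per chromosome proportional to length) with lengths drawn
#' uniformly from 0.5-5 kb. Purely synthetic annotation for pipeline
#' testing; ids are `g0001`, `g0002`, ... in genome order.
#'
#' @param genome a [genome_model()].
#' @param n_genes number of genes.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`, `length`
#'   (bp, 1-based inclusive).
#' @export
default_gene_models <- function(genome, n_genes = 2000L) {
  lens <- genome$chromosomes$length
  n_per <- round(n_genes * lens / sum(lens))
  n_per[1L] <- n_genes - sum(n_per[-1L])
  rows <- lapply(seq_along(lens), function(i) {
    gl <- sample(500:5000, n_per[i], replace = TRUE)
    start <- sort(sample.int(lens[i] - max(gl), n_per[i]))
    data.frame(chrom = genome$chromosomes$chrom[i],
               start = start, end = start + gl - 1L, length = gl)
  })
  out <- do.call(rbind, rows)
  out <- out[order(match(out$chrom, genome$chromosomes$chrom), out$start), ]
  data.frame(gene_id = sprintf("g%04d", seq_len(nrow(out))),
             chrom = out$chrom, start = out$start, end = out$end,
             length = out$length)
}

#' Simulate an RNA-seq count matrix with known differential expression
#'
#' Counts follow a negative binomial model: for gene g in sample j,
#' counts ~ NB(mu = s_j * a_g * FC_g^[j in dwarf], alpha) with
#' var = mu + alpha * mu^2. Per-sample library sizes s_j scatter
#' lognormally (sdlog 0.1) around `config$library_size`; baseline
#' abundances a_g are lognormal and normalised to sum to one. A fraction
#' `de_fraction` of genes is differentially expressed with |log2FC| drawn
#' uniformly from [lfc_min, lfc_max]; DE genes inside the candidate region
#' are up-regulated in dwarf with probability `region_up_prob` (elsewhere
#' 1/2), emulating the strong direction skew a structural-variant region
#' produces.
#'
#' @param config a [sim_config()]; uses its RNG seed stream (offset so the
#'   count draw is independent of the BSA draw under the same seed).
#' @param gene_models data.frame from [default_gene_models()] or a reader.
#' @param candidate_region list(chrom, start, end) carrying the direction
#'   skew; default A01:1-6,330,000.
#' @return List of class `sim_counts`: `counts` (integer matrix genes x 6),
#'   `gene_models`, `groups` (named character vector per sample), and
#'   `truth` (data.frame gene_id, is_de, log2fc, in_region).
#' @export
simulate_counts <- function(config,
                            gene_models = NULL,
                            candidate_region = list(chrom = "A01",
                                                    start = 1, end = 6.33e6)) {
  if (config$dispersion < 0) stop("dispersion must be non-negative")
  set.seed(config$seed + 1000L)
  if (is.null(gene_models)) {
    gene_models <- default_gene_models(default_genome(), config$n_genes)
  }
  ng <- nrow(gene_models)
  nrep <- config$rna_replicates
  groups <- stats::setNames(rep(c("tall", "dwarf"), each = nrep),
                            c(paste0("Tall", seq_len(nrep)),
                              paste0("Dwarf", seq_len(nrep))))
  in_region <- gene_models$chrom == candidate_region$chrom &
    gene_models$end >= candidate_region$start &
    gene_models$start <= candidate_region$end

  abund <- stats::rlnorm(ng, meanlog = 0, sdlog = 1)
  abund <- abund / sum(abund)
  is_de <- seq_len(ng) %in% sample.int(ng, round(config$de_fraction * ng))
  up_prob <- ifelse(in_region, config$region_up_prob, 0.5)
  sign <- ifelse(stats::runif(ng) < up_prob, 1, -1)
  lfc <- ifelse(is_de,
                sign * stats::runif(ng, config$lfc_min, config$lfc_max), 0)

  libsize <- config$library_size * exp(stats::rnorm(2 * nrep, 0, 0.1))
  mu <- outer(abund, libsize)                  # genes x samples
  mu[, groups == "dwarf"] <- mu[, groups == "dwarf"] * 2^lfc
  counts <- matrix(0L, nrow = ng, ncol = 2 * nrep,
                   dimnames = list(gene_models$gene_id, names(groups)))
  if (config$dispersion == 0) {
    counts[] <- stats::rpois(length(mu), mu)
  } else {
    counts[] <- stats::rnbinom(length(mu), mu = mu,
                               size = 1 / config$dispersion)
  }
  structure(list(counts = counts, gene_models = gene_models, groups = groups,
                 truth = data.frame(gene_id = gene_models$gene_id,
                                    is_de = is_de, log2fc = lfc,
                                    in_region = in_region)),
            class = "sim_counts")
}
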
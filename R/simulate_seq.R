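#' Simulate pooled sequencing depths over two bulks
#'
#' Standard pool-seq read model: at each marker and bulk the total depth is
#' Poisson(mean depth) and the number of reads carrying the maternal
#' (recurrent) allele is Binomial(depth, bulk maternal-allele frequency).
#' Sequencing error is off by default; with `error_rate > 0` each read flips
#' allele with that probability.
#'
#' @param bulks list with `tall` and `dwarf` `bc_population`s (see
#'   [select_bulks()]).
#' @param genome a [genome_model()].
#' @param depth_tall,depth_dwarf mean depth per bulk.
#' @param error_rate per-read allele flip probability (default 0).
#' @return A data.frame of SNP records: `chrom`, `pos`, `ref`, `alt`,
#'   `M_tall`, `P_tall`, `M_dwarf`, `P_dwarf`, `missing` (TRUE where either
#'   bulk has zero depth). The maternal allele is written as the REF allele.
#' @export
simulate_bulk_depths <- function(bulks, genome, depth_tall, depth_dwarf,
                                 error_rate = 0) {
  m <- nrow(genome$markers)
  one_bulk <- function(bulk, mean_depth) {
    freq <- bulk_maternal_freq(bulk)
    if (error_rate > 0) {
      freq <- freq * (1 - error_rate) + (1 - freq) * error_rate
    }
    depth <- stats::rpois(m, mean_depth)
    mm <- stats::rbinom(m, depth, freq)
    cbind(M = mm, P = depth - mm)
  }
  tall <- one_bulk(bulks$tall, depth_tall)
  dwarf <- one_bulk(bulks$dwarf, depth_dwarf)
  data.frame(
    chrom = genome$markers$chrom,
    pos = genome$markers$pos,
    ref = "A", alt = "T",
    M_tall = tall[, "M"], P_tall = tall[, "P"],
    M_dwarf = dwarf[, "M"], P_dwarf = dwarf[, "P"],
    missing = (tall[, "M"] + tall[, "P"] == 0L) |
              (dwarf[, "M"] + dwarf[, "P"] == 0L)
  )
}

#' Simulate a complete BSA-Seq experiment
#'
#' Runs the whole design in one call: builds the BC_n population from the
#' F1 by recurrent backcrossing (carrier selection on by default so the
#' causal locus keeps segregating), selects the phenotypic bulks, and
#' draws pooled read depths. With `null = TRUE` the causal locus has no
#' phenotypic effect and bulks are drawn at random from the population —
#' the no-QTL configuration used for calibration studies.
#'
#' @param config a [sim_config()].
#' @param genome a [genome_model()]; defaults to [default_genome()].
#' @param null simulate under the no-QTL null (default FALSE).
#' @return List with `snps` (SNP record table, see
#'   [simulate_bulk_depths()]), `population`, `bulks`, `genome` and `truth`
#'   (causal chrom/pos, or NULL under the null).
#' @export
simulate_bsa_experiment <- function(config, genome = default_genome(),
                                    null = FALSE) {
  set.seed(config$seed)
  pop <- advance_backcross(f1_individual(genome), recurrent_parent(genome),
                           generations = config$generations, genome = genome,
                           n_offspring = config$n_plants,
                           select_carriers = !null)
  if (null) {
    # phenotype unrelated to genotype: random labels, sized to fill bulks
    pop$phenotype <- sample(rep(c("tall", "dwarf"),
                                length.out = config$n_plants))
  }
  bulks <- select_bulks(pop, config$n_tall, config$n_dwarf)
  snps <- simulate_bulk_depths(bulks, genome,
                               depth_tall = config$depth_tall,
                               depth_dwarf = config$depth_dwarf)
  list(snps = snps, population = pop, bulks = bulks, genome = genome,
       truth = if (null) NULL else genome$causal)
}
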
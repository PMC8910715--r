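#' Simulate meiosis under the Haldane map function
#'
#' Produces gametes from an individual as mosaics of its two haplotypes.
#' Each chromosome starts from either haplotype with probability 1/2 and
#' switches between haplotypes in the interval between adjacent markers with
#' the Haldane recombination fraction r = (1 - exp(-2d/100))/2, where d is
#' the map distance in cM implied by the chromosome's cM/Mb rate. Crossovers
#' are independent across intervals (no interference) and chromosomes
#' assort independently.
#'
#' Randomness is taken from R's global RNG stream; set the seed with
#' [set.seed()] (top-level generators do this from their config).
#'
#' @param parent an [individual()].
#' @param genome a [genome_model()].
#' @param n number of gametes to draw.
#' @return If `n = 1` (default) a logical haplotype vector; otherwise a
#'   logical matrix of `nrow(genome$markers)` rows by `n` columns.
#' @export
simulate_meiosis <- function(parent, genome, n = 1L) {
  m <- nrow(genome$markers)
  if (length(parent$h1) != m || length(parent$h2) != m) {
    stop("parent haplotypes are not defined on this genome's markers")
  }
  use_h2 <- matrix(FALSE, nrow = m, ncol = n)
  for (ch in unique(genome$markers$chrom)) {
    idx <- which(genome$markers$chrom == ch)
    r <- recomb_fractions(genome, ch)
    k <- length(idx)
    # switch indicators: row 1 = random start, rows 2..k = crossover events
    sw <- matrix(0L, nrow = k, ncol = n)
    sw[1L, ] <- stats::rbinom(n, 1L, 0.5)
    if (k > 1L) {
      sw[-1L, ] <- stats::rbinom((k - 1L) * n, 1L, rep(r, times = n))
    }
    state <- apply(sw, 2L, cumsum) %% 2L
    use_h2[idx, ] <- state == 1L
  }
  g <- ifelse(use_h2, parent$h2, parent$h1)
  if (n == 1L) as.logical(g[, 1L]) else g
}

#' Advance a backcross lineage and produce a BC_n population
#'
#' Follows the standard recurrent-backcross scheme: at each generation a
#' single offspring of the current segregating parent crossed to the
#' recurrent parent becomes the next generation's parent; the final
#' generation yields `n_offspring` individuals. With `select_carriers` the
#' intermediate parent at every generation is required to be heterozygous at
#' the causal locus, so the final population segregates 1:1 tall:dwarf
#' there (marker-assisted retention of the donor allele, as needed to keep
#' a recessive trait segregating through eight backcrosses).
#'
#' @param f1 the F1 [individual()] (heterozygous at all markers).
#' @param recurrent the recurrent parent [individual()].
#' @param generations number of backcross generations (>= 1).
#' @param genome a [genome_model()].
#' @param n_offspring size of the final BC_n population.
#' @param select_carriers keep the causal locus segregating (default TRUE).
#' @return A `bc_population`: list with logical marker-by-individual
#'   matrices `h1` (gamete from the segregating parent) and `h2` (gamete
#'   from the recurrent parent, all recurrent alleles), and a `phenotype`
#'   character vector ("tall"/"dwarf").
#' @export
advance_backcross <- function(f1, recurrent, generations, genome,
                              n_offspring = 1L, select_carriers = TRUE) {
  if (generations < 1L) stop("generations must be >= 1")
  ci <- genome$causal_index
  parent <- f1
  if (generations > 1L) {
    for (gen in seq_len(generations - 1L)) {
      repeat {
        gam <- simulate_meiosis(parent, genome)
        if (!select_carriers || gam[ci]) break
      }
      parent <- individual(gam, recurrent$h1, genome)
    }
  }
  h1 <- simulate_meiosis(parent, genome, n = n_offspring)
  if (n_offspring == 1L) h1 <- matrix(h1, ncol = 1L)
  h2 <- matrix(FALSE, nrow = nrow(genome$markers), ncol = n_offspring)
  phenotype <- ifelse(h1[ci, ], "tall", "dwarf")
  structure(list(h1 = h1, h2 = h2, phenotype = phenotype, genome = genome),
            class = "bc_population")
}

#' @export
print.bc_population <- function(x, ...) {
  cat("<bc_population> ", ncol(x$h1), " individuals (",
      sum(x$phenotype == "tall"), " tall, ",
      sum(x$phenotype == "dwarf"), " dwarf) over ",
      nrow(x$h1), " markers\n", sep = "")
  invisible(x)
}

#' Extract one individual from a population
#'
#' @param population a `bc_population`.
#' @param i individual index.
#' @return An [individual()].
#' @export
population_individual <- function(population, i) {
  individual(population$h1[, i], population$h2[, i], population$genome)
}

#' Select phenotypic bulks from a backcross population
#'
#' Randomly draws `n_tall` tall and `n_dwarf` dwarf individuals. Under the
#' major recessive locus model every dwarf member is homozygous recurrent at
#' the causal locus and every tall member heterozygous.
#'
#' @param population a `bc_population`.
#' @param n_tall,n_dwarf bulk sizes.
#' @return List with `tall` and `dwarf`, each a `bc_population` subset.
#' @export
select_bulks <- function(population, n_tall, n_dwarf) {
  if (n_tall < 1L || n_dwarf < 1L) {
    stop("bulk sizes must be positive; an empty bulk has no SNP-index")
  }
  tall_idx <- which(population$phenotype == "tall")
  dwarf_idx <- which(population$phenotype == "dwarf")
  if (length(tall_idx) < n_tall || length(dwarf_idx) < n_dwarf) {
    stop("population has too few individuals of a phenotype class (",
         length(tall_idx), " tall, ", length(dwarf_idx), " dwarf)")
  }
  subset_pop <- function(idx) {
    structure(list(h1 = population$h1[, idx, drop = FALSE],
                   h2 = population$h2[, idx, drop = FALSE],
                   phenotype = population$phenotype[idx],
                   genome = population$genome),
              class = "bc_population")
  }
  list(tall = subset_pop(sample(tall_idx, n_tall)),
       dwarf = subset_pop(sample(dwarf_idx, n_dwarf)))
}

#' Recurrent-allele frequency of a bulk at each marker
#'
#' @param bulk a `bc_population`.
#' @return Numeric vector over markers: fraction of recurrent ("maternal")
#'   alleles among the bulk's 2n haplotypes.
#' @export
bulk_maternal_freq <- function(bulk) {
  n <- ncol(bulk$h1)
  donor <- rowSums(bulk$h1) + rowSums(bulk$h2)
  1 - donor / (2 * n)
}
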
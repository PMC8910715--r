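#' Genome model for the backcross simulator
#'
#' A genome model holds the chromosome table, the marker map and the causal
#' locus used by all simulation functions. Recombination is modelled with a
#' constant cM/Mb rate per chromosome and the Haldane (no-interference) map
#' function, so the probability of an odd number of crossovers between two
#' markers d cM apart is (1 - exp(-2d/100)) / 2.
#'
#' @param chromosomes data.frame with columns `chrom` (character) and
#'   `length` (bp).
#' @param markers data.frame with columns `chrom` and `pos` (bp, 1-based);
#'   positions must be strictly increasing within each chromosome.
#' @param rate recombination rate in cM/Mb. Either a single value applied to
#'   every chromosome or a named vector (names = chromosome names).
#' @param causal list with elements `chrom` and `pos`; must coincide with a
#'   marker position.
#'
#' @return An object of class `genome_model`: a list with `chromosomes`,
#'   `markers` (with an integer `index` column), `rate`, `causal` and
#'   `causal_index` (row of the causal marker in the marker table).
#' @export
#' @examples
#' g <- genome_model(
#'   chromosomes = data.frame(chrom = "A01", length = 1e6),
#'   markers     = data.frame(chrom = "A01", pos = c(1e5, 5e5, 9e5)),
#'   rate        = 2,
#'   causal      = list(chrom = "A01", pos = 5e5)
#' )
genome_model <- function(chromosomes, markers, rate, causal) {
  stopifnot(is.data.frame(chromosomes), all(c("chrom", "length") %in% names(chromosomes)))
  stopifnot(is.data.frame(markers), all(c("chrom", "pos") %in% names(markers)))
  if (!all(markers$chrom %in% chromosomes$chrom)) {
    stop("markers reference chromosomes absent from the chromosome table")
  }
  markers <- markers[order(match(markers$chrom, chromosomes$chrom), markers$pos), ,
                     drop = FALSE]
  for (ch in unique(markers$chrom)) {
    p <- markers$pos[markers$chrom == ch]
    if (any(diff(p) <= 0)) stop("marker positions must be strictly increasing on ", ch)
  }
  if (length(rate) == 1L && is.null(names(rate))) {
    rate <- stats::setNames(rep(rate, nrow(chromosomes)), chromosomes$chrom)
  }
  if (!all(chromosomes$chrom %in% names(rate))) {
    stop("recombination rate missing for some chromosome")
  }
  markers$index <- seq_len(nrow(markers))
  ci <- which(markers$chrom == causal$chrom & markers$pos == causal$pos)
  if (length(ci) != 1L) stop("causal locus must lie on exactly one marker")
  structure(
    list(chromosomes = chromosomes, markers = markers, rate = rate,
         causal = causal, causal_index = ci),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("<genome_model> ", nrow(x$chromosomes), " chromosome(s), ",
      nrow(x$markers), " markers; causal at ",
      x$causal$chrom, ":", format(x$causal$pos, big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' Default genome used across the synthetic study
#'
#' Two chromosomes sized like the smaller A-subgenome chromosomes of an
#' amphidiploid Brassica (23 and 25 Mb), markers every 100 kb, a uniform
#' 2 cM/Mb recombination rate and the causal dwarfing locus at A01:3,000,000
#' — inside the first few Mb of A01, where the mapping signal is expected.
#'
#' @return A [genome_model()].
#' @export
default_genome <- function() {
  chroms <- data.frame(chrom = c("A01", "A02"), length = c(23e6, 25e6))
  markers <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    data.frame(chrom = chroms$chrom[i],
               pos = seq(1e5, chroms$length[i], by = 1e5))
  }))
  genome_model(chroms, markers, rate = 2,
               causal = list(chrom = "A01", pos = 3e6))
}

#' Per-interval recombination fractions of a genome model
#'
#' Haldane map function applied to the physical distance between adjacent
#' markers of one chromosome: r = (1 - exp(-2 d / 100)) / 2 with d in cM.
#'
#' @param genome a [genome_model()].
#' @param chrom chromosome name.
#' @return Numeric vector of length (number of markers on `chrom`) - 1.
#' @export
recomb_fractions <- function(genome, chrom) {
  pos <- genome$markers$pos[genome$markers$chrom == chrom]
  d_cm <- diff(pos) / 1e6 * genome$rate[[chrom]]
  (1 - exp(-2 * d_cm / 100)) / 2
}

#' Construct an individual from two haplotypes
#'
#' Haplotypes are logical vectors over the genome's markers: `FALSE` for the
#' recurrent (maternal, "M") allele and `TRUE` for the donor (paternal, "P")
#' allele. The phenotype follows the major recessive locus model: dwarf iff
#' homozygous recurrent at the causal locus.
#'
#' @param h1,h2 logical haplotype vectors (length = marker count).
#' @param genome a [genome_model()].
#' @return An object of class `individual` with fields `h1`, `h2`,
#'   `phenotype` ("tall" or "dwarf").
#' @export
individual <- function(h1, h2, genome) {
  n <- nrow(genome$markers)
  if (length(h1) != n || length(h2) != n) {
    stop("haplotype length must equal the genome's marker count")
  }
  ci <- genome$causal_index
  pheno <- if (!h1[ci] && !h2[ci]) "dwarf" else "tall"
  structure(list(h1 = as.logical(h1), h2 = as.logical(h2), phenotype = pheno),
            class = "individual")
}

#' Founder individuals
#'
#' The recurrent parent (dwarf line) is homozygous recurrent everywhere;
#' the donor parent (tall line) homozygous donor; their F1 carries one
#' haplotype of each.
#'
#' @param genome a [genome_model()].
#' @return An `individual`.
#' @export
recurrent_parent <- function(genome) {
  n <- nrow(genome$markers)
  individual(rep(FALSE, n), rep(FALSE, n), genome)
}

#' @rdname recurrent_parent
#' @export
donor_parent <- function(genome) {
  n <- nrow(genome$markers)
  individual(rep(TRUE, n), rep(TRUE, n), genome)
}

#' @rdname recurrent_parent
#' @export
f1_individual <- function(genome) {
  n <- nrow(genome$markers)
  individual(rep(FALSE, n), rep(TRUE, n), genome)
}
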
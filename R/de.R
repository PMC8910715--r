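#' Fragments per kilobase per million mapped fragments
#'
#' FPKM = count / ((length / 1e3) * (total / 1e6)). Vectorised over genes.
#'
#' @param count fragment counts.
#' @param gene_length transcript/gene length in bp (> 0).
#' @param total total mapped fragments in the sample (> 0).
#' @return FPKM values.
#' @export
#' @examples
#' compute_fpkm(10, 1000, 1e6)  # 10
compute_fpkm <- function(count, gene_length, total) {
  if (any(gene_length <= 0)) stop("gene lengths must be positive")
  if (any(total <= 0)) stop("library size must be positive")
  count / ((gene_length / 1e3) * (total / 1e6))
}

#' FPKM matrix from a count matrix
#'
#' @param counts genes x samples matrix.
#' @param gene_length per-gene lengths (bp).
#' @param totals per-sample mapped fragments; defaults to column sums.
#' @return Matrix of FPKM, same dimnames as `counts`.
#' @export
fpkm_matrix <- function(counts, gene_length, totals = colSums(counts)) {
  sweep(counts / (gene_length / 1e3), 2, totals / 1e6, "/")
}

#' Median-of-ratios size factors
#'
#' For every gene with nonzero counts in all samples, the ratio of each
#' sample's count to the gene's geometric mean is formed; a sample's size
#' factor is the median of its ratios. Factors are returned as computed
#' (no rescaling).
#'
#' @param counts genes x samples matrix.
#' @return Named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) stop("no gene has nonzero counts in every sample")
  logc <- log(counts[ok, , drop = FALSE])
  logmeans <- rowMeans(logc)
  apply(exp(logc - logmeans), 2, stats::median)
}

#' Negative binomial Wald test for two groups
#'
#' Self-contained two-group NB test. Counts are divided by their size
#' factors; per gene the group means mu1 (tall) and mu2 (dwarf) are
#' computed, the dispersion is estimated by pooled method of moments
#' alpha = max(0, (s2 - mu) / mu^2) with s2 the pooled within-group
#' variance and mu the mean of the two group means, and the Wald statistic
#' is the log fold-change over its delta-method standard error:
#' SE^2 = (1/n1) (1/mu1' + alpha) + (1/n2) (1/mu2' + alpha), where
#' mu' = mu + 0.5 is the pseudo-counted mean also used in the fold change
#' log2FC = log2((mu2 + 0.5) / (mu1 + 0.5)). Two-sided p-values come from
#' the standard normal.
#'
#' @param counts genes x samples integer matrix.
#' @param groups character vector per sample, values "tall"/"dwarf"
#'   (log2FC is dwarf relative to tall).
#' @param sf size factors (default [size_factors()] of `counts`).
#' @return data.frame `gene_id`, `mu_tall`, `mu_dwarf`, `log2fc`,
#'   `alpha`, `stat`, `p`.
#' @export
nb_wald_test <- function(counts, groups, sf = size_factors(counts)) {
  if (length(unique(groups)) != 2L) stop("exactly two groups required")
  norm <- sweep(counts, 2, sf, "/")
  g1 <- groups == "tall"; g2 <- groups == "dwarf"
  n1 <- sum(g1); n2 <- sum(g2)
  mu1 <- rowMeans(norm[, g1, drop = FALSE])
  mu2 <- rowMeans(norm[, g2, drop = FALSE])
  v1 <- apply(norm[, g1, drop = FALSE], 1, stats::var)
  v2 <- apply(norm[, g2, drop = FALSE], 1, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mubar <- (mu1 + mu2) / 2
  alpha <- pmax(0, (s2 - mubar) / mubar^2)
  alpha[mubar == 0] <- 0
  lfc_ln <- log((mu2 + 0.5) / (mu1 + 0.5))
  se2 <- (1 / n1) * (1 / (mu1 + 0.5) + alpha) +
         (1 / n2) * (1 / (mu2 + 0.5) + alpha)
  stat <- lfc_ln / sqrt(se2)
  p <- 2 * stats::pnorm(-abs(stat))
  data.frame(gene_id = rownames(counts) %||% seq_len(nrow(counts)),
             mu_tall = mu1, mu_dwarf = mu2,
             log2fc = lfc_ln / log(2), alpha = alpha, stat = stat, p = p,
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with monotonicity enforcement, via `stats::p.adjust`.
#'
#' @param p p-values in \[0, 1\].
#' @return Adjusted p-values, each in \[p, 1\].
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify genes into DEG statuses
#'
#' Applies the expression filter and the fold-change / adjusted-p cutoffs:
#' genes whose FPKM falls below `fpkm_min` in any sample (rule "any"; or in
#' all samples with rule "all") are "filtered"; the rest are "up" if
#' log2FC >= `lfc_cutoff` and padj <= `padj_cutoff`, "down" if
#' log2FC <= -`lfc_cutoff` and padj <= `padj_cutoff`, else "ns".
#'
#' @param de data.frame with `log2fc` and `p` columns (see
#'   [nb_wald_test()]); a `padj` column is added if absent.
#' @param fpkm genes x samples FPKM matrix, rows aligned with `de`.
#' @param lfc_cutoff,padj_cutoff DEG thresholds (defaults 1, 0.05).
#' @param fpkm_min expression floor (default 1).
#' @param rule "any" (default) or "all" — which samples must fall below
#'   `fpkm_min` for exclusion.
#' @return `de` with `padj` and `status` columns.
#' @export
classify_degs <- function(de, fpkm, lfc_cutoff = 1, padj_cutoff = 0.05,
                          fpkm_min = 1, rule = c("any", "all")) {
  rule <- match.arg(rule)
  if (is.null(de$padj)) de$padj <- bh_adjust(de$p)
  low <- fpkm < fpkm_min
  excluded <- if (rule == "any") rowSums(low) > 0 else rowSums(low) == ncol(fpkm)
  status <- rep("ns", nrow(de))
  status[de$log2fc >= lfc_cutoff & de$padj <= padj_cutoff] <- "up"
  status[de$log2fc <= -lfc_cutoff & de$padj <= padj_cutoff] <- "down"
  status[excluded] <- "filtered"
  de$status <- status
  de
}

#' Full differential-expression pipeline
#'
#' Size factors, NB Wald test, BH adjustment, FPKM and DEG classification
#' in one call.
#'
#' @param counts genes x samples matrix.
#' @param gene_length per-gene lengths (bp).
#' @param groups per-sample group labels ("tall"/"dwarf").
#' @param rc a [run_config()].
#' @return List with `de` (classified result table) and `fpkm` (matrix).
#' @export
run_de_pipeline <- function(counts, gene_length, groups, rc = run_config()) {
  de <- nb_wald_test(counts, groups)
  de$padj <- bh_adjust(de$p)
  fpkm <- fpkm_matrix(counts, gene_length)
  de <- classify_degs(de, fpkm, lfc_cutoff = rc$lfc_cutoff,
                      padj_cutoff = rc$padj_cutoff, fpkm_min = rc$fpkm_min,
                      rule = rc$fpkm_filter_rule)
  # per-group mean FPKM for reporting
  de$fpkm_tall <- rowMeans(fpkm[, groups == "tall", drop = FALSE])
  de$fpkm_dwarf <- rowMeans(fpkm[, groups == "dwarf", drop = FALSE])
  list(de = de, fpkm = fpkm)
}
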
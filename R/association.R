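#' Intersect gene models with candidate intervals
#'
#' A gene belongs to an interval iff the two overlap by at least 1 bp under
#' 1-based inclusive coordinates (any-overlap rule; set
#' `rule = "start_within"` to require the gene start inside the interval).
#' Genes are assigned to every interval they overlap; the overall gene list
#' is de-duplicated.
#'
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`.
#' @param intervals data.frame `chrom`, `start`, `end`.
#' @param rule "any_overlap" (default) or "start_within".
#' @return List with `hits` (data.frame `interval`, `gene_id`),
#'   `per_interval` (list of gene-id vectors) and `genes` (unique gene ids
#'   over all intervals).
#' @export
intersect_genes_intervals <- function(genes, intervals,
                                      rule = c("any_overlap", "start_within")) {
  rule <- match.arg(rule)
  n_iv <- nrow(intervals)
  per_interval <- rep(list(character(0)), n_iv)
  hits <- data.frame(interval = integer(), gene_id = character())
  no_shared <- n_iv > 0L && !any(intervals$chrom %in% genes$chrom)
  if (no_shared) {
    warning("no shared chromosome names between genes and intervals")
  }
  if (n_iv > 0L && nrow(genes) > 0L && !no_shared) {
    g_start <- if (rule == "start_within") genes$start else genes$start
    g_end <- if (rule == "start_within") genes$start else genes$end
    gr_genes <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(g_start, g_end))
    gr_iv <- GenomicRanges::GRanges(
      intervals$chrom, IRanges::IRanges(intervals$start, intervals$end))
    ov <- GenomicRanges::findOverlaps(gr_genes, gr_iv)
    hits <- data.frame(
      interval = S4Vectors::subjectHits(ov),
      gene_id = genes$gene_id[S4Vectors::queryHits(ov)])
    per_interval <- lapply(seq_len(n_iv),
                           function(i) hits$gene_id[hits$interval == i])
  }
  list(hits = hits, per_interval = per_interval,
       genes = unique(hits$gene_id))
}

#' Percentage rounded half-up to two decimals
#'
#' @param numerator,denominator counts; denominator must be positive.
#' @return 100 * numerator / denominator, rounded half-up to 2 decimals.
#' @export
#' @examples
#' percent(542, 1256)  # 43.15
#' percent(538, 542)   # 99.26
percent <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  round_half_up(100 * numerator / denominator, 2)
}

#' Tally DEG direction within candidate intervals
#'
#' Counts up/down/ns/filtered genes per interval and over the union of all
#' intervals, with the up-regulated percentage among interval DEGs (NA
#' when an interval holds no DEG).
#'
#' @param de classified DE table (see [classify_degs()]), with `gene_id`
#'   and `status`.
#' @param assoc output of [intersect_genes_intervals()].
#' @return List with `per_interval` (data.frame interval, genes, up, down,
#'   ns, filtered, degs, up_percent) and `overall` (one-row data.frame over
#'   the de-duplicated union).
#' @export
tally_direction <- function(de, assoc) {
  status_of <- stats::setNames(de$status, de$gene_id)
  tally <- function(ids) {
    st <- status_of[ids]
    up <- sum(st == "up", na.rm = TRUE)
    down <- sum(st == "down", na.rm = TRUE)
    ns <- sum(st == "ns", na.rm = TRUE)
    filtered <- sum(st == "filtered", na.rm = TRUE)
    degs <- up + down
    data.frame(genes = length(ids), up = up, down = down, ns = ns,
               filtered = filtered, degs = degs,
               up_percent = if (degs > 0) percent(up, degs) else NA_real_)
  }
  per_iv <- do.call(rbind, lapply(seq_along(assoc$per_interval), function(i) {
    cbind(interval = i, tally(assoc$per_interval[[i]]))
  }))
  list(per_interval = per_iv, overall = tally(assoc$genes))
}

#' Hypergeometric over-representation test over gene sets
#'
#' Upper-tail hypergeometric test P(X >= overlap) of a gene list against
#' each user-supplied set, BH-adjusted across sets. A generic
#' over-representation analysis: pathway/ontology membership tables are
#' supplied by the caller, no live database is consulted.
#'
#' @param hit_genes character vector (e.g. the DEGs), must lie in
#'   `universe`.
#' @param sets named list of character vectors, each a subset of
#'   `universe`.
#' @param universe character vector of all eligible genes.
#' @return data.frame `set`, `set_size`, `overlap`, `p`, `padj`.
#' @export
hypergeometric_enrichment <- function(hit_genes, sets, universe) {
  if (!all(hit_genes %in% universe)) stop("hit genes must lie in the universe")
  for (s in names(sets)) {
    if (!all(sets[[s]] %in% universe)) stop("set '", s, "' is not contained in the universe")
  }
  N <- length(universe)
  n <- length(hit_genes)
  rows <- lapply(names(sets), function(s) {
    K <- length(sets[[s]])
    k <- length(intersect(hit_genes, sets[[s]]))
    p <- if (k == 0L) 1 else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, set_size = K, overlap = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$padj <- bh_adjust(out$p)
  out
}
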
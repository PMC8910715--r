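#' SNP-index of one bulk at one site
#'
#' The SNP-index is the fraction of reads carrying the maternal (recurrent
#' parent) allele: M / (M + P). Sites with zero total depth get a missing
#' value, never 0.
#'
#' @param M,P maternal/paternal read counts (vectors recycle).
#' @return Numeric vector in \[0, 1\], `NA` where M + P = 0.
#' @export
#' @examples
#' compute_snp_index(10, 10)  # 0.5
#' compute_snp_index(7, 0)    # 1
compute_snp_index <- function(M, P) {
  if (any(M < 0 | P < 0, na.rm = TRUE)) stop("allele depths must be >= 0")
  tot <- M + P
  ifelse(!is.na(tot) & tot > 0, M / tot, NA_real_)
}

#' Delta(SNP-index): dwarf bulk minus tall bulk
#'
#' @param index_dwarf,index_tall per-site SNP-index of each bulk.
#' @return Numeric vector in \[-1, 1\]; `NA` where either index is missing.
#' @export
compute_delta_index <- function(index_dwarf, index_tall) {
  index_dwarf - index_tall
}

#' Filter SNP records to informative sites
#'
#' Keeps biallelic, parent-polymorphic sites where both bulks have total
#' depth within `[min_depth, max_depth]` and the record is not flagged
#' missing. These are the standard QTL-seq site filters; the depth window
#' removes both low-confidence sites and collapsed repeats.
#'
#' @param records SNP record data.frame (see [simulate_bulk_depths()] /
#'   [read_allele_depths()]).
#' @param min_depth,max_depth inclusive per-bulk total depth bounds.
#' @return The retained rows.
#' @export
filter_informative_snps <- function(records, min_depth = 10, max_depth = 200) {
  if (min_depth > max_depth) stop("min_depth must not exceed max_depth")
  dt <- records$M_tall + records$P_tall
  dd <- records$M_dwarf + records$P_dwarf
  keep <- !is.na(dt) & !is.na(dd) &
    dt >= min_depth & dt <= max_depth &
    dd >= min_depth & dd <= max_depth
  if (!is.null(records$missing)) keep <- keep & !records$missing
  if (all(c("ref", "alt") %in% names(records))) {
    keep <- keep & !is.na(records$ref) & !is.na(records$alt) &
      records$ref != records$alt
  }
  records[keep, , drop = FALSE]
}

#' Build the SNP-index track from filtered records
#'
#' Adds per-bulk SNP-index columns and their difference
#' `delta = snp_index_dwarf - snp_index_tall`.
#'
#' @param records filtered SNP record data.frame.
#' @return The records with `snp_index_tall`, `snp_index_dwarf`, `delta`
#'   columns appended.
#' @export
build_index_track <- function(records) {
  records$snp_index_tall <- compute_snp_index(records$M_tall, records$P_tall)
  records$snp_index_dwarf <- compute_snp_index(records$M_dwarf, records$P_dwarf)
  records$delta <- compute_delta_index(records$snp_index_dwarf,
                                       records$snp_index_tall)
  records
}

#' Loess-smooth the delta track over physical position
#'
#' Tricube-weighted local linear regression (`stats::loess`, degree 1,
#' exact "direct" surface) of delta on bp position, fitted and evaluated
#' per chromosome — never across a chromosome boundary. The neighbourhood
#' holds `floor(span * n)` SNPs. Chromosomes with fewer than 5 usable SNPs
#' (or a neighbourhood below 2) are skipped with a warning and keep `NA`
#' smoothed values; missing deltas stay missing.
#'
#' @param track data.frame from [build_index_track()].
#' @param span neighbourhood fraction of per-chromosome SNPs (default 0.1).
#' @return `track` with a `delta_smooth` column.
#' @export
smooth_delta <- function(track, span = 0.1) {
  track$delta_smooth <- NA_real_
  for (ch in unique(track$chrom)) {
    sel <- which(track$chrom == ch & !is.na(track$delta))
    n <- length(sel)
    if (n < 5L || floor(span * n) < 2L) {
      warning("chromosome ", ch, " has too few SNPs to smooth (", n, ")")
      next
    }
    fit <- stats::loess(delta ~ pos, data = track[sel, ],
                        span = span, degree = 1, family = "gaussian",
                        surface = "direct")
    track$delta_smooth[sel] <- stats::fitted(fit)
  }
  track
}

#' Simulate null thresholds for delta(SNP-index)
#'
#' Two-level QTL-seq-style simulation under the no-QTL null of a segregating
#' backcross marker: each bulk member is heterozygous with probability 1/2
#' (the BC_n segregation ratio at a polymorphic site, whatever n — sites
#' monomorphic in the population carry delta 0 and never reach the
#' threshold test), giving the bulk's maternal-allele frequency; reads are
#' then Binomial(depth, frequency) in each bulk. Upper quantiles of the
#' simulated delta are tabulated per depth and regularised to be monotone
#' non-increasing in depth (suffix maximum), since deeper sites can only
#' tighten the null.
#'
#' @param n_tall,n_dwarf bulk sizes.
#' @param depths integer vector of depths to tabulate.
#' @param levels confidence levels (default 0.95 and 0.99).
#' @param reps simulation replicates per depth (>= 1000).
#' @return data.frame with `depth` and one `q<level>` column per level,
#'   e.g. `q95`, `q99`.
#' @export
simulate_null_thresholds <- function(n_tall, n_dwarf,
                                     depths = seq(10, 200, by = 5),
                                     levels = c(0.95, 0.99),
                                     reps = 2000L) {
  if (reps < 1000L) stop("use at least 1000 replicates")
  qname <- paste0("q", round(levels * 100))
  out <- data.frame(depth = depths)
  for (q in qname) out[[q]] <- NA_real_
  for (i in seq_along(depths)) {
    d <- depths[i]
    freq_t <- 1 - stats::rbinom(reps, n_tall, 0.5) / (2 * n_tall)
    freq_d <- 1 - stats::rbinom(reps, n_dwarf, 0.5) / (2 * n_dwarf)
    idx_t <- stats::rbinom(reps, d, freq_t) / d
    idx_d <- stats::rbinom(reps, d, freq_d) / d
    delta <- idx_d - idx_t
    out[i, qname] <- stats::quantile(delta, probs = levels, names = FALSE)
  }
  # monotone non-increasing in depth: take the suffix maximum
  for (q in qname) out[[q]] <- rev(cummax(rev(out[[q]])))
  out
}

#' Attach per-SNP thresholds to a track
#'
#' Looks up each SNP's threshold at the smaller of its two bulk depths
#' (conservative), matched to the nearest tabulated depth.
#'
#' @param track data.frame with depth columns.
#' @param thresholds output of [simulate_null_thresholds()].
#' @param level confidence level to attach (must be tabulated).
#' @return `track` with a `threshold` column.
#' @export
assign_thresholds <- function(track, thresholds, level = 0.95) {
  qcol <- paste0("q", round(level * 100))
  if (!qcol %in% names(thresholds)) {
    stop("level ", level, " not tabulated in thresholds")
  }
  d <- pmin(track$M_tall + track$P_tall, track$M_dwarf + track$P_dwarf)
  nearest <- vapply(d, function(x) which.min(abs(thresholds$depth - x)), 1L)
  track$threshold <- thresholds[[qcol]][nearest]
  track
}

#' Call candidate intervals from a smoothed track
#'
#' Maximal runs of consecutive SNPs (in genome order, per chromosome) whose
#' smoothed delta is at or above their threshold; runs separated by at most
#' `merge_gap` bp are merged; merged runs supported by fewer than
#' `min_snps` SNPs are dropped. Interval endpoints are the first and last
#' supporting SNP positions (1-based inclusive).
#'
#' @param track data.frame with `delta_smooth` and `threshold` columns.
#' @param min_snps minimum supporting SNPs per interval.
#' @param merge_gap maximum bp gap across which runs merge.
#' @return data.frame `chrom`, `start`, `end`, `n_snps`, `peak_delta`
#'   (possibly zero rows).
#' @export
call_candidate_intervals <- function(track, min_snps = 10L, merge_gap = 1e5) {
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_snps = integer(),
                      peak_delta = numeric())
  out <- empty
  for (ch in unique(track$chrom)) {
    tr <- track[track$chrom == ch, ]
    tr <- tr[order(tr$pos), ]
    above <- !is.na(tr$delta_smooth) & !is.na(tr$threshold) &
      tr$delta_smooth >= tr$threshold
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(first = starts[r$values], last = ends[r$values])
    runs$start <- tr$pos[runs$first]
    runs$end <- tr$pos[runs$last]
    runs$n_snps <- runs$last - runs$first + 1L
    runs$peak <- vapply(seq_len(nrow(runs)), function(i) {
      max(tr$delta_smooth[runs$first[i]:runs$last[i]])
    }, numeric(1))
    # merge runs whose gap is within merge_gap
    merged <- runs[1, ]
    if (nrow(runs) > 1L) {
      for (i in 2:nrow(runs)) {
        j <- nrow(merged)
        if (runs$start[i] - merged$end[j] <= merge_gap) {
          merged$end[j] <- runs$end[i]
          merged$last[j] <- runs$last[i]
          merged$n_snps[j] <- merged$n_snps[j] + runs$n_snps[i]
          merged$peak[j] <- max(merged$peak[j], runs$peak[i])
        } else {
          merged <- rbind(merged, runs[i, ])
        }
      }
    }
    merged <- merged[merged$n_snps >= min_snps, , drop = FALSE]
    if (nrow(merged)) {
      out <- rbind(out, data.frame(chrom = ch, start = merged$start,
                                   end = merged$end, n_snps = merged$n_snps,
                                   peak_delta = merged$peak))
    }
  }
  rownames(out) <- NULL
  out
}

#' Total span of candidate intervals in Mb
#'
#' Computes the union of the intervals per chromosome, sums end - start
#' over the union, and reports megabases rounded half-up to 2 decimals.
#'
#' @param intervals data.frame with `chrom`, `start`, `end` in bp.
#' @return Total span in Mb (2 decimals).
#' @export
#' @examples
#' iv <- data.frame(chrom = "A01",
#'                  start = c(0, 6.45, 6.51, 6.77, 7.00) * 1e6,
#'                  end   = c(6.33, 6.48, 6.53, 6.79, 7.01) * 1e6)
#' total_interval_span(iv)  # 6.41
total_interval_span <- function(intervals) {
  if (nrow(intervals) == 0L) return(0)
  total <- 0
  for (ch in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == ch, ]
    iv <- iv[order(iv$start), ]
    cur_s <- iv$start[1]; cur_e <- iv$end[1]
    if (nrow(iv) > 1L) {
      for (i in 2:nrow(iv)) {
        if (iv$start[i] <= cur_e) {
          cur_e <- max(cur_e, iv$end[i])
        } else {
          total <- total + (cur_e - cur_s)
          cur_s <- iv$start[i]; cur_e <- iv$end[i]
        }
      }
    }
    total <- total + (cur_e - cur_s)
  }
  round_half_up(total / 1e6, 2)
}

#' Run the full BSA scan on a SNP record table
#'
#' Filter, index, smooth, simulate thresholds and call intervals in one
#' step. The threshold simulation draws from the current RNG stream; set a
#' seed first for reproducibility.
#'
#' @param snps SNP record data.frame.
#' @param rc a [run_config()].
#' @param n_tall,n_dwarf bulk sizes used for the null simulation.
#' @return List with `track` (smoothed, thresholded), `thresholds` (the
#'   per-depth table) and `intervals`.
#' @export
bsa_scan <- function(snps, n_tall, n_dwarf, rc = run_config()) {
  track <- filter_informative_snps(snps, rc$min_depth, rc$max_depth)
  track <- build_index_track(track)
  track <- smooth_delta(track, span = rc$span)
  thr <- simulate_null_thresholds(
    n_tall, n_dwarf,
    depths = seq(rc$min_depth, rc$max_depth, by = 5),
    levels = unique(c(rc$confidence, 0.99)),
    reps = rc$threshold_reps)
  track <- assign_thresholds(track, thr, level = rc$confidence)
  intervals <- call_candidate_intervals(track, min_snps = rc$min_snps,
                                        merge_gap = rc$merge_gap)
  list(track = track, thresholds = thr, intervals = intervals)
}
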
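test_that("SNP-index and delta follow their definitions", {
  expect_equal(compute_snp_index(10, 10), 0.5)
  expect_equal(compute_snp_index(7, 0), 1.0)
  expect_equal(compute_snp_index(3, 9), 0.25)
  expect_true(is.na(compute_snp_index(0, 0)))
  expect_error(compute_snp_index(-1, 5), ">= 0")
  expect_equal(compute_delta_index(1.0, 0.5), 0.5)
  expect_equal(compute_delta_index(0.5, 0.5), 0.0)
  expect_equal(compute_delta_index(0.2, 0.9), -0.7)
  expect_true(is.na(compute_delta_index(NA_real_, 0.5)))
})

test_that("informative-site filter keeps exactly the hand-enumerated rows", {
  tab <- data.frame(
    chrom = "c1", pos = 1:10 * 100,
    ref = c("A","A","A","A","A","A","A","A","A","A"),
    alt = c("T","T","T","T","T","T","T","T","T","A"),
    M_tall  = c(25, 0,  5, 60, 90, 40, 300, 12, 55, 30),
    P_tall  = c(25, 0,  4, 50, 20, 30, 200, 10, 45, 30),
    M_dwarf = c(30, 40, 20, 70,  3, 500, 40, 11, 60, 35),
    P_dwarf = c(30, 40, 20, 60,  4, 400, 40, 12, 50, 35)
  )
  # bounds (10, 100): row1 keep; row2 tall depth 0; row3 tall depth 9 < 10;
  # row4 dwarf depth 130 > 100; row5 dwarf depth 7 < 10; row6 dwarf 900 > 100;
  # row7 tall 500 > 100; row8 keep (22/23); row9 keep (100/110 -> dwarf 110 > 100? no:
  # 60+50 = 110 > 100 -> drop); row10 ref == alt -> drop
  kept <- filter_informative_snps(tab, 10, 100)
  expect_equal(kept$pos, c(100, 800))
  expect_error(filter_informative_snps(tab, 100, 10), "exceed")
})

test_that("loess smoothing reproduces constants and lines exactly", {
  n <- 40
  track <- data.frame(chrom = "c1", pos = seq(1e5, 4e6, length.out = n),
                      delta = 0.3)
  sm <- smooth_delta(track, span = 0.3)
  expect_equal(sm$delta_smooth, rep(0.3, n), tolerance = 1e-9)
  track$delta <- 0.1 + track$pos * 1e-7
  sm <- smooth_delta(track, span = 0.3)
  expect_equal(sm$delta_smooth, track$delta, tolerance = 1e-9)
})

test_that("loess fitted values equal the direct tricube WLS solve", {
  set.seed(21)
  n <- 20
  track <- data.frame(chrom = "c1", pos = sort(runif(n, 1e5, 5e6)),
                      delta = rnorm(n, 0, 0.2))
  for (span in c(0.35, 0.5)) {
    sm <- smooth_delta(track, span = span)
    oracle <- tricube_wls(track$pos, track$delta, span)
    expect_equal(sm$delta_smooth, oracle, tolerance = 1e-10)
  }
})

test_that("smoothing is per-chromosome and skips sparse chromosomes", {
  track <- data.frame(chrom = rep(c("c1", "c2"), c(30, 3)),
                      pos = c(seq(1e5, 3e6, length.out = 30),
                              c(1e5, 2e5, 3e5)),
                      delta = c(rep(0.5, 30), rep(-0.5, 3)))
  expect_warning(sm <- smooth_delta(track, span = 0.4), "c2")
  expect_equal(sm$delta_smooth[track$chrom == "c1"], rep(0.5, 30),
               tolerance = 1e-9)
  expect_true(all(is.na(sm$delta_smooth[track$chrom == "c2"])))
  # missing deltas propagate, never imputed
  track$delta[5] <- NA
  sm <- suppressWarnings(smooth_delta(track, span = 0.4))
  expect_true(is.na(sm$delta_smooth[5]))
})

test_that("null thresholds are centred, ordered and reproducible", {
  set.seed(22)
  thr <- simulate_null_thresholds(36, 40, depths = c(20, 50, 100),
                                  reps = 5000)
  expect_true(all(thr$q99 >= thr$q95))
  expect_true(all(diff(thr$q95) <= 0))   # monotone non-increasing in depth
  # re-simulation oracle: same sampling scheme, same seed, depth 50
  set.seed(99)
  thr1 <- simulate_null_thresholds(36, 40, depths = 50, reps = 10000)
  set.seed(99)
  freq_t <- 1 - rbinom(10000, 36, 0.5) / 72
  freq_d <- 1 - rbinom(10000, 40, 0.5) / 80
  idx_t <- rbinom(10000, 50, freq_t) / 50
  idx_d <- rbinom(10000, 50, freq_d) / 50
  delta <- idx_d - idx_t
  expect_lt(abs(mean(delta)), 3 * sd(delta) / sqrt(10000))  # null mean ~ 0
  expect_equal(thr1$q95, unname(quantile(delta, 0.95)), tolerance = 1e-12)
  expect_equal(thr1$q99, unname(quantile(delta, 0.99)), tolerance = 1e-12)
  expect_error(simulate_null_thresholds(36, 40, reps = 100), "1000")
})

test_that("interval calling honours thresholds, merging and support", {
  mk_track <- function(pos, sm, thr = 0.3) {
    data.frame(chrom = "c1", pos = pos, delta_smooth = sm, threshold = thr)
  }
  # nothing above threshold
  expect_equal(nrow(call_candidate_intervals(
    mk_track(1:20 * 1000, rep(0.1, 20)), min_snps = 2)), 0L)
  # 12 SNPs above threshold spanning positions 100..200 only
  pos <- c(seq(100, 200, length.out = 12), seq(10000, 20000, length.out = 8))
  sm <- c(rep(0.5, 12), rep(0.0, 8))
  iv <- call_candidate_intervals(mk_track(pos, sm), min_snps = 10,
                                 merge_gap = 50)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$start, 100)
  expect_equal(iv$end, 200)
  expect_equal(iv$n_snps, 12L)
  # two runs 50 kb apart (split by one sub-threshold SNP) merge under a
  # 100 kb gap
  pos <- c(seq(1e5, 1.1e5, length.out = 6), 1.35e5,
           seq(1.6e5, 1.7e5, length.out = 6))
  sm <- c(rep(0.5, 6), 0.0, rep(0.5, 6))
  merged <- call_candidate_intervals(mk_track(pos, sm), min_snps = 10,
                                     merge_gap = 1e5)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$n_snps, 12L)
  split <- call_candidate_intervals(mk_track(pos, sm), min_snps = 5,
                                    merge_gap = 1e4)
  expect_equal(nrow(split), 2L)
})

test_that("total span sums the interval union in Mb", {
  five <- data.frame(chrom = "A01",
                     start = c(0, 6.45, 6.51, 6.77, 7.00) * 1e6,
                     end   = c(6.33, 6.48, 6.53, 6.79, 7.01) * 1e6)
  expect_identical(total_interval_span(five), 6.41)
  expect_identical(total_interval_span(five[0, ]), 0)
  overlapping <- data.frame(chrom = "c1", start = c(0, 3e6), end = c(5e6, 8e6))
  expect_identical(total_interval_span(overlapping), 8.00)
})

test_that("swapping bulk labels negates delta exactly", {
  cfg <- sim_config(seed = 23, n_plants = 150, n_tall = 8, n_dwarf = 8)
  g <- toy_genome(positions1 = seq(1e5, 3e6, by = 1e5))
  ex <- simulate_bsa_experiment(cfg, genome = g)
  tr <- build_index_track(ex$snps)
  swapped <- ex$snps
  swapped[, c("M_tall", "P_tall", "M_dwarf", "P_dwarf")] <-
    swapped[, c("M_dwarf", "P_dwarf", "M_tall", "P_tall")]
  tr2 <- build_index_track(swapped)
  expect_equal(tr2$delta, -tr$delta)
  # index and delta bounds hold everywhere
  ok <- !is.na(tr$delta)
  expect_true(all(tr$snp_index_tall[ok] >= 0 & tr$snp_index_tall[ok] <= 1))
  expect_true(all(tr$delta[ok] >= -1 & tr$delta[ok] <= 1))
})
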
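test_that("gene-interval overlap follows the 1 bp any-overlap rule", {
  genes <- data.frame(gene_id = c("a", "b", "c"),
                      chrom = "A01",
                      start = c(100, 400, 300),
                      end = c(200, 500, 350))
  iv <- data.frame(chrom = "A01", start = 50, end = 300)
  res <- intersect_genes_intervals(genes, iv)
  expect_setequal(res$genes, c("a", "c"))  # c touches by exactly 1 bp
  # start-within rule excludes the boundary gene
  res2 <- intersect_genes_intervals(genes, iv, rule = "start_within")
  expect_setequal(res2$genes, c("a", "c"))  # c starts at 300, inside
  iv2 <- data.frame(chrom = "A01", start = 50, end = 299)
  expect_setequal(intersect_genes_intervals(genes, iv2)$genes, "a")
  expect_warning(
    out <- intersect_genes_intervals(genes,
                                     data.frame(chrom = "Z9", start = 1,
                                                end = 1e6)),
    "chromosome")
  expect_length(out$genes, 0)
})

test_that("overlap assignment matches a brute-force all-pairs scan", {
  set.seed(51)
  genes <- data.frame(gene_id = sprintf("g%03d", 1:200),
                      chrom = sample(c("c1", "c2"), 200, replace = TRUE),
                      start = sample.int(1e6, 200))
  genes$end <- genes$start + sample.int(5000, 200)
  iv <- data.frame(chrom = c("c1", "c1", "c2"),
                   start = c(1e5, 6e5, 3e5), end = c(3e5, 7e5, 9e5))
  res <- intersect_genes_intervals(genes, iv)
  for (i in seq_len(nrow(iv))) {
    brute <- genes$gene_id[genes$chrom == iv$chrom[i] &
                             genes$end >= iv$start[i] &
                             genes$start <= iv$end[i]]
    expect_setequal(res$per_interval[[i]], brute)
  }
  expect_setequal(res$genes, unique(unlist(res$per_interval)))
})

test_that("percentages round half-up to two decimals", {
  expect_identical(percent(542, 1256), 43.15)
  expect_identical(percent(538, 542), 99.26)
  expect_identical(percent(0, 10), 0)
  expect_identical(percent(1, 800), 0.13)  # 0.125 rounds up
  expect_error(percent(1, 0), "positive")
  # complement identity within rounding
  set.seed(52)
  for (i in 1:20) {
    b <- sample(1:2000, 1)
    a <- sample(0:b, 1)
    expect_lt(abs(percent(a, b) + percent(b - a, b) - 100), 0.011)
  }
})

test_that("direction tallies count statuses per interval and overall", {
  de <- data.frame(gene_id = sprintf("g%02d", 1:12),
                   status = c(rep("up", 7), rep("down", 3), "ns", "filtered"))
  assoc <- list(per_interval = list(sprintf("g%02d", 1:10),
                                    sprintf("g%02d", 11:12),
                                    character(0)),
                genes = sprintf("g%02d", 1:12))
  out <- tally_direction(de, assoc)
  expect_equal(out$per_interval$up, c(7, 0, 0))
  expect_equal(out$per_interval$down, c(3, 0, 0))
  expect_equal(out$per_interval$up_percent, c(70, NA, NA))
  expect_equal(out$overall$degs, 10)
  expect_equal(out$overall$up_percent, 70)
  all_up <- tally_direction(transform(de, status = "up"), assoc)
  expect_equal(all_up$overall$down, 0)
  expect_equal(all_up$overall$up_percent, 100)
})

test_that("the configured direction skew is recovered inside the region", {
  cfg <- sim_config(seed = 53)
  sc <- simulate_counts(cfg)
  res <- run_de_pipeline(sc$counts, sc$gene_models$length, sc$groups)
  region <- data.frame(chrom = "A01", start = 1, end = 6.33e6)
  assoc <- intersect_genes_intervals(sc$gene_models, region)
  tal <- tally_direction(res$de, assoc)
  expect_gt(tal$overall$degs, 10)          # the region holds called DEGs
  expect_gt(tal$overall$up_percent, 80)    # and they skew up in dwarf
})

test_that("hypergeometric enrichment equals exhaustive enumeration", {
  universe <- letters[1:10]
  sets <- list(s1 = letters[1:5])
  hits <- letters[c(1:4)]
  res <- hypergeometric_enrichment(hits, sets, universe)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$p, hyper_enum(10, 5, 4, 4), tolerance = 1e-12)
  # empty set, zero overlap
  res0 <- hypergeometric_enrichment(hits, list(empty = character(0)), universe)
  expect_equal(res0$p, 1)
  # random configurations over a small universe
  set.seed(54)
  for (i in 1:5) {
    N <- sample(8:15, 1)
    uni <- as.character(seq_len(N))
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    hits_i <- sample(uni, n)
    sets_i <- list(s = uni[seq_len(K)])
    k <- length(intersect(hits_i, sets_i$s))
    res_i <- hypergeometric_enrichment(hits_i, sets_i, uni)
    expect_equal(res_i$p, hyper_enum(N, K, n, k), tolerance = 1e-10)
  }
  expect_error(hypergeometric_enrichment(c("zz"), sets, universe), "universe")
  expect_error(hypergeometric_enrichment(hits, list(bad = "zz"), universe),
               "contained")
})
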
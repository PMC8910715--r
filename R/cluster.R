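#' K-means clustering of DEG expression profiles
#'
#' Clusters per-gene z-score profiles (log-FPKM standardised across the six
#' samples) with Euclidean K-means. Centres are seeded by k-means++ and
#' refined by Lloyd iterations (`stats::kmeans`); the best of `restarts`
#' runs by total within-cluster sum of squares is kept. Clusters are then
#' relabelled 1..k by decreasing mean (dwarf - tall) profile difference, so
#' low labels are the clusters up-regulated in dwarf and the numbering is
#' deterministic.
#'
#' @param profiles genes x samples numeric matrix (z-scored rows).
#' @param groups per-column group labels ("tall"/"dwarf").
#' @param k number of clusters (default 6).
#' @param seed RNG seed for the restarts.
#' @param restarts number of k-means++ restarts (default 10).
#' @return List of class `kmeans_clusters`: `cluster` (named vector of
#'   labels 1..k), `sizes` (table), `centers` (k x samples matrix).
#' @export
kmeans_cluster <- function(profiles, groups, k = 6L, seed = 1L,
                           restarts = 10L) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < k) stop("fewer genes than clusters")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- profiles[kmeanspp_indices(profiles, k), , drop = FALSE]
    km <- suppressWarnings(
      stats::kmeans(profiles, centers = centers, iter.max = 100L,
                    algorithm = "Lloyd"))
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  # deterministic relabelling: decreasing dwarf-minus-tall centre contrast
  contrast <- rowMeans(best$centers[, groups == "dwarf", drop = FALSE]) -
    rowMeans(best$centers[, groups == "tall", drop = FALSE])
  ord <- order(contrast, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  cluster <- relabel[best$cluster]
  names(cluster) <- rownames(profiles)
  structure(list(cluster = cluster,
                 sizes = table(factor(cluster, levels = seq_len(k))),
                 centers = best$centers[ord, , drop = FALSE]),
            class = "kmeans_clusters")
}

# k-means++ seeding: first centre uniform, later centres with probability
# proportional to squared distance from the nearest chosen centre
kmeanspp_indices <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[idx[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      idx[j] <- sample.int(n, 1L)
    } else {
      idx[j] <- sample.int(n, 1L, prob = d2)
    }
    dj <- rowSums((x - matrix(x[idx[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  idx
}

#' Z-scored log-FPKM profiles of a gene set
#'
#' @param fpkm genes x samples FPKM matrix.
#' @param genes gene ids (rows) to keep.
#' @return Matrix of per-row z-scores of log2(FPKM + 1); rows with zero
#'   variance are dropped.
#' @export
zscore_profiles <- function(fpkm, genes) {
  x <- log2(fpkm[genes, , drop = FALSE] + 1)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  keep <- sd > 0
  (x[keep, , drop = FALSE] - mu[keep]) / sd[keep]
}
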
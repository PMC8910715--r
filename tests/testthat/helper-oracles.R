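# Independent oracles and small fixture builders shared across tests.
# Each oracle is a direct transcription of the underlying formula or an
# exhaustive enumeration, kept free of the package's own code paths.

# Tricube-weighted local linear fit at every point: the textbook loess
# computation with a neighbourhood of floor(span * n) points.
tricube_wls <- function(x, y, span) {
  n <- length(x)
  q <- floor(span * n)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    w <- pmax(0, 1 - (d / h)^3)^3
    X <- cbind(1, x - x[i])
    solve(crossprod(X, w * X), crossprod(X, w * y))[1]
  }, numeric(1))
}

# Step-up Benjamini-Hochberg by enumeration of the definition.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  pmin(adj, 1)[order(o)]
}

# Welch t with Satterthwaite df, straight from the formulas.
welch_formula <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# draws of size n from a universe of size N containing K marked items.
hyper_enum <- function(N, K, n, k) {
  draws <- combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# Minimal two-chromosome genome for unit tests; causal on the first
# marker so every toy individual is phenotypable.
toy_genome <- function(positions1 = c(1e5, 2e5, 3e5),
                       positions2 = numeric(0),
                       rate = 2) {
  chroms <- data.frame(chrom = "c1", length = max(positions1) + 1e5)
  markers <- data.frame(chrom = "c1", pos = positions1)
  if (length(positions2)) {
    chroms <- rbind(chroms,
                    data.frame(chrom = "c2", length = max(positions2) + 1e5))
    markers <- rbind(markers, data.frame(chrom = "c2", pos = positions2))
  }
  genome_model(chroms, markers, rate = rate,
               causal = list(chrom = "c1", pos = positions1[1]))
}
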
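# Independent brute-force oracles used to validate the analysis stack.
# These deliberately use naive loops / exhaustive enumeration, never the
# code paths (or vectorized shortcuts) they check.

# Benjamini-Hochberg step-up adjustment by its definition: the adjusted
# value of the i-th smallest p is min over j >= i of n * p_(j) / j, capped
# at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    m <- Inf
    for (j in i:n) m <- min(m, n * ps[j] / j)
    adj[i] <- min(1, m)
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Upper-tail hypergeometric probability by term-wise enumeration.
hyper_tail_oracle <- function(k, K, N, n) {
  if (k > min(K, n)) return(0)
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# Running-sum enrichment score, position-by-position.
es_oracle <- function(scores_sorted, hit_sorted, weight_p) {
  N <- length(scores_sorted)
  NH <- sum(hit_sorted)
  NR <- sum(abs(scores_sorted[hit_sorted])^weight_p)
  rs <- 0
  best <- 0
  for (i in seq_len(N)) {
    if (hit_sorted[i]) rs <- rs + abs(scores_sorted[i])^weight_p / NR
    else rs <- rs - 1 / (N - NH)
    if (abs(rs) > abs(best)) best <- rs
  }
  unname(best)
}

# UPGMA merge heights: repeatedly merge the cluster pair with the smallest
# mean original leaf-to-leaf distance. Returns the n-1 merge heights in
# merge order.
upgma_heights_oracle <- function(D) {
  D <- as.matrix(D)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf; bi <- NA; bj <- NA
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Final candidate order by direct double-loop competition ranking.
rank_order_oracle <- function(df) {
  comp <- function(x) vapply(x, function(v) sum(x > v) + 1L, integer(1))
  rs <- comp(df$internal_degree) + comp(df$modifier_degree) + comp(df$log2fc)
  df$gene_id[order(rs, -df$log2fc, df$gene_id)]
}

# Small labelled expression matrix for hand-arithmetic tests. A plain
# vector fills a genes x samples matrix column by column; the default is
# 3 genes and as many samples as the length allows.
make_expr <- function(values, genes = sprintf("g%d", 1:3),
                      samples = NULL, detection_p = NULL) {
  n_samp <- length(values) / length(genes)
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(n_samp))
  v <- matrix(values, nrow = length(genes), dimnames = list(genes, samples))
  expression_matrix(v, detection_p)
}
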
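#' Informative-probe filter
#'
#' Removes genes whose detection p-value exceeds the threshold in ALL
#' samples, keeping exactly the probes detected (p <= threshold) in at least
#' one sample — the informative-probe universe used downstream for
#' enrichment testing.
#'
#' @param x an [expression_matrix()] carrying detection p-values.
#' @param p_thresh detection p-value threshold (default 0.01).
#' @return Filtered [expression_matrix()].
#' @export
filter_informative <- function(x, p_thresh = 0.01) {
  if (is.null(x$detection_p))
    stop("detection p-values are required for informative-probe filtering")
  keep <- rowSums(x$detection_p <= p_thresh) >= 1
  expression_matrix(x$values[keep, , drop = FALSE],
                    x$detection_p[keep, , drop = FALSE])
}

#' Between-sample quantile normalization
#'
#' Optionally log2-transforms linear-scale intensities, then quantile
#' normalizes across samples so every sample shares the identical sorted
#' value distribution (the rank-based between-array normalization standing
#' in for robust-spline normalization).
#'
#' @param x an [expression_matrix()].
#' @param linear_scale if `TRUE`, values are linear intensities and are
#'   log2-transformed first (must be strictly positive).
#' @return Normalized [expression_matrix()] (detection p-values carried
#'   through unchanged).
#' @export
normalize_expression <- function(x, linear_scale = FALSE) {
  v <- x$values
  if (linear_scale) {
    if (any(v <= 0)) stop("linear-scale values must be strictly positive")
    v <- log2(v)
  }
  if (ncol(v) > 1) v <- limma::normalizeQuantiles(v)
  dimnames(v) <- dimnames(x$values)
  expression_matrix(v, x$detection_p)
}

#' Two-group differential expression with fold-change and FDR gates
#'
#' Per-gene Welch two-sample t-test on log2 intensities, Benjamini-Hochberg
#' adjustment across all tested genes, and a significance call requiring
#' both |log2fc| >= log2(fc_thresh) and FDR <= fdr_thresh. Genes with zero
#' variance in both groups and equal means get p = 1.
#'
#' @param groupA,groupB [expression_matrix()] objects (or plain matrices)
#'   with identical gene sets and >= 2 samples each.
#' @param fc_thresh fold-change threshold on the linear scale (default 2).
#' @param fdr_thresh BH-adjusted p-value threshold (default 0.05).
#' @return Data frame with gene_id, log2fc (B minus A), p_value, fdr,
#'   significant.
#' @export
differential_expression <- function(groupA, groupB, fc_thresh = 2,
                                    fdr_thresh = 0.05) {
  va <- if (inherits(groupA, "expression_matrix")) groupA$values else as.matrix(groupA)
  vb <- if (inherits(groupB, "expression_matrix")) groupB$values else as.matrix(groupB)
  if (!identical(rownames(va), rownames(vb)))
    stop("gene sets must be identical between groups")
  if (ncol(va) < 2 || ncol(vb) < 2)
    stop("each group needs at least 2 samples")
  welch <- welch_t(va, vb)
  fdr <- stats::p.adjust(welch$p, method = "BH")
  lfc <- rowMeans(vb) - rowMeans(va)
  data.frame(gene_id = rownames(va),
             log2fc = unname(lfc),
             p_value = unname(welch$p),
             fdr = unname(fdr),
             significant = unname(abs(lfc) >= log2(fc_thresh) & fdr <= fdr_thresh),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Vectorized Welch t-test over matrix rows (two-sided).
welch_t <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (mb - ma) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # degenerate: no variance anywhere; equal means => no evidence
  degen <- se2 == 0
  p[degen & ma == mb] <- 1
  p[degen & ma != mb] <- 0
  list(t = tstat, df = df, p = p)
}

#' Average-linkage clustering of samples on correlation distance
#'
#' Agglomerative (UPGMA) clustering of SAMPLES with pairwise distance
#' d(i, j) = 1 - Pearson correlation of their expression profiles.
#'
#' @param x an [expression_matrix()] (or plain matrix) with >= 2 samples,
#'   each with positive variance.
#' @return An object of class `hclust`.
#' @export
hierarchical_cluster <- function(x) {
  v <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
  if (ncol(v) < 2) stop("need at least 2 samples")
  if (any(apply(v, 2, stats::sd) == 0))
    stop("zero-variance sample: correlation distance undefined")
  d <- stats::as.dist(1 - stats::cor(v))
  stats::hclust(d, method = "average")
}

#' Write a cluster tree in Newick format
#' @param hc an `hclust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cluster_tree <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation test
#'
#' Upper-tail hypergeometric probability P(X >= k) of observing k or more
#' significant genes in a term, with the informative-probe universe as the
#' sampling frame; BH adjustment across all tested terms. Gene sets are
#' intersected with the universe before testing.
#'
#' @param significant character vector of significant gene ids (subset of
#'   `universe`).
#' @param universe character vector, the informative-probe universe.
#' @param gene_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @return Data frame with term, k, K, n, N, p_value, fdr (one row per
#'   tested term).
#' @export
hypergeom_enrich <- function(significant, universe, gene_sets) {
  if (length(universe) == 0) stop("universe must be non-empty")
  universe <- unique(universe)
  significant <- unique(significant)
  if (!all(significant %in% universe))
    stop("significant genes must be a subset of the universe")
  N <- length(universe)
  n <- length(significant)
  rows <- lapply(names(gene_sets), function(nm) {
    term <- intersect(gene_sets[[nm]], universe)
    K <- length(term)
    k <- length(intersect(term, significant))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = nm, k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Running-sum gene-set enrichment with permutation normalization
#'
#' Classic weighted Kolmogorov-Smirnov-style enrichment: genes are ordered
#' by decreasing score; hits increment the running sum by
#' |score|^weight_p (normalized to total 1 over hits) and misses decrement
#' by 1 / (N - |S|); ES is the maximum deviation from zero. NES divides ES
#' by the mean |ES| of same-sign gene-set-label permutations, and the FDR
#' is the same-sign permutation tail probability.
#'
#' @param scores named numeric vector of ranking scores (names are gene
#'   ids); ties keep input order.
#' @param gene_set character vector; must intersect the scored genes.
#' @param n_perm number of gene-label permutations (>= 10).
#' @param weight_p score-weighting exponent (default 1; 0 gives the
#'   unweighted statistic).
#' @param seed integer seed for the permutations.
#' @return A one-row data frame with es, nes, fdr, n_hits, n_perm, seed.
#' @export
gsea <- function(scores, gene_set, n_perm = 1000, weight_p = 1, seed = 1L) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  if (is.null(names(scores))) stop("scores must be named by gene id")
  if (any(!is.finite(scores))) stop("scores must be finite")
  hit <- names(scores) %in% gene_set
  if (!any(hit)) stop("gene_set is disjoint from the ranked genes")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  h <- hit[ord]
  es <- running_sum_es(s, h, weight_p)
  nh <- sum(h)
  set.seed(seed)
  perm_es <- vapply(seq_len(n_perm), function(i) {
    hp <- logical(length(s))
    hp[sample(length(s), nh)] <- TRUE
    running_sum_es(s, hp, weight_p)
  }, numeric(1))
  same <- perm_es[sign(perm_es) == sign(es)]
  nes <- if (length(same) > 0) es / mean(abs(same)) else NA_real_
  fdr <- if (length(same) > 0) mean(abs(same) >= abs(es)) else 0
  data.frame(es = es, nes = nes, fdr = fdr, n_hits = nh,
             n_perm = n_perm, seed = seed)
}

# ES of one ordered hit indicator: signed maximum deviation of the running
# sum (vectorized cumulative form).
running_sum_es <- function(s, h, weight_p) {
  n <- length(s)
  nh <- sum(h)
  if (nh == n) return(1)
  w <- abs(s)^weight_p
  inc <- ifelse(h, w, 0)
  tot <- sum(inc)
  step <- if (tot > 0) inc / tot else ifelse(h, 1 / nh, 0)
  step <- step - ifelse(h, 0, 1 / (n - nh))
  rs <- cumsum(step)
  unname(rs[which.max(abs(rs))])
}

#' Principal-coordinate analysis of samples
#'
#' Classical metric multidimensional scaling of samples under Euclidean
#' distance over genes: eigendecomposition of the double-centered squared
#' distance matrix, giving centered coordinates whose pairwise distances
#' reproduce the input distances for embeddable configurations.
#'
#' @param x an [expression_matrix()] or plain matrix (genes x samples), or
#'   a `dist` over samples.
#' @param n_components number of coordinates to retain (default 3).
#' @return List with `coordinates` (samples x components, centered columns)
#'   and `variance_fraction` (per retained component, from the positive
#'   eigenvalues).
#' @export
pcoa <- function(x, n_components = 3) {
  d <- if (inherits(x, "dist")) x else {
    v <- if (inherits(x, "expression_matrix")) x$values else as.matrix(x)
    stats::dist(t(v))
  }
  n <- attr(d, "Size")
  if (n < n_components + 1)
    stop("need at least n_components + 1 samples")
  fit <- suppressWarnings(stats::cmdscale(d, k = n_components, eig = TRUE))
  # retain only components backed by meaningfully positive eigenvalues;
  # near-zero eigenvalues contribute numerical noise, not geometry
  keep <- which(fit$eig[seq_len(ncol(fit$points))] > max(fit$eig) * 1e-8)
  coords <- fit$points[, keep, drop = FALSE]
  vf <- fit$eig[keep] / sum(fit$eig[fit$eig > 0])
  list(coordinates = coords, variance_fraction = vf)
}

#' Venn-partition counts over named differential-expression sets
#'
#' @param lists named list (>= 2 entries) of identifier vectors.
#' @return List with `regions` (data frame: membership pattern and count for
#'   every non-empty region of the Venn partition), `common` (size of the
#'   intersection of all sets) and `total` (size of the union).
#' @export
de_overlap <- function(lists) {
  if (length(lists) < 2) stop("need at least 2 named sets")
  if (is.null(names(lists)) || any(names(lists) == ""))
    stop("sets must be named")
  lists <- lapply(lists, unique)
  all_ids <- unique(unlist(lists))
  memb <- vapply(lists, function(s) all_ids %in% s, logical(length(all_ids)))
  if (length(all_ids) == 1) memb <- matrix(memb, nrow = 1,
                                           dimnames = list(NULL, names(lists)))
  pattern <- apply(memb, 1, function(r) paste(names(lists)[r], collapse = "&"))
  counts <- table(pattern)
  regions <- data.frame(region = names(counts),
                        count = as.integer(counts),
                        stringsAsFactors = FALSE)
  list(regions = regions,
       common = sum(rowSums(memb) == length(lists)),
       total = length(all_ids))
}

#' Read and write GMT gene-set files
#'
#' Standard tab-separated layout: set name, description, then member ids.
#'
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors with a
#'   `description` attribute per set.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop(sprintf("malformed GMT line: %s", l))
    structure(f[-(1:2)], description = f[2])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute).
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- "na"
    paste(c(nm, desc, as.character(sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
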
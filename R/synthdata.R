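#' Simulation configuration for the forward-programming screen
#'
#' Bundles the parameters of the synthetic two-condition expression
#' experiment that emulates a pluripotent-source versus megakaryocyte-target
#' array contrast: a planted subset of upregulated DNA-binding genes at a
#' stated log2 effect, decoy DNA-binding genes at a moderate effect, Gaussian
#' replicate noise on the log2 scale, and a fraction of undetected probes.
#'
#' @param n_genes total genes simulated.
#' @param n_tf_genes genes flagged as DNA-binding (a superset of the planted
#'   and decoy genes).
#' @param n_planted planted strongly upregulated DNA-binding genes: the
#'   ground-truth cocktail candidates.
#' @param planted_log2fc log2 effect added to planted genes in the target
#'   group (log2 units).
#' @param n_decoy DNA-binding genes given a moderate upregulation
#'   (`decoy_log2fc`) so that selection is exercised by genes that pass the
#'   fold-change screen but carry no planted network support.
#' @param decoy_log2fc log2 effect for decoy genes.
#' @param n_histone genes flagged as histone-coding (removed at curation).
#' @param reps_per_group replicate arrays per condition (>= 2).
#' @param noise_sd replicate noise standard deviation, log2 units.
#' @param baseline_mean baseline log2 intensity.
#' @param frac_undetected fraction of non-planted genes whose detection
#'   p-values exceed the informative-probe threshold in every sample.
#' @param n_modifiers chromatin-modifier genes (acetyltransferase /
#'   deacetylase / DNA-methyltransferase stand-ins) added as network nodes.
#' @param internal_edges_per_planted planted candidate-candidate edges per
#'   planted gene.
#' @param modifier_edges_per_planted planted candidate-modifier edges per
#'   planted gene.
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_tf_genes = 150,
                       n_planted = 10,
                       planted_log2fc = 3,
                       n_decoy = 12,
                       decoy_log2fc = 1.5,
                       n_histone = 10,
                       reps_per_group = 4,
                       noise_sd = 0.3,
                       baseline_mean = 8,
                       frac_undetected = 0.1,
                       n_modifiers = 15,
                       internal_edges_per_planted = 3,
                       modifier_edges_per_planted = 2,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$n_planted + cfg$n_decoy > cfg$n_tf_genes)
    stop("n_planted + n_decoy must not exceed n_tf_genes")
  if (cfg$n_tf_genes + cfg$n_histone > cfg$n_genes)
    stop("n_tf_genes + n_histone must not exceed n_genes")
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$reps_per_group < 2) stop("reps_per_group must be >= 2")
  if (cfg$frac_undetected < 0 || cfg$frac_undetected > 1)
    stop("frac_undetected must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic two-condition expression experiment
#'
#' Draws source and target log2 intensity matrices with independent Gaussian
#' noise, plants the configured upregulated DNA-binding genes in the target
#' group, flags histone genes, and records the ground truth (planted genes
#' plus the planted network edges used later by [gen_network()]).
#' Histone-flagged genes are drawn outside the DNA-binding set here; the
#' curation step removes them regardless of their DNA-binding status.
#'
#' @param config a [sim_config()].
#' @return A list with elements `source` and `target` (both
#'   [expression_matrix()] with detection p-values), `annotation` (data frame
#'   with gene_id, symbol, is_dna_binding, is_histone) and `truth` (list with
#'   planted_genes, decoy_genes, modifier_genes, planted_internal_edges,
#'   planted_modifier_edges).
#' @export
gen_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with(config, {
    set.seed(seed)
    ids <- sprintf("G%04d", seq_len(n_genes))
    tf_ids <- ids[seq_len(n_tf_genes)]
    planted <- tf_ids[seq_len(n_planted)]
    decoys <- if (n_decoy > 0) tf_ids[n_planted + seq_len(n_decoy)] else character(0)
    histones <- if (n_histone > 0) ids[n_tf_genes + seq_len(n_histone)] else character(0)
    samp_src <- sprintf("src_%d", seq_len(reps_per_group))
    samp_tgt <- sprintf("tgt_%d", seq_len(reps_per_group))

    base <- stats::rnorm(n_genes, baseline_mean, 1.5)
    draw <- function(n_samp) {
      matrix(stats::rnorm(n_genes * n_samp, 0, noise_sd), n_genes, n_samp) + base
    }
    src <- draw(reps_per_group)
    tgt <- draw(reps_per_group)
    tgt[match(planted, ids), ] <- tgt[match(planted, ids), ] + planted_log2fc
    if (n_decoy > 0)
      tgt[match(decoys, ids), ] <- tgt[match(decoys, ids), ] + decoy_log2fc
    dimnames(src) <- list(ids, samp_src)
    dimnames(tgt) <- list(ids, samp_tgt)

    # undetected probes: high detection p in every sample of both conditions
    eligible <- setdiff(ids, c(planted, decoys))
    n_und <- round(frac_undetected * n_genes)
    undetected <- if (n_und > 0) sample(eligible, min(n_und, length(eligible))) else character(0)
    det_p <- function(n_samp) {
      dp <- matrix(stats::runif(n_genes * n_samp, 0, 0.005), n_genes, n_samp)
      dp[match(undetected, ids), ] <- stats::runif(length(undetected) * n_samp, 0.5, 1)
      dp
    }
    dp_src <- det_p(reps_per_group); dimnames(dp_src) <- dimnames(src)
    dp_tgt <- det_p(reps_per_group); dimnames(dp_tgt) <- dimnames(tgt)

    modifiers <- if (n_modifiers > 0) sprintf("MOD%02d", seq_len(n_modifiers)) else character(0)
    internal_edges <- plant_ring_edges(planted, internal_edges_per_planted)
    modifier_edges <- plant_modifier_edges(planted, modifiers,
                                           modifier_edges_per_planted)

    annotation <- data.frame(
      gene_id = ids,
      symbol = ids,
      is_dna_binding = ids %in% tf_ids,
      is_histone = ids %in% histones,
      stringsAsFactors = FALSE
    )
    truth <- list(planted_genes = planted,
                  decoy_genes = decoys,
                  modifier_genes = modifiers,
                  planted_internal_edges = internal_edges,
                  planted_modifier_edges = modifier_edges)
    list(source = expression_matrix(src, dp_src),
         target = expression_matrix(tgt, dp_tgt),
         annotation = annotation,
         truth = truth)
  })
}

# Connect each planted gene to its k nearest neighbours on a ring: a simple
# deterministic pattern giving every planted gene internal degree >= k.
plant_ring_edges <- function(planted, k) {
  n <- length(planted)
  if (n < 2 || k < 1) return(empty_edges())
  k <- min(k, n - 1)
  pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
    j <- ((i - 1 + seq_len(k)) %% n) + 1
    cbind(planted[i], planted[j])
  }))
  canonical_edges(pairs[, 1], pairs[, 2])
}

plant_modifier_edges <- function(planted, modifiers, k) {
  if (length(planted) == 0 || length(modifiers) == 0 || k < 1)
    return(empty_edges())
  k <- min(k, length(modifiers))
  pairs <- do.call(rbind, lapply(seq_along(planted), function(i) {
    j <- ((i - 1 + seq_len(k) - 1) %% length(modifiers)) + 1
    cbind(planted[i], modifiers[j])
  }))
  canonical_edges(pairs[, 1], pairs[, 2])
}

empty_edges <- function() {
  data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE)
}

# Canonical undirected simple edge list: from < to, no self-loops, no
# duplicates regardless of orientation.
canonical_edges <- function(a, b) {
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  df <- data.frame(from = pmin(a, b), to = pmax(a, b),
                   stringsAsFactors = FALSE)
  df <- unique(df)
  df[order(df$from, df$to), , drop = FALSE]
}

#' Undirected interaction network over gene symbols
#'
#' @param edges two-column data frame (or matrix) of undirected edges; edges
#'   are canonicalized, self-loops dropped and duplicates merged.
#' @param modifiers character vector of chromatin-modifier gene symbols.
#' @return An `interaction_network` with canonical `edges` and `modifiers`.
#' @export
interaction_network <- function(edges, modifiers = character(0)) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) > 0 && ncol(edges) < 2)
    stop("edges must have two columns")
  ed <- if (nrow(edges) == 0) empty_edges() else
    canonical_edges(as.character(edges[[1]]), as.character(edges[[2]]))
  rownames(ed) <- NULL
  structure(list(edges = ed, modifiers = unique(as.character(modifiers))),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d edges, %d modifier genes\n",
              nrow(x$edges), length(x$modifiers)))
  invisible(x)
}

#' Generate a background interaction network around planted edges
#'
#' Starts from the planted candidate-candidate and candidate-modifier edges
#' in `truth` and adds Erdos-Renyi background edges: every other unordered
#' node pair is included independently with probability `p_background`.
#' Nodes are all annotated genes plus the modifier genes.
#'
#' @param annotation annotation data frame (needs `gene_id`).
#' @param truth truth list from [gen_expression()] (planted edge sets).
#' @param modifier_genes modifier symbols (defaults to the truth's set).
#' @param p_background background edge probability in \[0, 1\].
#' @param seed integer seed.
#' @return An [interaction_network()].
#' @export
gen_network <- function(annotation, truth,
                        modifier_genes = truth$modifier_genes,
                        p_background = 0.005, seed = 1L) {
  if (p_background < 0 || p_background > 1)
    stop("p_background must lie in [0, 1]")
  nodes <- unique(c(annotation$gene_id, modifier_genes))
  planted <- rbind(truth$planted_internal_edges, truth$planted_modifier_edges)
  set.seed(seed)
  bg <- sample_er_edges(nodes, p_background)
  net <- interaction_network(rbind(planted, bg), modifier_genes)
  # planted edges must survive canonicalization
  stopifnot(nrow(merge(net$edges, canonical_edges(planted$from, planted$to))) ==
              nrow(unique(canonical_edges(planted$from, planted$to))))
  net
}

# Sample Erdos-Renyi G(n, p) edges without materializing all C(n, 2) pairs:
# draw the binomial edge count, sample that many distinct pair indices, and
# unrank each index to its (i, j) node pair.
sample_er_edges <- function(nodes, p) {
  n <- length(nodes)
  n_pairs <- n * (n - 1) / 2
  if (n < 2 || p == 0) return(empty_edges())
  m <- if (p >= 1) n_pairs else stats::rbinom(1, n_pairs, p)
  if (m == 0) return(empty_edges())
  idx <- if (p >= 1) seq_len(n_pairs) else sort(sample(n_pairs, m))
  ij <- unrank_pair(idx, n)
  canonical_edges(nodes[ij[, 1]], nodes[ij[, 2]])
}

# Pair index k in 1..C(n,2) enumerates (1,2),(1,3),...,(1,n),(2,3),...
unrank_pair <- function(k, n) {
  r <- n * (n - 1) / 2 - k          # pairs strictly after k
  t <- floor((sqrt(8 * r + 1) - 1) / 2)
  i <- n - 1 - t
  j <- n - (r - t * (t + 1) / 2)
  cbind(i = i, j = j)
}

#' Generate a synthetic platelet survival series
#'
#' Counts decay exponentially from the first (equilibrium) time point with
#' multiplicative log-normal noise, emulating post-transfusion absolute
#' platelet counts measured by flow cytometry.
#'
#' @param true_half_life half-life in hours (> 0).
#' @param n0 count at the equilibrium (first) time point (> 0).
#' @param time_points ascending times in hours; the first is the equilibrium
#'   reference.
#' @param noise_sd standard deviation of the log-scale noise (0 = exact).
#' @param seed integer seed.
#' @return A data frame with columns `time_h` and `count`.
#' @export
gen_survival <- function(true_half_life, n0, time_points,
                         noise_sd = 0.05, seed = 1L) {
  if (true_half_life <= 0) stop("true_half_life must be > 0")
  if (n0 <= 0) stop("n0 must be > 0")
  if (is.unsorted(time_points, strictly = TRUE))
    stop("time_points must be strictly ascending")
  set.seed(seed)
  t0 <- time_points[1]
  mu <- n0 * 2^(-(time_points - t0) / true_half_life)
  counts <- mu * exp(stats::rnorm(length(time_points), 0, noise_sd))
  data.frame(time_h = time_points, count = counts)
}

#' Generate a synthetic cytometry event table
#'
#' Multinomial draw of `n_events` events over labelled classes with the
#' given probabilities; counts always sum exactly to `n_events`.
#'
#' @param n_events total events.
#' @param class_probs named numeric vector of class probabilities summing
#'   to 1 (within 1e-9).
#' @param seed integer seed.
#' @return A data frame with columns `label` and `count`.
#' @export
gen_cytometry <- function(n_events, class_probs, seed = 1L) {
  if (is.null(names(class_probs)) || any(names(class_probs) == ""))
    stop("class_probs must be a fully named vector")
  if (abs(sum(class_probs) - 1) > 1e-9)
    stop("class probabilities must sum to 1")
  set.seed(seed)
  counts <- as.vector(stats::rmultinom(1, n_events, class_probs))
  data.frame(label = names(class_probs), count = counts,
             stringsAsFactors = FALSE)
}
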
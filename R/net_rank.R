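#' Count candidate and modifier interaction partners
#'
#' For each candidate, counts (a) distinct OTHER candidates adjacent in the
#' network (internal degree) and (b) distinct chromatin-modifier genes
#' adjacent (modifier degree). Candidates absent from the network have both
#' degrees 0.
#'
#' @param candidates character vector of candidate gene ids (non-empty).
#' @param network an [interaction_network()].
#' @return Data frame with columns gene_id, internal_degree, modifier_degree.
#' @export
count_interactions <- function(candidates, network) {
  if (length(candidates) == 0) stop("candidates must be non-empty")
  ed <- network$edges
  # adjacency as symmetric long pairs
  a <- c(ed$from, ed$to)
  b <- c(ed$to, ed$from)
  internal <- vapply(candidates, function(g) {
    nb <- b[a == g]
    length(unique(nb[nb %in% setdiff(candidates, g)]))
  }, integer(1))
  modifier <- vapply(candidates, function(g) {
    nb <- b[a == g]
    length(unique(nb[nb %in% network$modifiers]))
  }, integer(1))
  data.frame(gene_id = candidates,
             internal_degree = unname(internal),
             modifier_degree = unname(modifier),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Apply the fold-change / connectivity exclusion rule
#'
#' Flags (never removes) candidates with low differential expression:
#' log2 differential below `fc_hard` (reason `low_fc`), or below `fc_soft`
#' with no reported interactions of either counted type
#' (reason `low_fc_no_interactions`).
#'
#' @param records data frame with gene_id, log2fc, internal_degree,
#'   modifier_degree.
#' @param fc_hard hard log2 fold-change floor (default 1).
#' @param fc_soft conditional floor applied when total degree is 0
#'   (default 2).
#' @return `records` with added columns `excluded` (logical) and
#'   `exclusion_reason` (`"low_fc"`, `"low_fc_no_interactions"` or `"none"`).
#' @export
apply_exclusion <- function(records, fc_hard = 1, fc_soft = 2) {
  if (fc_soft < fc_hard) stop("fc_soft must be >= fc_hard")
  total_deg <- records$internal_degree + records$modifier_degree
  reason <- rep("none", nrow(records))
  reason[records$log2fc >= fc_hard & records$log2fc < fc_soft & total_deg == 0] <-
    "low_fc_no_interactions"
  reason[records$log2fc < fc_hard] <- "low_fc"
  records$excluded <- reason != "none"
  records$exclusion_reason <- reason
  records
}

#' Rank candidates by rank-sum over three criteria
#'
#' Among non-excluded candidates, ranks separately by internal degree,
#' modifier degree and log2 differential (each descending, competition
#' ranking: ties share the smallest ordinal, the next ordinal is skipped),
#' sums the three ranks, and orders by ascending rank sum with ties broken
#' by higher log2fc then gene id. Excluded records follow the ranked block
#' with `final_rank` NA.
#'
#' @param records data frame from [apply_exclusion()] (needs `excluded`).
#' @return `records` with added columns rank_internal, rank_modifier,
#'   rank_fc, rank_sum, final_rank; rows reordered to final_rank order with
#'   excluded records last.
#' @export
rank_candidates <- function(records) {
  if (is.null(records$excluded))
    stop("apply_exclusion must be run before ranking")
  comp_rank <- function(x) rank(-x, ties.method = "min")
  rec <- records
  rec$rank_internal <- NA_integer_
  rec$rank_modifier <- NA_integer_
  rec$rank_fc <- NA_integer_
  rec$rank_sum <- NA_integer_
  rec$final_rank <- NA_integer_
  keep <- !rec$excluded
  if (any(keep)) {
    rec$rank_internal[keep] <- comp_rank(rec$internal_degree[keep])
    rec$rank_modifier[keep] <- comp_rank(rec$modifier_degree[keep])
    rec$rank_fc[keep] <- comp_rank(rec$log2fc[keep])
    rec$rank_sum[keep] <- rec$rank_internal[keep] + rec$rank_modifier[keep] +
      rec$rank_fc[keep]
    ord <- order(rec$rank_sum[keep], -rec$log2fc[keep], rec$gene_id[keep])
    rec$final_rank[keep][ord] <- seq_len(sum(keep))
  }
  excluded_block <- rec[!keep, , drop = FALSE]
  excluded_block <- excluded_block[order(excluded_block$gene_id), , drop = FALSE]
  out <- rbind(rec[keep, , drop = FALSE][order(rec$final_rank[keep]), , drop = FALSE],
               excluded_block)
  rownames(out) <- NULL
  out
}

#' Top-k shortlist from a ranked table
#'
#' @param table ranked data frame from [rank_candidates()].
#' @param k shortlist size (default 20).
#' @return Character vector of the first `min(k, m)` non-excluded gene ids
#'   in final-rank order.
#' @export
top_k <- function(table, k = 20) {
  if (k < 1) stop("k must be >= 1")
  kept <- table[!table$excluded, , drop = FALSE]
  kept <- kept[order(kept$final_rank), , drop = FALSE]
  utils::head(kept$gene_id, k)
}

#' One-call candidate prioritization
#'
#' Convenience wrapper chaining [count_interactions()], [apply_exclusion()]
#' and [rank_candidates()] for a curated candidate list.
#'
#' @param candidates data frame from [curate()] or a character vector of ids.
#' @param de data frame from [compute_de()] (log2fc looked up by gene id;
#'   candidates absent from the screen get log2fc `Inf` so curated additions
#'   are never fold-change-excluded).
#' @param network an [interaction_network()].
#' @param fc_hard,fc_soft exclusion thresholds, see [apply_exclusion()].
#' @return Ranked data frame as from [rank_candidates()].
#' @export
prioritize_candidates <- function(candidates, de, network,
                                  fc_hard = 1, fc_soft = 2) {
  ids <- if (is.data.frame(candidates)) candidates$gene_id else candidates
  rec <- count_interactions(ids, network)
  rec$log2fc <- de$log2fc[match(rec$gene_id, de$gene_id)]
  rec$log2fc[is.na(rec$log2fc)] <- Inf
  rec <- apply_exclusion(rec, fc_hard, fc_soft)
  rank_candidates(rec)
}
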
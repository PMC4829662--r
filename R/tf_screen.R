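#' Two-condition differential expression screen
#'
#' Computes the per-gene log2 differential (target minus source group mean)
#' used to screen for target-specific DNA-binding genes, together with a
#' target-detection flag derived from detection p-values when available.
#'
#' @param source,target [expression_matrix()] objects with identical,
#'   identically ordered gene ids.
#' @param detection_thresh detection p-value at or below which a probe counts
#'   as detected; a gene is `detected_target` if it is detected in at least
#'   one target sample (always `TRUE` when the target matrix carries no
#'   detection p-values).
#' @return Data frame with columns gene_id, mean_source, mean_target,
#'   log2fc (= mean_target - mean_source) and detected_target.
#' @export
compute_de <- function(source, target, detection_thresh = 0.01) {
  gs <- gene_ids(source); gt <- gene_ids(target)
  if (!identical(gs, gt)) {
    n <- min(length(gs), length(gt))
    bad <- which(gs[seq_len(n)] != gt[seq_len(n)])[1]
    if (is.na(bad)) bad <- n + 1
    stop(sprintf("gene sets differ between matrices (first discrepancy at row %d)", bad))
  }
  ms <- rowMeans(source$values)
  mt <- rowMeans(target$values)
  detected <- if (is.null(target$detection_p)) rep(TRUE, length(ms)) else
    rowSums(target$detection_p <= detection_thresh) >= 1
  data.frame(gene_id = gene_ids(source),
             mean_source = ms, mean_target = mt,
             log2fc = mt - ms,
             detected_target = detected,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select target-specific DNA-binding genes
#'
#' Applies the screening predicate: DNA-binding, detected in the target
#' condition, and log2 differential at or above `min_log2fc`. The result is
#' ordered by descending log2fc, ties broken by gene id.
#'
#' @param de data frame from [compute_de()].
#' @param annotation annotation data frame with gene_id, is_dna_binding.
#' @param min_log2fc log2 fold-change floor (default 1, the lower bound of
#'   the downstream exclusion rule).
#' @return Character vector of selected gene ids.
#' @export
select_mk_specific <- function(de, annotation, min_log2fc = 1) {
  miss <- setdiff(de$gene_id, annotation$gene_id)
  if (length(miss) > 0)
    stop(sprintf("annotation missing screened gene(s), e.g. %s", miss[1]))
  ann <- annotation[match(de$gene_id, annotation$gene_id), ]
  keep <- ann$is_dna_binding & de$detected_target & de$log2fc >= min_log2fc
  sel <- de[keep, , drop = FALSE]
  sel$gene_id[order(-sel$log2fc, sel$gene_id)]
}

#' Curate a candidate list: drop histones, add knowledge-based candidates
#'
#' Removes histone-flagged genes from the screened list and appends curated
#' additions, de-duplicating while preserving first occurrence. Additions
#' absent from the annotation are accepted (knowledge-based candidates need
#' not have passed the screen).
#'
#' @param candidates character vector of screened gene ids.
#' @param annotation annotation data frame with gene_id, is_histone.
#' @param additions character vector of curated additions (may be empty).
#' @return Data frame with columns gene_id and provenance
#'   (`"screen"` or `"curated_addition"`).
#' @export
curate <- function(candidates, annotation, additions = character(0)) {
  histones <- annotation$gene_id[annotation$is_histone]
  kept <- candidates[!candidates %in% histones]
  out <- data.frame(gene_id = kept,
                    provenance = rep("screen", length(kept)),
                    stringsAsFactors = FALSE)
  new <- additions[!additions %in% kept]
  if (length(new) > 0)
    out <- rbind(out, data.frame(gene_id = new,
                                 provenance = "curated_addition",
                                 stringsAsFactors = FALSE))
  out <- out[!duplicated(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
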
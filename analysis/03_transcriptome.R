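#!/usr/bin/env Rscript
# Stage 3: whole-transcriptome comparison of the two conditions.
#
# Informative-probe filtering (detection P <= 0.01 in at least one sample),
# quantile normalization, Welch differential expression at the 2-fold / 5%
# FDR gate, average-linkage clustering of samples on 1 - Pearson
# correlation, hypergeometric enrichment of a planted gene set over the
# informative universe, running-sum GSEA on the fold-change ranking, and
# principal-coordinate ordination of the samples.

library(mkfop)

in_dir <- "results/simulated"
out_dir <- "results/transcriptome"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

src <- read_expression_matrix(file.path(in_dir, "source.tsv"))
tgt <- read_expression_matrix(file.path(in_dir, "target.tsv"))
truth <- read_truth(file.path(in_dir, "truth.txt"))

combined <- expression_matrix(cbind(src$values, tgt$values),
                              cbind(src$detection_p, tgt$detection_p))
informative <- filter_informative(combined, p_thresh = 0.01)
norm <- normalize_expression(informative)

keep <- gene_ids(norm)
groupA <- expression_matrix(norm$values[, sample_ids(src)])
groupB <- expression_matrix(norm$values[, sample_ids(tgt)])
de <- differential_expression(groupA, groupB, fc_thresh = 2, fdr_thresh = 0.05)
write_table_tsv(de, file.path(out_dir, "de_results.tsv"))

hc <- hierarchical_cluster(norm)
write_cluster_tree(hc, file.path(out_dir, "sample_tree.nwk"))

sig <- de$gene_id[de$significant]
sets <- list(planted = truth$planted_genes,
             decoys = truth$decoy_genes,
             random = keep[seq(1, length(keep), by = 7)])
enr <- hypergeom_enrich(intersect(sig, keep), keep, sets)
write_table_tsv(enr, file.path(out_dir, "enrichment.tsv"))

scores <- setNames(de$log2fc, de$gene_id)
gs <- gsea(scores, truth$planted_genes, n_perm = 1000, seed = 11L)
write_table_tsv(gs, file.path(out_dir, "gsea.tsv"))

ord <- pcoa(norm, n_components = 3)
coords <- data.frame(sample_id = rownames(ord$coordinates), ord$coordinates)
write_table_tsv(coords, file.path(out_dir, "pcoa_coordinates.tsv"))

ov <- de_overlap(list(up = de$gene_id[de$significant & de$log2fc > 0],
                      all_sig = sig))
write_table_tsv(ov$regions, file.path(out_dir, "overlap_regions.tsv"))

message(sprintf("universe %d probes; %d significant; planted-set ES %.2f (NES %.2f, FDR %.2f); first PCoA axis %.0f%% variance",
                length(keep), length(sig), gs$es, gs$nes, gs$fdr,
                100 * ord$variance_fraction[1]))
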
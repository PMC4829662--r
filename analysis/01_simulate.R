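#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the inputs of a megakaryocyte forward-programming screen: a
# pluripotent-source vs MK-target expression contrast with 10 planted
# strongly upregulated DNA-binding factors (log2 effect 3) and 12 moderate
# decoys, a protein-interaction network with planted candidate-candidate
# and candidate-modifier edges over an Erdos-Renyi background, a platelet
# survival series decaying with half-life 7.1 h from the 30-min
# equilibrium point, and a cytometry event table.

library(mkfop)

out_dir <- "results/simulated"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1L)
sim <- gen_expression(cfg)
net <- gen_network(sim$annotation, sim$truth, p_background = 0.005, seed = 2L)
surv_fop <- gen_survival(7.1, 1000, c(0.5, 2, 6, 12, 24), noise_sd = 0.05, seed = 3L)
surv_donor <- gen_survival(19.7, 1000, c(0.5, 2, 6, 12, 24), noise_sd = 0.05, seed = 4L)
cyto <- gen_cytometry(1e5, c(calcein_pos = 0.32, calcein_neg = 0.68), seed = 5L)

write_expression_matrix(sim$source, file.path(out_dir, "source.tsv"))
write_expression_matrix(sim$target, file.path(out_dir, "target.tsv"))
write_annotation(sim$annotation, file.path(out_dir, "annotation.tsv"))
write_network(net, file.path(out_dir, "edges.tsv"),
              file.path(out_dir, "modifiers.txt"))
write_truth(sim$truth, file.path(out_dir, "truth.txt"))
write_survival_series(surv_fop, file.path(out_dir, "survival_fop.csv"))
write_survival_series(surv_donor, file.path(out_dir, "survival_donor.csv"))
write_table_tsv(cyto, file.path(out_dir, "cytometry.tsv"))

message(sprintf("simulated %d genes x %d samples per condition; %d network edges; planted factors: %s",
                nrow(sim$source$values), ncol(sim$source$values),
                nrow(net$edges), paste(sim$truth$planted_genes, collapse = ", ")))
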
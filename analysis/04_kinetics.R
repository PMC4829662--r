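#!/usr/bin/env Rscript
# Stage 4: platelet yield and kinetics calculations.
#
# Fits exponential half-lives to the simulated programmed-MK and donor
# survival series (relative to the 30-min equilibrium point), converts the
# cytometry event table to the assay percentages, and projects the platelet
# yield from one million input cells to transfusion units.

library(mkfop)

in_dir <- "results/simulated"
out_dir <- "results/kinetics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

fop <- fit_half_life(read_survival_series(file.path(in_dir, "survival_fop.csv")))
donor <- fit_half_life(read_survival_series(file.path(in_dir, "survival_donor.csv")))
fits <- data.frame(group = c("fopMK", "donor"),
                   half_life_h = c(fop$half_life, donor$half_life),
                   r_squared = c(fop$r_squared, donor$r_squared))
write_table_tsv(fits, file.path(out_dir, "half_life_fits.tsv"))

cyto <- read_table_tsv(file.path(in_dir, "cytometry.tsv"))
viable_pct <- aggregation_pct(cyto$count[cyto$label == "calcein_pos"],
                              sum(cyto$count))

proj <- project_yield(input_cells = 1e6, mk_per_input = 2e5,
                      platelets_per_mk = 5)
metrics <- data.frame(
  metric = c("viable_platelet_pct", "qpcr_rel_expr_dct3",
             "absolute_count_per_ul", "total_mk", "total_platelets",
             "transfusion_units"),
  value = c(viable_pct, qpcr_rel_expr(23, 20),
            absolute_count(3000, 1000, 1000),
            proj$total_mk, proj$total_platelets, proj$n_units))
write_table_tsv(metrics, file.path(out_dir, "assay_metrics.tsv"))

message(sprintf("half-lives: fopMK %.2f h (r2 %.3f), donor %.2f h (r2 %.3f); yield: %.1e MKs -> %.1e platelets (%d units)",
                fop$half_life, fop$r_squared, donor$half_life, donor$r_squared,
                proj$total_mk, proj$total_platelets, proj$n_units))
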
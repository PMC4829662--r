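#' Default pipeline configuration
#'
#' All analysis thresholds at their standard values: screening fold-change
#' floor 1, exclusion thresholds 1 and 2, detection threshold 0.01,
#' differential-expression gates 2-fold and 5% FDR, shortlist size 20.
#'
#' @param ... overrides for any configuration entry (unknown keys are
#'   rejected).
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    sim = sim_config(),
    min_log2fc = 1,
    detection_thresh = 0.01,
    fc_hard = 1,
    fc_soft = 2,
    top_k = 20,
    fc_thresh = 2,
    fdr_thresh = 0.05,
    p_background = 0.005,
    additions = character(0),
    survival = list(true_half_life = 7.1, n0 = 1000,
                    time_points = c(0.5, 2, 6, 12, 24), noise_sd = 0.05)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key: %s", unknown[1]))
  cfg[names(dots)] <- dots
  if ("seed" %in% names(dots) && !"sim" %in% names(dots))
    cfg$sim$seed <- as.integer(cfg$seed)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$fc_soft < cfg$fc_hard) stop("fc_soft must be >= fc_hard")
  if (cfg$fdr_thresh <= 0 || cfg$fdr_thresh > 1)
    stop("fdr_thresh must lie in (0, 1]")
  if (cfg$detection_thresh <= 0 || cfg$detection_thresh > 1)
    stop("detection_thresh must lie in (0, 1]")
  if (cfg$top_k < 1) stop("top_k must be >= 1")
  if (cfg$p_background < 0 || cfg$p_background > 1)
    stop("p_background must lie in [0, 1]")
  invisible(cfg)
}

#' Run the full synthetic screen-and-rank pipeline
#'
#' Executes simulate -> screen -> curate -> network ranking -> shortlist ->
#' survival fit on synthetic inputs, optionally writing every intermediate
#' table under `out_dir`, and returns the results with a run manifest
#' (configuration snapshot, output files and their digests).
#'
#' @param config list from [pipeline_config()].
#' @param out_dir optional output directory; created if missing.
#' @return List with elements `de`, `candidates`, `ranked`, `shortlist`,
#'   `truth`, `kinetics`, and `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  validate_config(config)
  sim <- gen_expression(config$sim)
  de <- compute_de(sim$source, sim$target,
                   detection_thresh = config$detection_thresh)
  selected <- select_mk_specific(de, sim$annotation,
                                 min_log2fc = config$min_log2fc)
  candidates <- curate(selected, sim$annotation, config$additions)
  network <- gen_network(sim$annotation, sim$truth,
                         p_background = config$p_background,
                         seed = config$sim$seed + 1L)
  ranked <- prioritize_candidates(candidates, de, network,
                                  fc_hard = config$fc_hard,
                                  fc_soft = config$fc_soft)
  shortlist <- top_k(ranked, config$top_k)
  sv <- config$survival
  series <- gen_survival(sv$true_half_life, sv$n0, sv$time_points,
                         sv$noise_sd, seed = config$sim$seed + 2L)
  kinetics <- fit_half_life(series)

  outputs <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_expression_matrix(sim$source, p("source.tsv"))
    write_expression_matrix(sim$target, p("target.tsv"))
    write_annotation(sim$annotation, p("annotation.tsv"))
    write_network(network, p("edges.tsv"), p("modifiers.txt"))
    write_table_tsv(de, p("de_table.tsv"))
    write_table_tsv(candidates, p("candidates.tsv"))
    write_table_tsv(ranked, p("ranked.tsv"))
    writeLines(shortlist, p("shortlist.txt"))
    write_survival_series(series, p("survival.csv"))
    write_truth(sim$truth, p("truth.txt"))
    outputs <- list.files(out_dir, full.names = TRUE)
  }
  manifest <- list(config = config,
                   outputs = basename(outputs),
                   digests = if (length(outputs)) tools::md5sum(outputs) else NULL,
                   n_selected = length(selected),
                   n_candidates = nrow(candidates),
                   n_excluded = sum(ranked$excluded),
                   timestamp = format(Sys.time(), tz = "UTC"))
  list(de = de, candidates = candidates, ranked = ranked,
       shortlist = shortlist, truth = sim$truth, kinetics = kinetics,
       manifest = manifest)
}

#' Tabular and network readers/writers
#'
#' Tab-separated text with header for tables; two-column edge lists plus a
#' one-symbol-per-line modifier file for networks; a key=value text file for
#' simulation ground truth.
#'
#' @param df data frame.
#' @param path,edge_path,modifier_path file paths.
#' @return Readers return the parsed object; writers return the path
#'   invisibly.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_table_tsv
#' @param annotation annotation data frame.
#' @export
write_annotation <- function(annotation, path) write_table_tsv(annotation, path)

#' @rdname write_table_tsv
#' @export
read_annotation <- function(path) {
  df <- read_table_tsv(path)
  needed <- c("gene_id", "is_dna_binding", "is_histone")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0)
    stop(sprintf("annotation file missing column %s", miss[1]))
  df$is_dna_binding <- as.logical(df$is_dna_binding)
  df$is_histone <- as.logical(df$is_histone)
  df
}

#' @rdname write_table_tsv
#' @param network an [interaction_network()].
#' @export
write_network <- function(network, edge_path, modifier_path) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(network$modifiers, modifier_path)
  invisible(edge_path)
}

#' @rdname write_table_tsv
#' @export
read_network <- function(edge_path, modifier_path = NULL) {
  ed <- utils::read.delim(edge_path, header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("from", "to"))
  mods <- if (!is.null(modifier_path)) readLines(modifier_path) else character(0)
  interaction_network(ed, mods)
}

#' @rdname write_table_tsv
#' @param truth truth list from [gen_expression()].
#' @export
write_truth <- function(truth, path) {
  flat <- c(
    planted_genes = paste(truth$planted_genes, collapse = ","),
    decoy_genes = paste(truth$decoy_genes, collapse = ","),
    modifier_genes = paste(truth$modifier_genes, collapse = ","),
    planted_internal_edges = paste(paste(truth$planted_internal_edges$from,
                                         truth$planted_internal_edges$to,
                                         sep = "-"), collapse = ","),
    planted_modifier_edges = paste(paste(truth$planted_modifier_edges$from,
                                         truth$planted_modifier_edges$to,
                                         sep = "-"), collapse = ","))
  writeLines(paste(names(flat), flat, sep = "="), path)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- stats::setNames(vapply(kv, function(x)
    if (length(x) > 1) x[2] else "", character(1)),
    vapply(kv, `[`, character(1), 1))
  split_ids <- function(s) if (nzchar(s)) strsplit(s, ",", fixed = TRUE)[[1]] else character(0)
  split_edges <- function(s) {
    ids <- split_ids(s)
    if (length(ids) == 0) return(empty_edges())
    parts <- strsplit(ids, "-", fixed = TRUE)
    data.frame(from = vapply(parts, `[`, character(1), 1),
               to = vapply(parts, `[`, character(1), 2),
               stringsAsFactors = FALSE)
  }
  list(planted_genes = split_ids(vals[["planted_genes"]]),
       decoy_genes = split_ids(vals[["decoy_genes"]]),
       modifier_genes = split_ids(vals[["modifier_genes"]]),
       planted_internal_edges = split_edges(vals[["planted_internal_edges"]]),
       planted_modifier_edges = split_edges(vals[["planted_modifier_edges"]]))
}
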
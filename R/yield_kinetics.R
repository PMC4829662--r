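#' Relative qPCR expression (2^-dCt)
#'
#' Relative expression of a target transcript versus a housekeeping
#' reference from their Ct values: 2^-(ct_target - ct_reference).
#'
#' @param ct_target,ct_reference threshold cycles (finite).
#' @return Relative expression (dimensionless).
#' @export
qpcr_rel_expr <- function(ct_target, ct_reference) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_reference)))
    stop("Ct values must be finite")
  2^-(ct_target - ct_reference)
}

#' Bead-based absolute cell concentration
#'
#' Converts cytometry event counts to absolute concentration using counting
#' beads of known concentration: cells/ul = cell_events / bead_events *
#' bead_conc.
#'
#' @param cell_events gated cell events.
#' @param bead_events bead events (> 0).
#' @param bead_conc bead concentration (beads per ul, > 0).
#' @return Cell concentration per ul.
#' @export
absolute_count <- function(cell_events, bead_events, bead_conc) {
  if (any(bead_events <= 0)) stop("bead_events must be > 0")
  if (any(bead_conc <= 0)) stop("bead_conc must be > 0")
  cell_events / bead_events * bead_conc
}

#' Platelets released per megakaryocyte sown
#'
#' @param platelet_count platelets harvested.
#' @param mk_seeded megakaryocytes sown (> 0).
#' @return Platelets per MK.
#' @export
platelets_per_mk <- function(platelet_count, mk_seeded) {
  if (any(mk_seeded <= 0)) stop("mk_seeded must be > 0")
  platelet_count / mk_seeded
}

#' Project platelet yield to transfusion units
#'
#' Scales a per-input-cell megakaryocyte yield and a per-MK platelet release
#' up to total platelets and whole transfusion units (floor).
#'
#' @param input_cells starting pluripotent cells.
#' @param mk_per_input megakaryocytes obtained per input cell.
#' @param platelets_per_mk platelets released per megakaryocyte.
#' @param unit_size platelets per transfusion unit (default 2.4e11).
#' @return List with input_cells, mk_per_input, platelets_per_mk, unit_size,
#'   total_mk, total_platelets, n_units.
#' @export
project_yield <- function(input_cells, mk_per_input, platelets_per_mk,
                          unit_size = 2.4e11) {
  if (any(c(input_cells, mk_per_input, platelets_per_mk, unit_size) <= 0))
    stop("all arguments must be positive")
  total_mk <- input_cells * mk_per_input
  total_platelets <- total_mk * platelets_per_mk
  list(input_cells = input_cells,
       mk_per_input = mk_per_input,
       platelets_per_mk = platelets_per_mk,
       unit_size = unit_size,
       total_mk = total_mk,
       total_platelets = total_platelets,
       n_units = floor(total_platelets / unit_size))
}

#' Platelet survival half-life from an exponential decay fit
#'
#' Ordinary least squares of log2(count) on time over the points at or after
#' the equilibrium reference (the early post-transfusion sample once the
#' circulation has equilibrated); the half-life is -1/slope.
#'
#' @param series data frame with columns `time_h` (ascending hours) and
#'   `count` (positive absolute counts), e.g. from [gen_survival()].
#' @param equilibrium_index position of the equilibrium reference point
#'   (default 1); earlier points are excluded from the fit.
#' @return List with half_life (hours), log2_intercept, r_squared, n_points.
#' @export
fit_half_life <- function(series, equilibrium_index = 1) {
  t <- series$time_h; y <- series$count
  if (length(t) - equilibrium_index + 1 < 3)
    stop("need at least 3 points at or after the equilibrium index")
  idx <- seq(equilibrium_index, length(t))
  t <- t[idx]; y <- y[idx]
  if (any(y <= 0)) stop("counts must be positive")
  fit <- stats::lm(log2(y) ~ t)
  slope <- unname(stats::coef(fit)[2])
  if (slope >= 0) stop("no decay detected (non-negative slope)")
  ly <- log2(y)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((ly - mean(ly))^2)
  list(half_life = -1 / slope,
       log2_intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       n_points = length(t))
}

#' Aggregation percentage from gated cytometry counts
#'
#' Fraction of viable (Calcein-positive) double CD31-positive aggregate
#' events among all live events, as a percentage.
#'
#' @param gated_double_positive aggregate-gated events.
#' @param total_live total live events (> 0).
#' @return Percentage in \[0, 100\] for in-gate counts.
#' @export
aggregation_pct <- function(gated_double_positive, total_live) {
  if (any(total_live <= 0)) stop("total_live must be > 0")
  100 * gated_double_positive / total_live
}

#' Agonist-induced delta-aggregation
#'
#' Difference between stimulated and unstimulated aggregation percentages;
#' negative values are preserved (no clamping).
#'
#' @param stimulated_pct,unstimulated_pct percentages in \[0, 100\].
#' @return stimulated_pct - unstimulated_pct.
#' @export
delta_aggregation <- function(stimulated_pct, unstimulated_pct) {
  rng <- c(stimulated_pct, unstimulated_pct)
  if (any(rng < 0 | rng > 100)) stop("percentages must lie in [0, 100]")
  stimulated_pct - unstimulated_pct
}

#' Bead adhesion percentage
#'
#' @param bound_single_beads single beads bound by platelets.
#' @param total_single_beads all single beads (> 0).
#' @return Percentage bound.
#' @export
adhesion_pct <- function(bound_single_beads, total_single_beads) {
  if (any(total_single_beads <= 0)) stop("total_single_beads must be > 0")
  100 * bound_single_beads / total_single_beads
}

#' Thrombus incorporation density
#'
#' Labelled platelet events per 100 square micrometres of thrombus area.
#'
#' @param labelled_events labelled platelets counted in the thrombus.
#' @param thrombus_area thrombus area in square micrometres (> 0).
#' @return Events per 100 um^2.
#' @export
thrombus_density <- function(labelled_events, thrombus_area) {
  if (any(thrombus_area <= 0)) stop("thrombus_area must be > 0")
  labelled_events / thrombus_area * 100
}

#' Read and write survival series CSV (header: time_h,count)
#' @param path file path.
#' @return `read_survival_series` returns the data frame.
#' @export
read_survival_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_h", "count") %in% names(df)))
    stop("survival CSV must have columns time_h,count")
  df
}

#' @rdname read_survival_series
#' @param series data frame with time_h, count.
#' @export
write_survival_series <- function(series, path) {
  utils::write.csv(series[, c("time_h", "count")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
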
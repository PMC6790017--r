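#' Bony arch index
#'
#' BAI = h / l, navicular height over foot length. During weight bearing a
#' BAI below 0.21 indicates a low (flat) arch and 0.21--0.27 a normal arch.
#'
#' @param h navicular height, mm (>= 0).
#' @param l foot length, mm (> 0).
#' @return h / l (unitless). Vectorised.
#' @export
compute_bai <- function(h, l) {
  if (any(l <= 0)) stop("foot length l must be > 0")
  if (any(h < 0)) stop("navicular height h must be >= 0")
  h / l
}

#' Classify arch type from weight-bearing BAI
#'
#' Low arch is BAI < 0.21; normal arch 0.21--0.27 (both boundaries included,
#' since low arch is defined strictly below 0.21); high arch above 0.27.
#'
#' @param bai weight-bearing BAI values.
#' @return factor with levels `low`, `normal`, `high`.
#' @export
classify_arch <- function(bai) {
  cls <- ifelse(bai < 0.21, "low", ifelse(bai <= 0.27, "normal", "high"))
  factor(cls, levels = c("low", "normal", "high"))
}

#' Arch flexibility
#'
#' Deformation (non-weight-bearing minus weight-bearing navicular height)
#' per unit load, in micrometres per newton: `1000 * (h_nwb - h_wb) / load`.
#' The load is the cycle's peak load -- the load that produced the
#' deformation.
#'
#' @param h_nwb non-weight-bearing height, mm.
#' @param h_wb weight-bearing height, mm.
#' @param load peak load, N (> 0).
#' @return flexibility in um/N. Vectorised.
#' @export
compute_flexibility <- function(h_nwb, h_wb, load) {
  if (any(load <= 0)) stop("load must be > 0")
  1000 * (h_nwb - h_wb) / load
}

#' Energy absorption per cycle
#'
#' Elastic strain energy stored in one loading cycle, treating the foot as a
#' linear-elastic body: deformation times load over two,
#' `(d / 1000) * load / 2` joules (deformation in mm).
#'
#' @param deformation arch deformation, mm; negative values are physically
#'   implausible and flagged with a warning, not clipped.
#' @param load peak load, N (> 0).
#' @return energy in J. Vectorised.
#' @export
compute_energy <- function(deformation, load) {
  if (any(load <= 0)) stop("load must be > 0")
  if (any(deformation < 0))
    warning(sum(deformation < 0), " negative deformation value(s) retained")
  (deformation / 1000) * load / 2
}

#' Per-cycle arch metrics for one specimen
#'
#' Derives BAI (weight-bearing and non-weight-bearing), deformation,
#' flexibility, energy absorption and arch classification from segmented
#' cycle records.
#'
#' @param records a `cycle_records` data.frame from [segment_cycles()].
#' @param foot_length_mm the specimen's foot length.
#' @return data.frame of class `arch_metrics`: `cycle`, `peak_load_N`,
#'   `bai_wb`, `bai_nwb`, `deformation_mm`, `flexibility_um_per_N`,
#'   `energy_J`, `arch_class`.
#' @examples
#' rec <- data.frame(cycle = 1, h_wb_mm = 52.5, h_nwb_mm = 56.5,
#'                   peak_load_N = 500, min_load_N = 0, wb_duration_s = 0.95)
#' arch_metrics(rec, foot_length_mm = 250)
#' @export
arch_metrics <- function(records, foot_length_mm) {
  d <- records$h_nwb_mm - records$h_wb_mm
  out <- data.frame(
    cycle = records$cycle,
    peak_load_N = records$peak_load_N,
    bai_wb = compute_bai(records$h_wb_mm, foot_length_mm),
    bai_nwb = compute_bai(records$h_nwb_mm, foot_length_mm),
    deformation_mm = d,
    flexibility_um_per_N = compute_flexibility(records$h_nwb_mm,
                                               records$h_wb_mm,
                                               records$peak_load_N),
    energy_J = suppressWarnings(compute_energy(d, records$peak_load_N))
  )
  if (any(d < 0))
    warning(sum(d < 0), " cycle(s) with negative deformation retained")
  out$arch_class <- classify_arch(out$bai_wb)
  class(out) <- c("arch_metrics", "data.frame")
  out
}

#' First-versus-last-cycle metric differences
#'
#' The fatigue effect size used for between-group comparison: metric at the
#' first cycle minus metric at the last cycle (cycle 1 vs cycle 10,000 in the
#' full protocol).
#'
#' @param metrics an `arch_metrics` data.frame for one specimen.
#' @param cycles length-2 vector: the two endpoint cycles (default
#'   `c(1, 10000)`).
#' @param specimen_id identifier used in error messages and output.
#' @return one-row data.frame: `specimen_id`, `delta_bai`,
#'   `delta_flexibility_um_per_N`, `delta_energy_J`.
#' @export
compute_deltas <- function(metrics, cycles = c(1, 10000),
                           specimen_id = NA_character_) {
  i1 <- match(cycles[1], metrics$cycle)
  i2 <- match(cycles[2], metrics$cycle)
  if (is.na(i1) || is.na(i2)) {
    stop("specimen ", specimen_id, ": endpoint cycle(s) ",
         paste(cycles[c(is.na(i1), is.na(i2))], collapse = ", "),
         " not present in the metric table")
  }
  data.frame(
    specimen_id = specimen_id,
    delta_bai = metrics$bai_wb[i1] - metrics$bai_wb[i2],
    delta_flexibility_um_per_N = metrics$flexibility_um_per_N[i1] -
      metrics$flexibility_um_per_N[i2],
    delta_energy_J = metrics$energy_J[i1] - metrics$energy_J[i2]
  )
}

#' Write a per-specimen metrics table
#'
#' @param metrics an `arch_metrics` data.frame.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  data.table::fwrite(as.data.frame(metrics), path)
  invisible(path)
}
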
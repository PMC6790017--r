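#' Segment a specimen trace into loading cycles
#'
#' A loading cycle is one weight-bearing excursion (a maximal run of samples
#' with axial load at or above the threshold, 50 N by definition of the
#' weight-bearing phase) paired with the non-weight-bearing trough that
#' follows it. The weight-bearing navicular height `h_wb` is read at the
#' sample of maximum load within the excursion (earliest such sample on
#' ties), the non-weight-bearing height `h_nwb` at the sample of minimum load
#' within the following trough. A final excursion with no following trough is
#' dropped; a leading trough before the first excursion is ignored, so
#' segmentation is invariant to prepending or appending sub-threshold
#' samples.
#'
#' @param trace a `specimen_trace` (from [simulate_specimen()] or
#'   [read_trace()]).
#' @param wb_threshold weight-bearing force threshold in N (default 50).
#' @return A data.frame of class `cycle_records` with 1-based consecutive
#'   `cycle` and columns `h_wb_mm`, `h_nwb_mm`, `peak_load_N`, `min_load_N`,
#'   `wb_duration_s`. Cycles where the loaded height exceeds the unloaded
#'   height (physically implausible) are kept but counted in the
#'   `"n_implausible"` attribute and reported with a warning.
#' @examples
#' p <- generator_params("normal", total_cycles = 3)
#' rec <- segment_cycles(simulate_specimen(p, 1))
#' rec
#' @export
segment_cycles <- function(trace, wb_threshold = 50) {
  s <- trace$samples
  if (is.null(s) || nrow(s) == 0) stop("trace has no samples")
  dt <- diff(s$time_s)
  if (length(dt)) {
    if (any(dt <= 0)) stop("sample times must be strictly increasing")
    if (max(dt) - min(dt) > 1e-6 * stats::median(dt) + 1e-9)
      stop("non-uniform sampling: time steps range ",
           signif(min(dt), 6), " to ", signif(max(dt), 6), " s")
  }
  rate <- if (!is.null(trace$sampling_rate_hz) && !is.na(trace$sampling_rate_hz))
    trace$sampling_rate_hz else 1 / stats::median(dt)

  wb_flag <- s$load_N >= wb_threshold
  if (!any(wb_flag)) {
    warning("load never reaches the weight-bearing threshold (",
            wb_threshold, " N); zero cycles")
    return(empty_cycle_records())
  }

  d <- data.table::as.data.table(s)
  d[, wb := wb_flag]
  d[, run := data.table::rleid(wb)]
  runs <- d[, .(is_wb = wb[1L],
                peak_i = .I[which.max(load_N)],
                min_i = .I[which.min(load_N)],
                n = .N), by = run]

  keep <- which(runs$is_wb &
                  seq_len(nrow(runs)) < nrow(runs))  # excursion with a follower
  if (length(keep) == 0) {
    warning("no completed cycle (every excursion lacks a following trough)")
    return(empty_cycle_records())
  }
  pk <- runs$peak_i[keep]
  tr <- runs$min_i[keep + 1L]

  rec <- data.frame(
    cycle = seq_along(keep),
    h_wb_mm = s$navicular_y_mm[pk],
    h_nwb_mm = s$navicular_y_mm[tr],
    peak_load_N = s$load_N[pk],
    min_load_N = s$load_N[tr],
    wb_duration_s = runs$n[keep] / rate
  )
  n_bad <- sum(rec$h_nwb_mm < rec$h_wb_mm)
  if (n_bad > 0)
    warning(n_bad, " cycle(s) have non-weight-bearing height below ",
            "weight-bearing height (flagged, kept)")
  dropped <- nrow(s) - sum(runs$n[c(keep, keep + 1L)])
  structure(rec, class = c("cycle_records", "data.frame"),
            n_implausible = n_bad, n_samples_dropped = dropped,
            wb_threshold = wb_threshold)
}

empty_cycle_records <- function() {
  structure(data.frame(cycle = integer(), h_wb_mm = numeric(),
                       h_nwb_mm = numeric(), peak_load_N = numeric(),
                       min_load_N = numeric(), wb_duration_s = numeric()),
            class = c("cycle_records", "data.frame"),
            n_implausible = 0L, n_samples_dropped = 0L, wb_threshold = NA_real_)
}

#' Extract cycle records at checkpoint cycles
#'
#' @param records a `cycle_records` data.frame (or any data.frame with a
#'   `cycle` column).
#' @param checkpoints cycle indices to extract (default: cycle 1 plus every
#'   1000th cycle up to the last observed cycle).
#' @return the rows of `records` at the requested cycles, in checkpoint
#'   order.
#' @export
checkpoint_series <- function(records,
                              checkpoints = default_checkpoints(max(records$cycle))) {
  if (nrow(records) == 0) stop("no cycle records")
  idx <- match(checkpoints, records$cycle)
  if (anyNA(idx)) {
    stop("checkpoint(s) beyond the observed cycle range: ",
         paste(checkpoints[is.na(idx)], collapse = ", "),
         " (last observed cycle ", max(records$cycle), ")")
  }
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a per-specimen cycle table
#'
#' @param records a `cycle_records` data.frame.
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_cycle_table <- function(records, path) {
  data.table::fwrite(as.data.frame(records), path)
  invisible(path)
}
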
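# shared fixtures, all generated in code

# fully deterministic generator settings (every stochastic term off)
noise_free_params <- function(group = "obese", total_cycles = 50, ...) {
  generator_params(group,
                   total_cycles = total_cycles,
                   marker_noise_sd_mm = 0, load_noise_sd_N = 0,
                   tendon_noise_sd_N = 0, offset_sd_bai = 0,
                   jitter_sd_cycles = 0, d_specimen_cv = 0,
                   foot_length_sd_mm = 0, lof_r2 = 1, ...)
}

# hand-built three-cycle trace with extrema planted by construction:
# each cycle is 8 samples at 1 Hz ramping 0 -> peak -> 0, heights chosen
# so h_wb / h_nwb per cycle are known exactly
toy_trace <- function(peaks = c(500, 520, 480),
                      h_wb = c(55, 54, 53), h_nwb = c(60, 59, 58)) {
  loads <- heights <- numeric(0)
  for (i in seq_along(peaks)) {
    frac <- c(0, 0.3, 0.7, 1, 0.7, 0.3, 0.1, 0)   # trough at both ends
    loads <- c(loads, peaks[i] * frac)
    heights <- c(heights, h_nwb[i] - (h_nwb[i] - h_wb[i]) * frac)
  }
  n <- length(loads)
  structure(list(specimen_id = "toy", group = "toy", foot_length_mm = 250,
                 peak_load_N = max(peaks), sampling_rate_hz = 1,
                 seed = NA_integer_,
                 samples = data.frame(time_s = seq_len(n) - 1, load_N = loads,
                                      tendon_N = 0, navicular_y_mm = heights)),
            class = "specimen_trace")
}

# independent least-squares oracle: raw normal equations
normal_equations_fit <- function(x, y, order) {
  X <- outer(x, 0:order, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# plain record table, segmentation bookkeeping attributes dropped
strip_attrs <- function(d) {
  out <- as.data.frame(d)
  attributes(out) <- attributes(out)[c("names", "class", "row.names")]
  class(out) <- "data.frame"
  out
}

# metric tables + manifest for a small cohort, one segmentation pass
cohort_metrics <- function(coh) {
  mets <- list()
  for (id in names(coh$traces)) {
    tr <- coh$traces[[id]]
    rec <- suppressWarnings(segment_cycles(tr))
    mets[[id]] <- suppressWarnings(arch_metrics(rec, tr$foot_length_mm))
  }
  mets
}
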
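#' Reproducible lack-of-fit pattern for a group trajectory
#'
#' Real creep trajectories deviate systematically from any low-order
#' polynomial; the published cubic fits capture about 94.7% of the checkpoint
#' variance. The generator reproduces this with a deterministic deviation
#' pattern, identical for every specimen of a group, constructed on the
#' checkpoint grid so that it (i) is orthogonal to all polynomial bases up to
#' order 5 -- it therefore changes neither the fitted coefficients of any
#' candidate order nor the AIC order choice nor the fitted inflection point --
#' and (ii) vanishes at the calibration-anchor checkpoints, so anchored group
#' means stay exact. Its amplitude is set so a cubic fit of
#' trajectory + pattern attains R^2 = `lof_r2` on the grid.
#'
#' @param params a [generator_params()] object.
#' @param grid checkpoint grid on which the pattern is constructed.
#' @return numeric vector of BAI deviations, one per grid point.
#' @export
lack_of_fit_pattern <- function(params, grid = default_checkpoints()) {
  r2 <- params$lof_r2
  if (r2 >= 1) return(numeric(length(grid)))
  z <- grid / max(grid)
  # constraint rows: orthogonality to polynomials of order <= 5, and zeros
  # at the anchor checkpoints
  C <- t(outer(z, 0:5, `^`))
  zi <- match(params$lof_zero_cycles, grid)
  zi <- zi[!is.na(zi)]
  if (length(zi)) C <- rbind(C, diag(length(grid))[zi, , drop = FALSE])
  sv <- svd(C, nu = 0, nv = length(grid))
  null_dim <- length(grid) - qr(C)$rank
  if (null_dim < 1) {
    warning("no room for a lack-of-fit pattern on this grid; returning zeros")
    return(numeric(length(grid)))
  }
  g <- sv$v[, length(grid) - null_dim + 1L]  # one direction of the null space
  if (g[which.max(abs(g))] < 0) g <- -g      # fixed sign convention
  v <- eval_trajectory(params$trajectory, grid)
  tss <- sum((v - mean(v))^2)
  g * sqrt(tss * (1 - r2) / r2) / sqrt(sum(g^2))
}

# per-specimen trajectory: the group anchors shifted by a constant BAI offset,
# with the stationary inflection moved to chi0 + delta.  Re-solving (rather
# than shifting the cubic's argument) keeps anchored checkpoint values exact
# and keeps every specimen cubic monotone for any delta.
specimen_trajectory <- function(params, offset, delta) {
  if (offset == 0 && delta == 0) return(params$trajectory)
  calibrate_trajectory(rbind(
    traj_value(1, params$b0_bai + offset),
    traj_value(params$anchor_cycle, params$anchor_bai + offset),
    traj_d1(params$inflection_cycle + delta, 0),
    traj_d2(params$inflection_cycle + delta, 0)
  ), range = c(1, 10000))
}

# power-law stiffening: fraction of the first-cycle deformation present at
# cycle c; equals 1 at c = 1 and d_retained at c = total_cycles
deformation_decay <- function(c, total_cycles, retained, shape = 1) {
  if (total_cycles <= 1) return(rep(1, length(c)))
  u <- (c - 1) / (total_cycles - 1)
  1 - (1 - retained) * u^shape
}

#' Simulate one specimen's multi-channel loading trace
#'
#' Produces the raw 20 Hz record of one cadaveric-foot run: time, axial load
#' (triangular 0 -> F -> 0 within each 1 s cycle), posterior-tibial tendon
#' traction (32 N setpoint engaged whenever axial load exceeds 150 N) and
#' vertical navicular-marker position. The marker height at peak load follows
#' the specimen's calibrated cubic BAI trajectory (plus the group lack-of-fit
#' pattern and measurement noise) scaled by foot length; the unloaded height
#' exceeds it by the cycle's elastic deformation.
#'
#' @param params a [generator_params()] object.
#' @param specimen_seed integer seed for this specimen's random draws.
#' @param specimen_id identifier stored with the trace.
#' @return An object of class `specimen_trace`: a list with `specimen_id`,
#'   `group`, `foot_length_mm`, `peak_load_N`, `sampling_rate_hz`, `seed`, and
#'   `samples` (data.frame: `time_s`, `load_N`, `tendon_N`, `navicular_y_mm`).
#'   The attribute `"planted"` records the latent truth (specimen cubic,
#'   inflection cycle, offsets) for verification.
#' @examples
#' p <- generator_params("obese", total_cycles = 5)
#' tr <- simulate_specimen(p, specimen_seed = 1)
#' head(tr$samples)
#' @export
simulate_specimen <- function(params, specimen_seed,
                              specimen_id = paste0(params$group, "_01")) {
  validate_generator_params(params)
  set.seed(as.integer(specimen_seed %% .Machine$integer.max))

  l <- rnorm(1, params$foot_length_mean_mm, params$foot_length_sd_mm)
  if (l <= 0) stop("drawn foot length is non-positive; check foot length parameters")
  offset <- rnorm(1, 0, params$offset_sd_bai)
  delta  <- rnorm(1, 0, params$jitter_sd_cycles)
  dmult  <- if (params$d_specimen_cv > 0) {
    s <- sqrt(log(1 + params$d_specimen_cv^2))
    exp(rnorm(1, -s^2 / 2, s))   # lognormal, unit mean
  } else 1

  traj <- specimen_trajectory(params, offset, delta)

  C   <- params$total_cycles
  spc <- round(params$sampling_rate_hz / params$cycle_rate_hz)
  cyc <- seq_len(C)

  grid <- default_checkpoints(max(10000, C))
  g <- lack_of_fit_pattern(params, grid)
  g_c <- if (all(g == 0)) numeric(C) else
    approx(grid, g, xout = cyc, rule = 2)$y

  bai_wb <- eval_trajectory(traj, cyc) + g_c
  w <- l * bai_wb                                            # loaded height, mm
  d <- params$d0_mm * dmult *
    deformation_decay(cyc, C, params$d_retained, params$d_shape)
  if (any(d <= 0)) stop("non-positive deformation; check deformation parameters")

  u   <- (seq_len(spc) - 1) / spc          # phase within one cycle
  tri <- 1 - abs(2 * u - 1)                # triangular waveform, peak at u = 0.5
  n   <- C * spc + 1L                      # one trailing unloaded sample
  time_s <- c(rep(cyc - 1, each = spc) + rep(u, C), C) / params$cycle_rate_hz
  frac   <- c(rep(tri, C), 0)
  load   <- params$peak_load_N * frac
  if (params$load_noise_sd_N > 0)
    load <- pmax(0, load + rnorm(n, 0, params$load_noise_sd_N))

  # a trough sample (start of a cycle, zero load) reflects the deformation
  # state left by the preceding excursion, so the trough following cycle c
  # carries w(c), d(c); the trailing sample closes the final cycle
  c_eff <- pmax(rep(cyc, each = spc) - rep(c(1, rep(0, spc - 1)), C), 1L)
  w_s <- c(w[c_eff], w[C])
  d_s <- c(d[c_eff], d[C])
  y <- w_s + d_s * (1 - frac)
  if (params$marker_noise_sd_mm > 0)
    y <- y + rnorm(n, 0, params$marker_noise_sd_mm)

  engaged <- load >= params$tendon_engage_N
  tendon <- ifelse(engaged, params$tendon_force_N, 0)
  if (params$tendon_noise_sd_N > 0)
    tendon[engaged] <- tendon[engaged] +
      rnorm(sum(engaged), 0, params$tendon_noise_sd_N)

  structure(
    list(specimen_id = specimen_id, group = params$group,
         foot_length_mm = l, peak_load_N = params$peak_load_N,
         sampling_rate_hz = params$sampling_rate_hz, seed = specimen_seed,
         samples = data.frame(time_s = time_s, load_N = load,
                              tendon_N = tendon, navicular_y_mm = y)),
    class = "specimen_trace",
    planted = list(trajectory = traj, inflection = traj$inflection,
                   offset = offset, delta = delta, deform_mult = dmult,
                   deformation_mm = d)
  )
}

#' @export
print.specimen_trace <- function(x, ...) {
  cat(sprintf("<specimen_trace> %s (group %s): %d samples @ %g Hz, foot length %.1f mm, peak load %g N\n",
              x$specimen_id, x$group, nrow(x$samples), x$sampling_rate_hz,
              x$foot_length_mm, x$peak_load_N))
  invisible(x)
}

# fixed arithmetic for per-specimen child seeds (documented, reproducible)
child_seed <- function(master_seed, group_index, specimen_index) {
  (as.numeric(master_seed) * 1009 + group_index * 101 +
     specimen_index) %% .Machine$integer.max
}

#' Simulate a multi-group cohort of specimen traces
#'
#' @param params_list named list of [generator_params()], one per group
#'   (default: the calibrated three-group experiment).
#' @param n_per_group specimens per group (>= 2 for group statistics; the
#'   experiment used 6).
#' @param master_seed master seed; per-specimen seeds are derived by fixed
#'   arithmetic so the cohort is fully reproducible.
#' @param outdir optional directory: when given, one trace CSV per specimen
#'   plus a `manifest.csv` are written there.
#' @return list with `traces` (list of `specimen_trace`) and `manifest`
#'   (data.frame: `specimen_id`, `group`, `foot_length_mm`, `peak_load_N`,
#'   `seed`).
#' @examples
#' coh <- simulate_cohort(default_cohort_params(total_cycles = 3),
#'                        n_per_group = 2, master_seed = 1)
#' coh$manifest
#' @export
simulate_cohort <- function(params_list = default_cohort_params(),
                            n_per_group = 6, master_seed = 1,
                            outdir = NULL) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (is.null(names(params_list)) || any(names(params_list) == ""))
    stop("params_list must be a named list (one entry per group)")
  traces <- list()
  rows <- list()
  for (gi in seq_along(params_list)) {
    p <- params_list[[gi]]
    for (si in seq_len(n_per_group)) {
      id <- sprintf("%s_%02d", p$group, si)
      if (!is.null(traces[[id]])) stop("duplicate specimen id: ", id)
      sd_i <- child_seed(master_seed, gi, si)
      tr <- simulate_specimen(p, specimen_seed = sd_i, specimen_id = id)
      traces[[id]] <- tr
      rows[[id]] <- data.frame(specimen_id = id, group = p$group,
                               foot_length_mm = tr$foot_length_mm,
                               peak_load_N = p$peak_load_N, seed = sd_i)
    }
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  if (n_per_group < 2)
    warning("n_per_group < 2: group confidence intervals will be undefined")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (tr in traces)
      write_trace(tr, file.path(outdir, paste0(tr$specimen_id, ".csv")))
    data.table::fwrite(manifest, file.path(outdir, "manifest.csv"))
  }
  list(traces = traces, manifest = manifest)
}

#' Read and write specimen trace files
#'
#' Trace files are UTF-8 CSV with a header row and columns `time_s`,
#' `load_N`, `tendon_N`, `navicular_y_mm`; specimen metadata travels in the
#' cohort manifest.
#'
#' @param trace a `specimen_trace`.
#' @param path file path.
#' @param specimen_id,group,foot_length_mm,peak_load_N,sampling_rate_hz
#'   metadata attached on read (typically from a manifest row); the sampling
#'   rate defaults to the observed time step.
#' @return `read_trace` returns a `specimen_trace`; `write_trace` returns the
#'   path invisibly.
#' @export
write_trace <- function(trace, path) {
  data.table::fwrite(trace$samples, path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path, specimen_id = NA_character_, group = NA_character_,
                       foot_length_mm = NA_real_, peak_load_N = NA_real_,
                       sampling_rate_hz = NULL) {
  s <- as.data.frame(data.table::fread(path))
  need <- c("time_s", "load_N", "tendon_N", "navicular_y_mm")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("trace file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(sampling_rate_hz)) {
    dt <- diff(s$time_s[seq_len(min(50, nrow(s)))])
    sampling_rate_hz <- if (length(dt)) 1 / stats::median(dt) else NA_real_
  }
  structure(list(specimen_id = specimen_id, group = group,
                 foot_length_mm = foot_length_mm, peak_load_N = peak_load_N,
                 sampling_rate_hz = sampling_rate_hz, seed = NA_integer_,
                 samples = s[need]),
            class = "specimen_trace")
}
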
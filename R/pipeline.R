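#' Pipeline run configuration
#'
#' Assembles (and validates) the configuration driving [run_pipeline()]:
#' which stages run, where inputs come from and outputs go, the checkpoint
#' grid, candidate polynomial orders, significance level, CI method and the
#' master seed. A configuration can equivalently be loaded from a YAML file
#' mirroring these fields (see `load_config()` and the packaged
#' `default_config.yaml`).
#'
#' @param outdir output directory.
#' @param stages stages to execute, in order, a subset of
#'   `c("generate", "segment", "metrics", "fit", "stats")`.
#' @param seed master seed.
#' @param n_per_group specimens per group when generating.
#' @param total_cycles cycles per specimen when generating.
#' @param groups named list of [generator_params()] (default: calibrated
#'   three-group experiment); ignored when `input_dir` supplies traces.
#' @param input_dir directory of existing trace CSVs plus `manifest.csv`
#'   (enables analysis of externally supplied data without generation).
#' @param checkpoints checkpoint grid (default: cycle 1 plus every 1000th).
#' @param orders candidate polynomial orders.
#' @param alpha significance level.
#' @param ci_method `"t"` or `"bootstrap"`.
#' @param wb_threshold weight-bearing threshold, N.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(outdir,
                            stages = c("generate", "segment", "metrics",
                                       "fit", "stats"),
                            seed = 1,
                            n_per_group = 6,
                            total_cycles = 10000,
                            groups = NULL,
                            input_dir = NULL,
                            checkpoints = NULL,
                            orders = 1:5,
                            alpha = 0.05,
                            ci_method = "t",
                            wb_threshold = 50) {
  known <- c("generate", "segment", "metrics", "fit", "stats")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(groups)) groups <- default_cohort_params(total_cycles = total_cycles)
  if (!is.null(input_dir) && !dir.exists(input_dir))
    stop("input_dir does not exist: ", input_dir)
  if (is.null(checkpoints)) checkpoints <- default_checkpoints(total_cycles)
  structure(list(outdir = outdir, stages = known[known %in% stages],
                 seed = seed, n_per_group = n_per_group,
                 total_cycles = total_cycles, groups = groups,
                 input_dir = input_dir, checkpoints = checkpoints,
                 orders = orders, alpha = alpha, ci_method = ci_method,
                 wb_threshold = wb_threshold),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] fields; per-group generator settings
#' sit under `groups:` and are passed to [generator_params()]. Fields not
#' present fall back to the defaults. See
#' `system.file("extdata", "default_config.yaml", package = "archfatigue")`.
#'
#' @param path YAML file.
#' @param outdir,seed optional overrides of the file's values.
#' @return list of class `run_config`.
#' @export
load_config <- function(path, outdir = NULL, seed = NULL) {
  y <- yaml::read_yaml(path)
  groups <- NULL
  if (!is.null(y$groups)) {
    groups <- lapply(names(y$groups), function(g) {
      args <- y$groups[[g]]
      args$group <- g
      if (!is.null(y$total_cycles) && is.null(args$total_cycles))
        args$total_cycles <- y$total_cycles
      do.call(generator_params, args)
    })
    names(groups) <- names(y$groups)
  }
  pipeline_config(
    outdir = if (!is.null(outdir)) outdir else y$outdir %||% "archfatigue_out",
    stages = y$stages %||% c("generate", "segment", "metrics", "fit", "stats"),
    seed = if (!is.null(seed)) seed else y$seed %||% 1,
    n_per_group = y$n_per_group %||% 6,
    total_cycles = y$total_cycles %||% 10000,
    groups = groups,
    input_dir = y$input_dir,
    checkpoints = unlist(y$checkpoints) %||% NULL,
    orders = unlist(y$orders) %||% 1:5,
    alpha = y$alpha %||% 0.05,
    ci_method = y$ci_method %||% "t",
    wb_threshold = y$wb_threshold %||% 50)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cheap FNV-1a content hash so outputs can state which configuration
# produced them without a cryptography dependency
config_hash <- function(config) {
  # analytic settings only: output locations do not change the analysis
  keep <- setdiff(names(config), c("groups", "outdir", "input_dir"))
  s <- paste(vapply(keep, function(k)
    paste0(k, "=", paste(deparse(config[[k]]), collapse = "")),
    character(1)), collapse = ";")
  for (g in names(config$groups)) {
    p <- config$groups[[g]]
    s <- paste0(s, "|", g, ":",
                paste(signif(p$trajectory$coefficients, 12), collapse = ","),
                ",", p$peak_load_N, ",", p$total_cycles, ",", p$offset_sd_bai,
                ",", p$jitter_sd_cycles, ",", p$d0_mm, ",", p$d_retained,
                ",", p$lof_r2)
  }
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order -- generate (or read) traces,
#' segment cycles, derive arch metrics, fit fatigue trajectories, run group
#' statistics -- writing every stage's tables under `config$outdir` together
#' with a run manifest recording inputs, outputs, seed, configuration hash
#' and warnings. A stage failure halts the run naming the stage and
#' offending specimen.
#'
#' @param config a `run_config` from [pipeline_config()] or [load_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) list with `manifest` (specimen table), `records`,
#'   `metrics`, `fits`, `stats`, `run_manifest` (file inventory), `outdir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  out <- config$outdir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  warnings_log <- character()
  note_warning <- function(stage, w) {
    warnings_log <<- c(warnings_log, sprintf("[%s] %s", stage, conditionMessage(w)))
    invokeRestart("muffleWarning")
  }
  header <- c(sprintf("seed: %s", config$seed),
              sprintf("config_hash: %s", hash),
              sprintf("archfatigue_version: %s", as.character(packageVersion("archfatigue"))))
  files <- character()
  emit <- function(path) files <<- c(files, path)

  # --- traces -------------------------------------------------------------
  traces <- NULL; manifest <- NULL
  if ("generate" %in% config$stages) {
    say("generate: %d specimens/group x %d cycles (seed %s)",
        config$n_per_group, config$total_cycles, config$seed)
    tr_dir <- file.path(out, "traces")
    coh <- withCallingHandlers(
      simulate_cohort(config$groups, n_per_group = config$n_per_group,
                      master_seed = config$seed, outdir = tr_dir),
      warning = function(w) note_warning("generate", w))
    traces <- coh$traces
    manifest <- coh$manifest
    for (id in names(traces)) emit(file.path(tr_dir, paste0(id, ".csv")))
    emit(file.path(tr_dir, "manifest.csv"))
  } else {
    if (is.null(config$input_dir))
      stop("stage 'generate' disabled and no input_dir given")
    mpath <- file.path(config$input_dir, "manifest.csv")
    if (!file.exists(mpath)) stop("missing manifest: ", mpath)
    manifest <- as.data.frame(data.table::fread(mpath))
    say("reading %d traces from %s", nrow(manifest), config$input_dir)
    traces <- lapply(seq_len(nrow(manifest)), function(i) {
      r <- manifest[i, ]
      read_trace(file.path(config$input_dir, paste0(r$specimen_id, ".csv")),
                 specimen_id = r$specimen_id, group = r$group,
                 foot_length_mm = r$foot_length_mm,
                 peak_load_N = r$peak_load_N)
    })
    names(traces) <- manifest$specimen_id
  }

  # --- segment ------------------------------------------------------------
  records <- NULL
  if (any(c("segment", "metrics", "fit", "stats") %in% config$stages)) {
    cyc_dir <- file.path(out, "cycles")
    dir.create(cyc_dir, showWarnings = FALSE)
    records <- list()
    for (id in names(traces)) {
      rec <- tryCatch(
        withCallingHandlers(
          segment_cycles(traces[[id]], wb_threshold = config$wb_threshold),
          warning = function(w) note_warning(paste0("segment/", id), w)),
        error = function(e) stop("stage 'segment' failed on specimen ", id,
                                 ": ", conditionMessage(e), call. = FALSE))
      records[[id]] <- rec
      emit(write_cycle_table(rec, file.path(cyc_dir, paste0(id, ".csv"))))
    }
    say("segment: %d specimens, %s cycles each", length(records),
        paste(range(vapply(records, nrow, numeric(1))), collapse = "-"))
  }

  # --- metrics ------------------------------------------------------------
  metrics <- NULL
  if (any(c("metrics", "fit", "stats") %in% config$stages)) {
    met_dir <- file.path(out, "metrics")
    dir.create(met_dir, showWarnings = FALSE)
    fl <- setNames(manifest$foot_length_mm, manifest$specimen_id)
    metrics <- list()
    for (id in names(records)) {
      m <- tryCatch(
        withCallingHandlers(
          arch_metrics(records[[id]], fl[[id]]),
          warning = function(w) note_warning(paste0("metrics/", id), w)),
        error = function(e) stop("stage 'metrics' failed on specimen ", id,
                                 ": ", conditionMessage(e), call. = FALSE))
      metrics[[id]] <- m
      emit(write_metrics_table(m, file.path(met_dir, paste0(id, ".csv"))))
    }
  }

  # --- fatigue fits -------------------------------------------------------
  fits <- NULL
  if ("fit" %in% config$stages) {
    cp <- config$checkpoints
    fits <- tryCatch(
      withCallingHandlers(
        fit_cohort(metrics, checkpoints = cp, orders = config$orders),
        warning = function(w) note_warning("fit", w)),
      error = function(e) stop("stage 'fit' failed: ", conditionMessage(e),
                               call. = FALSE))
    emit(write_fit_report(fits, file.path(out, "fatigue_fits.csv")))
    say("fit: selected orders %s",
        paste(sort(unique(fits$summary$selected_order)), collapse = ", "))
  }

  # --- statistics ---------------------------------------------------------
  stats_res <- NULL
  if ("stats" %in% config$stages) {
    stats_res <- tryCatch(
      withCallingHandlers(
        cohort_stats(metrics, manifest, checkpoints = config$checkpoints,
                     alpha = config$alpha, ci_method = config$ci_method),
        warning = function(w) note_warning("stats", w)),
      error = function(e) stop("stage 'stats' failed: ", conditionMessage(e),
                               call. = FALSE))
    emit(write_stats_report(stats_res, file.path(out, "stats"),
                            header = header))
  }

  run_manifest <- data.frame(
    file = c("(header)", files),
    info = c(paste(header, collapse = "; "), rep("", length(files))))
  mf <- file.path(out, "run_manifest.txt")
  writeLines(c(header,
               sprintf("elapsed_s: %.1f", as.numeric(Sys.time() - t0, units = "secs")),
               sprintf("stages: %s", paste(config$stages, collapse = ",")),
               "outputs:", paste0("  ", files),
               if (length(warnings_log)) c("warnings:", paste0("  ", warnings_log))
               else "warnings: none"),
             mf)
  say("done in %.1f s -> %s", as.numeric(Sys.time() - t0, units = "secs"), out)
  invisible(list(manifest = manifest, records = records, metrics = metrics,
                 fits = fits, stats = stats_res, run_manifest = run_manifest,
                 outdir = out))
}
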
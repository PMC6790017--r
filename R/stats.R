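#' Mean, SD and 95% confidence interval of a group sample
#'
#' Summaries are reported as mean and 95% CI. The default CI is the
#' t-interval `mean +/- t(0.975, n-1) * SD / sqrt(n)`; a percentile
#' bootstrap is available for skeptics of the normal-theory interval on
#' n = 6 samples.
#'
#' @param x numeric values (one per specimen).
#' @param conf confidence level (default 0.95).
#' @param method `"t"` (default) or `"bootstrap"` (percentile, `B` draws).
#' @param B bootstrap replicates.
#' @return one-row data.frame: `n`, `mean`, `sd`, `ci_lo`, `ci_hi`,
#'   `ci_defined`. With fewer than two values the CI is omitted
#'   (`ci_defined = FALSE`) and flagged with a warning.
#' @export
summarize_group <- function(x, conf = 0.95, method = c("t", "bootstrap"),
                            B = 2000) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 1) stop("no values to summarise")
  m <- mean(x)
  if (n < 2) {
    warning("n < 2: confidence interval undefined")
    return(data.frame(n = n, mean = m, sd = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_, ci_defined = FALSE))
  }
  s <- sd(x)
  if (method == "t") {
    hw <- qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n)
    lo <- m - hw; hi <- m + hw
  } else {
    bm <- vapply(seq_len(B),
                 function(i) mean(x[sample.int(n, n, replace = TRUE)]),
                 numeric(1))
    qs <- quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  data.frame(n = n, mean = m, sd = s, ci_lo = lo, ci_hi = hi,
             ci_defined = TRUE)
}

#' Normality screen
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution with the
#' sample's estimated mean and SD (the screen used before choosing
#' nonparametric group tests), or the Lilliefors-corrected variant which
#' accounts for the estimated parameters.
#'
#' @param x numeric values, n >= 3.
#' @param alpha significance level for the verdict.
#' @param method `"ks"` (default) or `"lilliefors"`.
#' @return one-row data.frame: `method`, `statistic`, `p`, `verdict`
#'   (`"normal"` / `"non-normal"` / `"degenerate"`).
#' @export
normality_screen <- function(x, alpha = 0.05, method = c("ks", "lilliefors")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("normality screen needs n >= 3 (got ", length(x), ")")
  if (sd(x) == 0) {
    warning("constant input: normality screen degenerate")
    return(data.frame(method = method, statistic = NA_real_, p = NA_real_,
                      verdict = "degenerate"))
  }
  ht <- if (method == "ks") {
    suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  } else {
    nortest::lillie.test(x)
  }
  data.frame(method = method, statistic = unname(ht$statistic),
             p = ht$p.value,
             verdict = ifelse(ht$p.value < alpha, "non-normal", "normal"))
}

#' Between-group comparison: Kruskal-Wallis with gatekept pairwise tests
#'
#' Omnibus Kruskal-Wallis rank test across groups; pairwise two-sample
#' rank-sum (Wilcoxon) tests, exact where the samples permit, are run only
#' when the omnibus test is significant (gatekeeping), with Bonferroni
#' adjustment over the number of pairwise comparisons.
#'
#' @param x metric values.
#' @param g group labels (same length as `x`).
#' @param pairwise run pairwise comparisons after a significant omnibus test?
#' @param alpha omnibus gate level.
#' @return data.frame of test rows: `test`, `comparison`, `statistic`,
#'   `p`, `p_adjusted`, `adjustment`. Pairwise rows appear only when the
#'   gate opens.
#' @export
between_group_test <- function(x, g, pairwise = TRUE, alpha = 0.05) {
  g <- factor(g)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs n >= 2")
  if (length(unique(x)) == 1L) {
    omni <- data.frame(test = "kruskal-wallis", comparison = "omnibus",
                       statistic = 0, p = 1, p_adjusted = NA_real_,
                       adjustment = NA_character_)
    return(omni)
  }
  kw <- kruskal.test(x, g)
  omni <- data.frame(test = "kruskal-wallis", comparison = "omnibus",
                     statistic = unname(kw$statistic), p = kw$p.value,
                     p_adjusted = NA_real_, adjustment = NA_character_)
  if (!pairwise || is.na(kw$p.value) || kw$p.value >= alpha) return(omni)

  lev <- levels(g)
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  k <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    xi <- x[g == pr[1]]; xj <- x[g == pr[2]]
    wt <- suppressWarnings(wilcox.test(xi, xj, exact = TRUE))
    data.frame(test = "rank-sum", comparison = paste(pr, collapse = " vs "),
               statistic = unname(wt$statistic), p = wt$p.value,
               p_adjusted = min(1, wt$p.value * k), adjustment = "bonferroni")
  })
  rbind(omni, do.call(rbind, rows))
}

#' Within-group time trend: Friedman test
#'
#' Friedman rank test of time-dependent change across checkpoints, blocking
#' on specimen. Requires complete blocks (every specimen observed at every
#' checkpoint).
#'
#' @param values data.frame with columns `specimen_id`, `cycle`, `value`
#'   (long format), or a numeric matrix with specimens as rows and
#'   checkpoints as columns.
#' @return one-row data.frame: `test`, `statistic`, `df`, `p`.
#' @export
within_group_trend_test <- function(values) {
  if (is.matrix(values)) {
    m <- values
  } else {
    need <- c("specimen_id", "cycle", "value")
    if (!all(need %in% names(values)))
      stop("long input needs columns specimen_id, cycle, value")
    sp <- sort(unique(values$specimen_id))
    cyc <- sort(unique(values$cycle))
    m <- matrix(NA_real_, length(sp), length(cyc),
                dimnames = list(sp, cyc))
    m[cbind(match(values$specimen_id, sp), match(values$cycle, cyc))] <-
      values$value
    if (anyNA(m)) {
      ij <- which(is.na(m), arr.ind = TRUE)[1, ]
      stop("incomplete block: specimen ", sp[ij[1]], " missing checkpoint ",
           cyc[ij[2]])
    }
  }
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need >= 2 specimens and >= 2 checkpoints")
  ft <- friedman.test(m)
  stat <- unname(ft$statistic); p <- ft$p.value
  if (is.nan(stat)) {   # no within-block variation at all
    warning("time-constant blocks: no rank variation, trend test degenerate")
    stat <- 0; p <- 1
  }
  data.frame(test = "friedman", statistic = stat,
             df = unname(ft$parameter), p = p)
}

#' Group checkpoint summaries across specimens
#'
#' Per group and checkpoint, the across-specimen mean, SD and 95% CI of each
#' arch metric.
#'
#' @param metrics_by_specimen named list of `arch_metrics` data.frames.
#' @param manifest data.frame mapping `specimen_id` to `group`.
#' @param checkpoints checkpoint cycles (default: grid of the shortest run).
#' @param metrics metric columns to summarise.
#' @param conf,method,B passed to [summarize_group()].
#' @return data.frame of class `group_series`: `group`, `cycle`, `metric`,
#'   `n`, `mean`, `sd`, `ci_lo`, `ci_hi`, `ci_defined`.
#' @export
group_series <- function(metrics_by_specimen, manifest,
                         checkpoints = NULL,
                         metrics = c("bai_wb", "flexibility_um_per_N",
                                     "energy_J"),
                         conf = 0.95, method = "t", B = 2000) {
  if (is.null(checkpoints)) {
    last <- min(vapply(metrics_by_specimen, function(m) max(m$cycle),
                       numeric(1)))
    checkpoints <- default_checkpoints(last)
  }
  grp <- setNames(as.character(manifest$group), manifest$specimen_id)
  rows <- list()
  for (gname in unique(grp)) {
    ids <- names(metrics_by_specimen)[grp[names(metrics_by_specimen)] == gname]
    for (cp in checkpoints) {
      for (met in metrics) {
        vals <- vapply(ids, function(id) {
          m <- metrics_by_specimen[[id]]
          i <- match(cp, m$cycle)
          if (is.na(i)) stop("specimen ", id, " lacks checkpoint ", cp)
          m[[met]][i]
        }, numeric(1))
        sm <- suppressWarnings(summarize_group(vals, conf = conf,
                                               method = method, B = B))
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(group = gname, cycle = cp, metric = met), sm)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("group_series", "data.frame")
  out
}

#' First checkpoint at which a group's arch is significantly low
#'
#' "Significantly below 0.21" is operationalised as the upper bound of the
#' group's 95% CI of weight-bearing BAI falling below the low-arch threshold.
#'
#' @param series a `group_series` data.frame.
#' @param threshold low-arch BAI threshold (0.21).
#' @param metric metric column screened (weight-bearing BAI).
#' @return data.frame: `group`, `onset_cycle` (`NA` when the group never
#'   drops significantly below the threshold).
#' @export
flag_low_arch_onset <- function(series, threshold = 0.21, metric = "bai_wb") {
  s <- series[series$metric == metric & series$ci_defined, , drop = FALSE]
  out <- lapply(split(s, s$group), function(d) {
    d <- d[order(d$cycle), ]
    hit <- which(d$ci_hi < threshold)
    data.frame(group = d$group[1],
               onset_cycle = if (length(hit)) d$cycle[hit[1]] else NA_real_)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Full group-comparison statistical battery for a cohort
#'
#' Reproduces the experiment's analysis: normality screening; Kruskal-Wallis
#' tests (with gatekept Bonferroni-adjusted pairwise rank-sum tests) of
#' first-cycle BAI, flexibility and energy absorption and of their
#' first-versus-last-cycle differences; Friedman within-group time trends;
#' group checkpoint summaries (mean, 95% CI); and the low-arch onset
#' checkpoint per group.
#'
#' @param metrics_by_specimen named list of `arch_metrics` data.frames.
#' @param manifest data.frame with `specimen_id` and `group`.
#' @param checkpoints checkpoint grid (default from the data).
#' @param alpha significance level.
#' @param ci_method `"t"` or `"bootstrap"` CIs.
#' @return list of class `cohort_stats`: `series` (group checkpoint
#'   summaries), `normality`, `first_cycle_tests`, `delta` (per-specimen
#'   deltas), `delta_tests`, `trend_tests`, `low_arch_onset`, `alpha`,
#'   `checkpoints`.
#' @export
cohort_stats <- function(metrics_by_specimen, manifest, checkpoints = NULL,
                         alpha = 0.05, ci_method = "t") {
  if (is.null(checkpoints)) {
    last <- min(vapply(metrics_by_specimen, function(m) max(m$cycle),
                       numeric(1)))
    checkpoints <- default_checkpoints(last)
  }
  grp <- setNames(as.character(manifest$group), manifest$specimen_id)
  ids <- names(metrics_by_specimen)
  metcols <- c(bai = "bai_wb", flexibility = "flexibility_um_per_N",
               energy = "energy_J")

  series <- group_series(metrics_by_specimen, manifest,
                         checkpoints = checkpoints, method = ci_method)

  first_vals <- lapply(metcols, function(col)
    vapply(ids, function(id) {
      m <- metrics_by_specimen[[id]]
      m[[col]][match(1, m$cycle)]
    }, numeric(1)))
  gvec <- grp[ids]

  normality <- do.call(rbind, lapply(names(metcols), function(nm) {
    cbind(metric = nm,
          normality_screen(first_vals[[nm]], alpha = alpha))
  }))

  first_tests <- do.call(rbind, lapply(names(metcols), function(nm) {
    cbind(metric = nm,
          between_group_test(first_vals[[nm]], gvec, alpha = alpha))
  }))

  endpoints <- c(min(checkpoints), max(checkpoints))
  deltas <- do.call(rbind, lapply(ids, function(id)
    compute_deltas(metrics_by_specimen[[id]], cycles = endpoints,
                   specimen_id = id)))
  deltas$group <- grp[deltas$specimen_id]
  dcols <- c(bai = "delta_bai", flexibility = "delta_flexibility_um_per_N",
             energy = "delta_energy_J")
  delta_tests <- do.call(rbind, lapply(names(dcols), function(nm) {
    cbind(metric = nm,
          between_group_test(deltas[[dcols[nm]]], deltas$group, alpha = alpha))
  }))

  trend <- list()
  for (gname in unique(gvec)) {
    gids <- ids[gvec == gname]
    for (nm in names(metcols)) {
      long <- do.call(rbind, lapply(gids, function(id) {
        m <- metrics_by_specimen[[id]]
        i <- match(checkpoints, m$cycle)
        data.frame(specimen_id = id, cycle = checkpoints,
                   value = m[[metcols[nm]]][i])
      }))
      trend[[length(trend) + 1L]] <-
        cbind(group = gname, metric = nm, within_group_trend_test(long))
    }
  }
  trend_tests <- do.call(rbind, trend)

  structure(list(series = series, normality = normality,
                 first_cycle_tests = first_tests,
                 delta = deltas, delta_tests = delta_tests,
                 trend_tests = trend_tests,
                 low_arch_onset = flag_low_arch_onset(series),
                 alpha = alpha, checkpoints = checkpoints),
            class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("<cohort_stats>\n")
  cat("  low-arch onset (CI upper bound < 0.21):\n")
  for (i in seq_len(nrow(x$low_arch_onset)))
    cat(sprintf("    %-8s %s\n", x$low_arch_onset$group[i],
                ifelse(is.na(x$low_arch_onset$onset_cycle[i]), "never",
                       sprintf("cycle %g", x$low_arch_onset$onset_cycle[i]))))
  cat("  within-group Friedman trends:\n")
  for (i in seq_len(nrow(x$trend_tests)))
    cat(sprintf("    %-8s %-12s chi2 = %7.2f, p = %.3g\n",
                x$trend_tests$group[i], x$trend_tests$metric[i],
                x$trend_tests$statistic[i], x$trend_tests$p[i]))
  omni <- x$first_cycle_tests[x$first_cycle_tests$comparison == "omnibus", ]
  cat("  first-cycle Kruskal-Wallis:",
      paste(sprintf("%s p = %.3g", omni$metric, omni$p), collapse = ", "), "\n")
  invisible(x)
}

#' Write the statistics report (CSV tables plus a readable summary)
#'
#' @param stats a `cohort_stats` object.
#' @param dir output directory (created if needed).
#' @param header optional character vector of comment lines (seed, config
#'   hash) prepended to the text report.
#' @return the directory, invisibly.
#' @export
write_stats_report <- function(stats, dir, header = character()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(as.data.frame(stats$series),
                     file.path(dir, "group_series.csv"))
  data.table::fwrite(stats$normality, file.path(dir, "normality.csv"))
  data.table::fwrite(stats$first_cycle_tests,
                     file.path(dir, "first_cycle_tests.csv"))
  data.table::fwrite(stats$delta, file.path(dir, "deltas.csv"))
  data.table::fwrite(stats$delta_tests, file.path(dir, "delta_tests.csv"))
  data.table::fwrite(stats$trend_tests, file.path(dir, "trend_tests.csv"))
  data.table::fwrite(stats$low_arch_onset, file.path(dir, "low_arch_onset.csv"))
  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", header), capture_print(stats)), con)
  invisible(dir)
}

capture_print <- function(x) utils::capture.output(print(x))
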
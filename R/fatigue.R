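#' Least-squares polynomial fit of a cycle series
#'
#' Fits `value ~ poly(cycle, order)` by least squares. Because cycle indices
#' span 1..10,000, the design matrix is built on an internally scaled
#' abscissa and the coefficients are transformed back to the raw cycle
#' scale; predictions and inflection points are invariant to the internal
#' scale.
#'
#' @param cycle,value the series (equal length; cycles distinct; at least
#'   `order + 2` points).
#' @param order polynomial order `p >= 0`.
#' @param scale internal abscissa scale (default: `max(abs(cycle))`).
#' @return list with `order`, `coefficients` (named `b0`..`bp`, raw scale),
#'   `fitted`, `residuals`, `se` (residual sum of squares), `r2`, `n`, and
#'   `r2_degenerate` (`TRUE` when the series is constant, in which case
#'   `r2` is reported as 1 and flagged).
#' @export
fit_polynomial <- function(cycle, value, order, scale = NULL) {
  if (length(cycle) != length(value)) stop("cycle and value lengths differ")
  if (anyDuplicated(cycle)) stop("cycle values must be distinct")
  n <- length(value)
  if (n <= order + 1)
    stop("need more than order + 1 = ", order + 1, " points (got ", n, ")")
  if (is.null(scale)) scale <- max(abs(cycle), 1)
  z <- cycle / scale
  X <- outer(z, 0:order, `^`)
  fit <- lm.fit(X, value)
  if (fit$rank < order + 1)
    stop("rank-deficient design: polynomial order ", order,
         " is not identifiable from these cycles")
  bz <- fit$coefficients
  b <- setNames(as.numeric(bz) / scale^(0:order), paste0("b", 0:order))
  res <- as.numeric(fit$residuals)
  se <- sum(res^2)
  tss <- sum((value - mean(value))^2)
  degenerate <- tss <= .Machine$double.eps * n
  r2 <- if (degenerate) 1 else 1 - se / tss
  list(order = order, coefficients = b, fitted = as.numeric(fit$fitted.values),
       residuals = res, se = se, r2 = r2, n = n, r2_degenerate = degenerate)
}

#' Gaussian AIC for a polynomial fit
#'
#' `AIC = n {log(2 pi Se / n) + 1} + 2 (p + 1)` with `n` fitted points,
#' residual sum of squares `Se`, polynomial order `p`, natural logarithm.
#' A zero residual sum of squares makes the log undefined; it is floored at
#' a tiny epsilon with a warning (interpolating fits then rank by the
#' parameter penalty alone).
#'
#' @param se residual sum of squares.
#' @param n number of fitted points.
#' @param p polynomial order.
#' @param se_floor epsilon floor applied to `se`.
#' @return the AIC value.
#' @export
polynomial_aic <- function(se, n, p, se_floor = 1e-30) {
  if (se < se_floor) {
    warning("residual sum of squares below ", se_floor,
            "; AIC computed at the epsilon floor")
    se <- se_floor
  }
  n * (log(2 * pi * se / n) + 1) + 2 * (p + 1)
}

#' Fit candidate polynomial orders and select by AIC
#'
#' Fits every candidate order, scores each with the Gaussian AIC
#' (see [polynomial_aic()]), and selects the minimiser; ties break toward
#' the smaller order. For the selected fit of order >= 2 the inflection
#' point(s) -- roots of the second derivative inside the observed cycle
#' range -- are located (for a cubic, `-b2 / (3 b3)`).
#'
#' @param cycle,value the series to fit.
#' @param orders candidate polynomial orders (default `1:5`; on the standard
#'   11-point checkpoint grid, 5 is the largest order leaving a residual).
#' @return object of class `fatigue_fit`: list with `fits` (per-order results
#'   from [fit_polynomial()]), `table` (order, se, aic, r2, selected),
#'   `selected_order`, `coefficients`, `r2`, `inflection` (numeric, possibly
#'   length 0), `cycle_range`, `n`.
#' @examples
#' p <- generator_params("obese")
#' cyc <- default_checkpoints()
#' fit <- aic_select(cyc, eval_trajectory(p$trajectory, cyc) + rnorm(11, 0, 1e-3))
#' fit$selected_order
#' @export
aic_select <- function(cycle, value, orders = 1:5) {
  if (length(orders) < 1) stop("no candidate orders")
  orders <- sort(unique(as.integer(orders)))
  fits <- lapply(orders, function(p) fit_polynomial(cycle, value, p))
  # floor Se relative to the series variance so that fits with numerically
  # zero residual share one floor and rank by the parameter penalty alone
  tss <- sum((value - mean(value))^2)
  floor_v <- max(1e-10 * tss, 1e-30)
  se_all <- vapply(fits, `[[`, numeric(1), "se")
  if (any(se_all < floor_v))
    warning("residual sum of squares ~ 0 for order(s) ",
            paste(orders[se_all < floor_v], collapse = ", "),
            "; AIC computed at the epsilon floor")
  aic <- vapply(seq_along(fits), function(i)
    suppressWarnings(polynomial_aic(max(se_all[i], floor_v),
                                    fits[[i]]$n, orders[i],
                                    se_floor = floor_v)),
    numeric(1))
  sel <- which.min(aic)           # first minimum = smallest order on ties
  tab <- data.frame(order = orders,
                    se = vapply(fits, `[[`, numeric(1), "se"),
                    aic = aic,
                    r2 = vapply(fits, `[[`, numeric(1), "r2"),
                    selected = seq_along(orders) == sel)
  best <- fits[[sel]]
  rng <- range(cycle)
  infl <- if (best$order >= 2) {
    inflection_point(best$coefficients, rng)
  } else numeric(0)
  structure(list(fits = setNames(fits, paste0("order_", orders)),
                 table = tab, selected_order = best$order,
                 coefficients = best$coefficients, r2 = best$r2,
                 se = best$se, inflection = infl, cycle_range = rng,
                 n = best$n),
            class = "fatigue_fit")
}

#' Inflection points of a fitted polynomial
#'
#' Real roots of the second derivative of the polynomial that lie within the
#' observed cycle range, in ascending order. For a cubic with `b3 != 0` this
#' is the single point `-b2 / (3 b3)`; a "cubic" with `b3 == 0` has none
#' (warned). For higher orders, repeated roots are reported once with a
#' `multiplicity` attribute.
#'
#' @param coefficients polynomial coefficients `b0..bp` (raw cycle scale).
#' @param cycle_range length-2 numeric: admissible cycle range.
#' @param tol relative tolerance for treating a root as real.
#' @return numeric vector (possibly empty) of inflection cycles, ascending.
#' @examples
#' inflection_point(c(0, 0, -3, 1), c(-5, 5))  # x^3 - 3 x^2 -> 1
#' @export
inflection_point <- function(coefficients, cycle_range, tol = 1e-8) {
  b <- as.numeric(coefficients)
  p <- length(b) - 1
  if (p < 2) return(numeric(0))
  if (p == 3 && b[4] == 0) {
    warning("cubic term is zero; no inflection point")
    return(numeric(0))
  }
  d2 <- poly_deriv(poly_deriv(b))
  if (all(d2 == 0) || length(d2) == 1) return(numeric(0))
  if (length(d2) == 2) {                 # linear second derivative (cubic fit)
    root <- -d2[1] / d2[2]
    roots <- root
  } else {
    # scale for numerical stability of polyroot on wide cycle ranges
    s <- max(abs(cycle_range), 1)
    d2s <- d2 * s^(seq_along(d2) - 1)
    rt <- polyroot(d2s)
    keep <- abs(Im(rt)) <= tol * (1 + abs(Re(rt)))
    roots <- Re(rt[keep]) * s
  }
  roots <- roots[roots >= min(cycle_range) & roots <= max(cycle_range)]
  if (!length(roots)) return(numeric(0))
  roots <- sort(roots)
  grp <- cumsum(c(1, diff(roots) > tol * max(abs(roots), 1)))
  out <- as.numeric(tapply(roots, grp, mean))
  mult <- as.integer(table(grp))
  if (any(mult > 1)) attr(out, "multiplicity") <- mult
  out
}

#' @export
print.fatigue_fit <- function(x, ...) {
  cat(sprintf("<fatigue_fit> %d points, candidate orders {%s}\n",
              x$n, paste(x$table$order, collapse = ", ")))
  cat(sprintf("  selected order %d by AIC (AIC %.2f, R^2 %.4f)\n",
              x$selected_order, min(x$table$aic), x$r2))
  if (length(x$inflection))
    cat(sprintf("  inflection point(s): %s cycles\n",
                paste(round(x$inflection, 1), collapse = ", ")))
  else cat("  no in-range inflection point\n")
  invisible(x)
}

#' Fit fatigue trajectories for every specimen of a cohort
#'
#' Extracts the weight-bearing BAI checkpoint series per specimen, runs
#' [aic_select()] on each, and collects selected orders, R^2 and inflection
#' cycles. Per-specimen fitting (rather than fitting the pooled group mean)
#' is what yields an across-specimen SD of the inflection point.
#'
#' Two order-selection policies are available. The default, `"cohort"`,
#' mirrors how a single model order is chosen for a whole experiment: the
#' order minimising the summed AIC over all specimens (the joint-likelihood
#' criterion under a common order) is used for every specimen's reported fit
#' and inflection point, while each specimen's own AIC pick is still recorded
#' in `selected_order`. `"specimen"` instead reports each specimen's own
#' AIC-selected fit; note that a specimen whose inflection sits near the end
#' of the observed range carries little in-range curvature, so per-specimen
#' selection tends to drop to order 2 exactly for the latest inflections and
#' thereby censors (biases down) the across-specimen inflection mean.
#'
#' @param metrics_by_specimen named list of `arch_metrics` data.frames.
#' @param checkpoints cycle grid on which to fit (default: cycle 1 plus every
#'   1000th cycle).
#' @param orders candidate polynomial orders.
#' @param series which metric column to fit (default weight-bearing BAI).
#' @param order_selection `"cohort"` (default) or `"specimen"`, see Details.
#' @return list with `fits` (named list of `fatigue_fit`), `consensus_order`
#'   (the summed-AIC minimiser), and `summary` (data.frame: `specimen_id`,
#'   `selected_order` -- the specimen's own AIC pick --, `fit_order` -- the
#'   order of the reported fit --, `se`, `aic`, `r2`, `inflection_cycle`,
#'   `NA` when the reported fit has no in-range inflection).
#' @export
fit_cohort <- function(metrics_by_specimen,
                       checkpoints = NULL, orders = 1:5,
                       series = "bai_wb",
                       order_selection = c("cohort", "specimen")) {
  order_selection <- match.arg(order_selection)
  fits <- list()
  aic_mat <- NULL
  used_orders <- NULL
  for (id in names(metrics_by_specimen)) {
    m <- metrics_by_specimen[[id]]
    cp <- if (is.null(checkpoints)) default_checkpoints(max(m$cycle)) else checkpoints
    idx <- match(cp, m$cycle)
    if (anyNA(idx))
      stop("specimen ", id, ": checkpoint(s) ",
           paste(cp[is.na(idx)], collapse = ", "), " missing from metrics")
    feasible <- orders[orders + 1 < length(cp)]
    if (!length(feasible))
      stop("specimen ", id, ": no candidate order is identifiable from ",
           length(cp), " checkpoints")
    if (length(feasible) < length(orders) && id == names(metrics_by_specimen)[1])
      warning("candidate order(s) ", paste(setdiff(orders, feasible), collapse = ", "),
              " dropped: not identifiable from ", length(cp), " checkpoints")
    f <- aic_select(cp, m[[series]][idx], orders = feasible)
    fits[[id]] <- f
    if (is.null(aic_mat)) {
      used_orders <- f$table$order
      aic_mat <- matrix(NA_real_, 0, length(used_orders))
    }
    aic_mat <- rbind(aic_mat, f$table$aic)
  }
  consensus <- used_orders[which.min(colSums(aic_mat))]

  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    fo <- if (order_selection == "cohort") consensus else f$selected_order
    ff <- f$fits[[paste0("order_", fo)]]
    infl <- if (fo >= 2) {
      inflection_point(ff$coefficients, f$cycle_range)
    } else numeric(0)
    data.frame(
      specimen_id = id, selected_order = f$selected_order, fit_order = fo,
      se = ff$se, aic = f$table$aic[f$table$order == fo], r2 = ff$r2,
      inflection_cycle = if (length(infl)) infl[1] else NA_real_)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(fits = fits, consensus_order = consensus, summary = summary)
}

#' Write a cohort fit report
#'
#' One row per specimen and candidate order with coefficients, residual sum
#' of squares, AIC, R^2, selection flag and inflection cycle.
#'
#' @param cohort_fit result of [fit_cohort()].
#' @param path CSV path.
#' @return the path, invisibly.
#' @export
write_fit_report <- function(cohort_fit, path) {
  smry <- cohort_fit$summary
  rows <- list()
  for (id in names(cohort_fit$fits)) {
    f <- cohort_fit$fits[[id]]
    srow <- smry[smry$specimen_id == id, ]
    for (fo in f$fits) {
      co <- setNames(rep(NA_real_, 6), paste0("b", 0:5))
      co[names(fo$coefficients)] <- fo$coefficients
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = id, order = fo$order, t(co), se = fo$se,
        aic = f$table$aic[f$table$order == fo$order],
        r2 = fo$r2,
        aic_pick = fo$order == srow$selected_order,
        selected = fo$order == srow$fit_order,
        inflection_cycle = if (fo$order == srow$fit_order)
          srow$inflection_cycle else NA_real_)
    }
  }
  data.table::fwrite(do.call(rbind, rows), path)
  invisible(path)
}
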
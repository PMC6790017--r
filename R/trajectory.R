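#' Trajectory constraints for cubic calibration
#'
#' Helper constructors for the linear constraints accepted by
#' [calibrate_trajectory()]. A constraint pins the value, first derivative or
#' second derivative of the cubic \eqn{B(c) = b_0 + b_1 c + b_2 c^2 + b_3 c^3}
#' at one cycle index.
#'
#' @param x cycle index at which the constraint applies.
#' @param y required value of the function (or derivative) at `x`.
#' @return A one-row data.frame with columns `type`, `x`, `y`.
#' @examples
#' traj_value(1000, 0.203)
#' traj_d2(6500, 0)
#' @export
traj_value <- function(x, y) data.frame(type = "value", x = x, y = y)

#' @rdname traj_value
#' @export
traj_d1 <- function(x, y) data.frame(type = "d1", x = x, y = y)

#' @rdname traj_value
#' @export
traj_d2 <- function(x, y) data.frame(type = "d2", x = x, y = y)

as_constraint_df <- function(constraints) {
  if (is.data.frame(constraints)) {
    df <- constraints
  } else if (is.list(constraints)) {
    df <- do.call(rbind, lapply(constraints, function(k) {
      if (is.data.frame(k)) k else data.frame(type = k$type, x = k$x, y = k$y)
    }))
  } else {
    stop("constraints must be a data.frame or a list of constraints")
  }
  if (!all(c("type", "x", "y") %in% names(df))) {
    stop("each constraint needs fields 'type', 'x', 'y'")
  }
  bad <- setdiff(df$type, c("value", "d1", "d2"))
  if (length(bad)) stop("unknown constraint type(s): ", paste(bad, collapse = ", "))
  df
}

# One row of the (scaled) design matrix for a constraint.  The system is
# solved on z = x / scale to keep the Vandermonde conditioning sane when
# cycle indices span 1..10,000; coefficients are returned on the raw scale.
constraint_row <- function(type, z) {
  switch(type,
    value = c(1, z, z^2, z^3),
    d1    = c(0, 1, 2 * z, 3 * z^2),
    d2    = c(0, 0, 2, 6 * z)
  )
}

#' Calibrate a cubic BAI-versus-cycle trajectory from linear constraints
#'
#' Solves for the unique cubic \eqn{B(c)} satisfying exactly four independent
#' linear constraints on its value, slope or curvature (e.g. an initial BAI,
#' a printed group mean at a given cycle, and a stationary inflection point).
#' This is how the synthetic generator turns published group-level anchor
#' values into a smooth creep trajectory.
#'
#' @param constraints four constraints built with [traj_value()], [traj_d1()],
#'   [traj_d2()] (a data.frame or a list of them).
#' @param range cycle range over which the trajectory is used; monotonicity is
#'   enforced on this interval.
#' @param monotone one of `"non-increasing"` (default, the physical
#'   expectation for a creeping arch), `"none"`.
#' @param scale internal abscissa scale for conditioning (default `1e4`).
#' @return An object of class `arch_cubic`: a list with `coefficients`
#'   (named `b0`..`b3`, raw-cycle scale), `inflection` (root of the second
#'   derivative, or `NA` if the cubic term vanishes), `range`, and the
#'   constraint table.
#' @details If the constraint system is singular the error message names the
#'   linearly dependent constraints. If the solution is not monotone in the
#'   requested direction on `range`, it is rejected with a diagnostic giving
#'   the location and magnitude of the violation.
#' @examples
#' # a stationary (saddle) inflection guarantees monotonicity:
#' tr <- calibrate_trajectory(rbind(
#'   traj_value(1, 0.24), traj_value(1000, 0.203),
#'   traj_d1(6500, 0), traj_d2(6500, 0)
#' ))
#' tr$inflection
#' eval_trajectory(tr, c(1, 1000, 10000))
#' @export
calibrate_trajectory <- function(constraints, range = c(1, 10000),
                                 monotone = c("non-increasing", "none"),
                                 scale = 1e4) {
  monotone <- match.arg(monotone)
  df <- as_constraint_df(constraints)
  if (nrow(df) != 4) {
    stop("exactly 4 constraints are required to determine a cubic (got ",
         nrow(df), ")")
  }
  A <- t(vapply(seq_len(4),
                function(i) constraint_row(df$type[i], df$x[i] / scale),
                numeric(4)))
  # derivative constraints are with respect to z = x/scale; rescale the rhs
  pw <- c(value = 0, d1 = 1, d2 = 2)[df$type]
  rhs <- df$y * scale^pw

  qrA <- qr(A)
  if (qrA$rank < 4) {
    dep <- sort(qrA$pivot[seq.int(qrA$rank + 1, 4)])
    stop("singular constraint system: constraint(s) ",
         paste(dep, collapse = ", "),
         " are linearly dependent on the others")
  }
  bz <- solve(qrA, rhs)
  bz[abs(bz) < 1e-10 * max(abs(bz), 1)] <- 0   # numerically-zero terms
  b <- as.numeric(bz) / scale^(0:3)
  names(b) <- paste0("b", 0:3)

  obj <- structure(
    list(coefficients = b,
         inflection = cubic_inflection(b),
         range = range,
         constraints = df),
    class = "arch_cubic"
  )

  if (monotone == "non-increasing") {
    viol <- max_slope_on(b, range)
    if (viol$slope > 1e-10 * max(1, abs(b[1]))) {
      stop(sprintf(paste0(
        "calibrated cubic is not monotonically non-increasing on [%g, %g]: ",
        "slope %.3e at cycle %.1f; adjust the anchors ",
        "(a stationary inflection, B'(chi0) = 0, always yields a monotone cubic)"),
        range[1], range[2], viol$slope, viol$at))
    }
  }
  obj
}

# maximum of B'(c) on [range]: quadratic in c, check vertex + endpoints
max_slope_on <- function(b, range) {
  d1 <- function(x) b[2] + 2 * b[3] * x + 3 * b[4] * x^2
  cand <- range
  if (abs(b[4]) > 0) {
    vx <- -b[3] / (3 * b[4])   # vertex of the slope parabola
    if (vx >= range[1] && vx <= range[2]) cand <- c(cand, vx)
  }
  s <- d1(cand)
  i <- which.max(s)
  list(slope = unname(s[i]), at = unname(cand[i]))
}

#' Evaluate a cubic trajectory (or raw coefficients) at cycle indices
#'
#' @param traj an `arch_cubic` object or a numeric vector of polynomial
#'   coefficients in increasing order.
#' @param x cycle indices.
#' @return numeric vector of trajectory values.
#' @export
eval_trajectory <- function(traj, x) {
  b <- if (inherits(traj, "arch_cubic")) traj$coefficients else traj
  eval_poly(b, x)
}

eval_poly <- function(b, x) {
  b <- unname(b)
  y <- numeric(length(x))
  for (k in rev(seq_along(b))) y <- y * x + b[k]   # Horner
  y
}

# coefficients of the derivative polynomial
poly_deriv <- function(b) {
  if (length(b) <= 1) return(0)
  b[-1] * seq_len(length(b) - 1)
}

#' Inflection point of a cubic
#'
#' For a cubic with coefficients \eqn{b_0..b_3} (and \eqn{b_3 \ne 0}), the
#' unique root of the second derivative is \eqn{\chi_0 = -b_2 / (3 b_3)}.
#'
#' @param b numeric vector of cubic coefficients `b0..b3`.
#' @return the inflection cycle, or `NA_real_` if `b3 == 0`.
#' @export
cubic_inflection <- function(b) {
  if (length(b) < 4 || b[4] == 0) return(NA_real_)
  unname(-b[3] / (3 * b[4]))
}

#' @export
print.arch_cubic <- function(x, ...) {
  b <- x$coefficients
  cat("<arch_cubic> B(c) = b0 + b1*c + b2*c^2 + b3*c^3\n")
  cat(sprintf("  coefficients: %s\n",
              paste(sprintf("%s=%.6g", names(b), b), collapse = ", ")))
  cat(sprintf("  range: [%g, %g]   inflection: %s\n", x$range[1], x$range[2],
              ifelse(is.na(x$inflection), "none",
                     sprintf("%.1f cycles", x$inflection))))
  v <- eval_poly(b, x$range)
  cat(sprintf("  B(%g) = %.4f, B(%g) = %.4f\n",
              x$range[1], v[1], x$range[2], v[2]))
  invisible(x)
}
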
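test_that("exact and degenerate polynomial fits behave as specified", {
  x <- 1:8
  f <- fit_polynomial(x, 2 + 3 * x, 1)
  expect_equal(unname(f$coefficients), c(2, 3), tolerance = 1e-10)
  expect_equal(f$se, 0, tolerance = 1e-18)
  expect_equal(f$r2, 1)

  fc <- fit_polynomial(x, rep(5, 8), 2)
  expect_true(fc$r2_degenerate)
  expect_equal(fc$r2, 1)   # flagged degenerate variance

  expect_error(fit_polynomial(1:4, 1:4, 3), "more than order")
  expect_error(fit_polynomial(c(1, 1, 2), c(1, 2, 3), 1), "distinct")
})

test_that("least squares agrees with an independent normal-equations solve", {
  set.seed(42)
  for (rep in 1:5) {
    x <- seq(0.5, 10, length.out = 11)
    b_true <- rnorm(4)
    y <- eval_trajectory(b_true, x) + rnorm(11, 0, 0.2)
    f <- fit_polynomial(x, y, 3)
    oracle <- normal_equations_fit(x, y, 3)
    expect_equal(unname(f$coefficients), oracle, tolerance = 1e-7)
  }
})

test_that("coefficients returned on the raw cycle scale survive wide abscissae", {
  cyc <- default_checkpoints()
  b_true <- generator_params("obese")$trajectory$coefficients
  y <- eval_trajectory(b_true, cyc)
  f <- fit_polynomial(cyc, y, 3)
  expect_equal(unname(f$coefficients), unname(b_true), tolerance = 1e-6)
  # fit is invariant to the internal abscissa scaling
  f2 <- fit_polynomial(cyc, y, 3, scale = 173)
  expect_equal(f2$fitted, f$fitted, tolerance = 1e-9)
  expect_equal(cubic_inflection(f2$coefficients),
               cubic_inflection(f$coefficients), tolerance = 1e-4)
})

test_that("reported AIC equals the Gaussian formula to machine precision", {
  set.seed(42)
  for (rep in 1:10) {
    n <- sample(8:30, 1)
    x <- seq_len(n)
    y <- rnorm(n, 10 - 0.3 * x + 0.01 * x^2, 0.5)
    orders <- 1:4
    sel <- aic_select(x, y, orders)
    for (i in seq_along(orders)) {
      f <- sel$fits[[i]]
      expect_equal(sel$table$aic[i],
                   n * (log(2 * pi * f$se / n) + 1) + 2 * (orders[i] + 1),
                   tolerance = 1e-12)
    }
    expect_equal(sel$selected_order, sel$table$order[which.min(sel$table$aic)])
  }
})

test_that("AIC selection finds the generating order and breaks ties downward", {
  set.seed(42)
  x <- seq(1, 100, length.out = 20)
  # under a linear truth AIC occasionally pays the small penalty for a spare
  # order, but the modal selection over replicates is the generating order
  picks <- replicate(50, aic_select(x, 5 - 0.02 * x + rnorm(20, 0, 0.05))$selected_order)
  expect_equal(as.integer(names(which.max(table(picks)))), 1)
  expect_gt(mean(picks == 1), 0.45)
  y_lin <- 5 - 0.02 * x + rnorm(20, 0, 0.05)
  expect_equal(aic_select(x, y_lin, orders = 4)$selected_order, 4)  # single candidate
  # an exactly interpolated series floors Se; penalty then prefers order 3
  y_cub <- 1 + x - 0.1 * x^2 + 0.001 * x^3
  sel <- suppressWarnings(aic_select(x, y_cub, orders = 3:5))
  expect_equal(sel$selected_order, 3)
})

test_that("inflection points come from the second derivative inside the range", {
  expect_equal(inflection_point(c(0, 0, -3, 1), c(-5, 5)), 1)  # x^3 - 3x^2
  expect_warning(out <- inflection_point(c(1, 2, -1, 0), c(-5, 5)), "cubic term")
  expect_length(out, 0)
  expect_length(inflection_point(c(0, 0, -30, 1), c(-5, 5)), 0) # root 10 off-range
  set.seed(42)
  for (i in 1:25) {
    b <- rnorm(4); if (abs(b[4]) < 0.1) b[4] <- sign(b[4] + 0.01) * 0.5
    chi <- -b[3] / (3 * b[4])
    got <- inflection_point(b, chi + c(-1, 1))
    expect_equal(got, chi, tolerance = 1e-8)
  }
  # quartic with two in-range roots, ascending: y = x^4 - 2x^2 -> d2 roots +-1/sqrt(3)
  r <- inflection_point(c(0, 0, -2, 0, 1), c(-2, 2))
  expect_equal(r, c(-1, 1) / sqrt(3), tolerance = 1e-8)
})

test_that("noise-free cohort round-trips the planted cubic and inflection", {
  p <- noise_free_params("obese", total_cycles = 10000)
  tr <- simulate_specimen(p, specimen_seed = 6)
  m <- arch_metrics(segment_cycles(tr), tr$foot_length_mm)
  cp <- default_checkpoints()
  sel <- suppressWarnings(aic_select(cp, m$bai_wb[match(cp, m$cycle)]))
  expect_equal(sel$selected_order, 3)
  expect_equal(unname(sel$coefficients),
               unname(p$trajectory$coefficients), tolerance = 1e-6)
  expect_equal(sel$inflection, 6500, tolerance = 0.5)
  expect_equal(sel$r2, 1, tolerance = 1e-9)
})

test_that("fit_cohort summarises per-specimen fits and guards its inputs", {
  coh <- simulate_cohort(default_cohort_params(total_cycles = 100),
                         n_per_group = 2, master_seed = 13)
  mets <- cohort_metrics(coh)
  fc <- suppressWarnings(fit_cohort(mets, checkpoints = c(1, seq(10, 100, 10))))
  expect_equal(nrow(fc$summary), 6)
  expect_true(all(fc$summary$selected_order %in% 1:5))
  expect_error(fit_cohort(mets, checkpoints = c(1, 150)), "missing")
  expect_error(suppressWarnings(fit_cohort(mets, checkpoints = c(1, 50, 100),
                                           orders = 4)), "no candidate order")
})
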
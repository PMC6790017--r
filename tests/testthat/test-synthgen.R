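test_that("noise-free specimen reproduces the group trajectory exactly", {
  p <- noise_free_params("obese", total_cycles = 60)
  tr <- simulate_specimen(p, specimen_seed = 1)
  rec <- segment_cycles(tr)
  expect_equal(nrow(rec), 60)
  expect_equal(rec$peak_load_N, rep(1000, 60))          # exact peak load
  bai <- compute_bai(rec$h_wb_mm, tr$foot_length_mm)
  expect_equal(bai, eval_trajectory(p$trajectory, 1:60), tolerance = 1e-10)
  # planted deformation recovered exactly from the following troughs
  d_true <- attr(tr, "planted")$deformation_mm
  expect_equal(rec$h_nwb_mm - rec$h_wb_mm, d_true, tolerance = 1e-10)
  # group-mean extracted BAI is non-increasing in the noise-free trace
  expect_true(all(diff(bai) <= 1e-12))
})

test_that("tendon traction engages exactly where axial load crosses threshold", {
  p <- generator_params("insole", total_cycles = 30)
  tr <- simulate_specimen(p, specimen_seed = 3)
  s <- tr$samples
  engaged <- abs(s$tendon_N - 32) < 1     # at the 32 N setpoint (within noise)
  expect_identical(engaged, s$load_N >= 150)
  expect_true(all(s$tendon_N[!engaged] == 0))
})

test_that("trace sampling is uniform, loads non-negative, invalid params rejected", {
  p <- generator_params("normal", total_cycles = 10)
  tr <- simulate_specimen(p, specimen_seed = 9)
  dt <- diff(tr$samples$time_s)
  expect_true(all(abs(dt - 1 / 20) < 1e-9))
  expect_true(all(tr$samples$load_N >= 0))
  expect_equal(nrow(tr$samples), 10 * 20 + 1)

  expect_error(generator_params("obese", d0_mm = 0), "d0_mm")
  expect_error(generator_params("obese", d_retained = 1.5), "d_retained")
  expect_error(generator_params("obese", d_retained = 0), "d_retained")
  expect_error(generator_params("obese", foot_length_mean_mm = -5), "foot length")
  expect_error(generator_params("nogroup"), "unknown group")
})

test_that("cohorts are deterministic under a master seed and sized correctly", {
  pars <- default_cohort_params(total_cycles = 5)
  c1 <- simulate_cohort(pars, n_per_group = 2, master_seed = 11)
  c2 <- simulate_cohort(pars, n_per_group = 2, master_seed = 11)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(lapply(c1$traces, `[[`, "samples"),
                   lapply(c2$traces, `[[`, "samples"))
  c3 <- simulate_cohort(pars, n_per_group = 2, master_seed = 12)
  expect_false(identical(c1$traces[[1]]$samples, c3$traces[[1]]$samples))

  expect_equal(length(c1$traces), 6)
  expect_equal(nrow(c1$manifest), 6)
  expect_setequal(unique(c1$manifest$group), c("normal", "obese", "insole"))

  out <- file.path(tempdir(), "coh_out")
  simulate_cohort(pars, n_per_group = 2, master_seed = 11, outdir = out)
  expect_length(list.files(out, pattern = "csv$"), 7)  # 6 traces + manifest

  expect_warning(simulate_cohort(pars, n_per_group = 1, master_seed = 1),
                 "confidence intervals")
})

test_that("planted inflection cycles are jittered at the configured SD", {
  p <- generator_params("obese", total_cycles = 3)
  infl <- vapply(1:40, function(i)
    attr(simulate_specimen(p, specimen_seed = 1000 + i), "planted")$inflection,
    numeric(1))
  expect_gt(sd(infl), 350)       # configured 547.7, n = 40 sampling band
  expect_lt(sd(infl), 800)
  expect_lt(abs(mean(infl) - 6500), 270)
})

test_that("trace files round-trip through CSV", {
  p <- noise_free_params("normal", total_cycles = 4)
  tr <- simulate_specimen(p, specimen_seed = 2)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  tr2 <- read_trace(f, specimen_id = tr$specimen_id, group = tr$group,
                    foot_length_mm = tr$foot_length_mm,
                    peak_load_N = tr$peak_load_N)
  expect_equal(tr2$samples, tr$samples, tolerance = 1e-12)
  expect_equal(tr2$sampling_rate_hz, 20, tolerance = 1e-6)
  expect_error(suppressWarnings(
    read_trace(system.file("extdata", "default_config.yaml",
                           package = "archfatigue"))), "lacks column")
})

test_that("lack-of-fit pattern is orthogonal to polynomial bases and anchored at zeros", {
  p <- generator_params("obese")
  grid <- default_checkpoints()
  g <- lack_of_fit_pattern(p, grid)
  z <- grid / max(grid)
  for (k in 0:5) expect_lt(abs(sum(g * z^k)), 1e-10)
  expect_equal(g[match(c(1, 1000, 2000, 10000), grid)], rep(0, 4),
               tolerance = 1e-12)
  # amplitude set so a cubic attains the target R^2 on trajectory + pattern
  y <- eval_trajectory(p$trajectory, grid) + g
  fit <- fit_polynomial(grid, y, 3)
  expect_equal(fit$r2, 0.930, tolerance = 1e-6)
})
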
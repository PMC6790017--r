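test_that("BAI arithmetic and arch classification boundaries", {
  expect_equal(compute_bai(52.5, 250), 0.21)
  expect_equal(as.character(classify_arch(0.21)), "normal")  # boundary -> normal
  expect_equal(compute_bai(0, 250), 0)
  expect_equal(compute_bai(50.75, 250), 0.203)
  expect_equal(as.character(classify_arch(c(0.2099, 0.27, 0.2701))),
               c("low", "normal", "high"))
  expect_error(compute_bai(50, 0), "foot length")
  expect_error(compute_bai(-1, 250), "height")
  # scale invariance
  expect_equal(compute_bai(52.5 * 3.7, 250 * 3.7), compute_bai(52.5, 250))
})

test_that("flexibility and energy formulas", {
  expect_equal(compute_flexibility(56, 55, 1000), 1.0)   # 1 mm @ 1000 N -> 1 um/N
  expect_equal(compute_flexibility(55, 55, 500), 0)
  expect_equal(compute_flexibility(59, 55, 500), 8.0)    # 4 mm @ 500 N
  expect_error(compute_flexibility(56, 55, 0), "load")

  expect_equal(compute_energy(2, 1000), 1.0)             # 2 mm @ 1000 N -> 1 J
  expect_equal(compute_energy(0, 500), 0)
  expect_equal(compute_energy(6, 1000), 3.0)
  expect_warning(compute_energy(-0.5, 500), "negative deformation")
})

test_that("energy and flexibility satisfy E = flexibility * load^2 / 2e6", {
  set.seed(42)
  for (i in 1:50) {
    d <- runif(1, 0, 8); load <- runif(1, 100, 1500)
    flex <- compute_flexibility(d, 0, load)
    expect_equal(compute_energy(d, load), flex * load^2 / 2e6, tolerance = 1e-12)
  }
})

test_that("arch_metrics assembles the per-cycle table consistently", {
  rec <- data.frame(cycle = 1:3, h_wb_mm = c(55, 54, 50),
                    h_nwb_mm = c(60, 58, 53),
                    peak_load_N = c(1000, 1000, 1000),
                    min_load_N = 0, wb_duration_s = 0.95)
  m <- arch_metrics(rec, foot_length_mm = 250)
  expect_equal(m$bai_wb, c(0.22, 0.216, 0.20))
  expect_equal(m$deformation_mm, c(5, 4, 3))
  expect_equal(m$flexibility_um_per_N, c(5, 4, 3))
  expect_equal(m$energy_J, c(2.5, 2, 1.5))
  expect_equal(as.character(m$arch_class), c("normal", "normal", "low"))
  # linkage identity on every record
  expect_equal(m$energy_J, m$flexibility_um_per_N * m$peak_load_N^2 / 2e6)
})

test_that("first-versus-last deltas subtract endpoint metrics", {
  m <- data.frame(cycle = c(1, 5000, 10000), bai_wb = c(0.24, 0.21, 0.20),
                  flexibility_um_per_N = c(8.0, 7.8, 7.5),
                  energy_J = c(1.0, 0.95, 0.9))
  d <- compute_deltas(m, specimen_id = "s1")
  expect_equal(d$delta_bai, 0.04)
  expect_equal(d$delta_flexibility_um_per_N, 0.5)
  expect_equal(d$delta_energy_J, 0.1, tolerance = 1e-12)

  # identical endpoint metrics -> zero deltas
  m0 <- rbind(m[1, ], within(m[1, ], cycle <- 10000))
  expect_equal(unlist(compute_deltas(m0)[-1]), c(delta_bai = 0,
               delta_flexibility_um_per_N = 0, delta_energy_J = 0))
  expect_error(compute_deltas(m[1:2, ], specimen_id = "s9"), "s9")
})

test_that("noise-free deltas match the closed-form stiffening loss", {
  # delta flexibility = d0 * (1 - retained) * 1000 / F
  p <- noise_free_params("obese", total_cycles = 200)
  tr <- simulate_specimen(p, specimen_seed = 4)
  m <- arch_metrics(segment_cycles(tr), tr$foot_length_mm)
  d <- compute_deltas(m, cycles = c(1, 200))
  expect_equal(d$delta_flexibility_um_per_N, 6 * (1 - 0.6) * 1000 / 1000,
               tolerance = 0.02)
  expect_equal(d$delta_energy_J, (6 - 6 * 0.6) / 1000 * 1000 / 2,
               tolerance = 0.02)
})

test_that("default cohorts reproduce the first-load ordering of the groups", {
  coh <- simulate_cohort(default_cohort_params(total_cycles = 300),
                         n_per_group = 4, master_seed = 42)
  mets <- cohort_metrics(coh)
  grp <- setNames(coh$manifest$group, coh$manifest$specimen_id)
  first_flex <- vapply(mets, function(m) m$flexibility_um_per_N[1], numeric(1))
  first_en <- vapply(mets, function(m) m$energy_J[1], numeric(1))
  g <- grp[names(mets)]
  med <- function(x, gr) median(x[g == gr])
  # flexibility: normal > obese > insole; energy: obese highest
  expect_gt(med(first_flex, "normal"), med(first_flex, "obese"))
  expect_gt(med(first_flex, "obese"), med(first_flex, "insole"))
  expect_gt(med(first_en, "obese"), med(first_en, "normal"))
  expect_gt(med(first_en, "obese"), med(first_en, "insole"))
  # fatigue deltas: obese loses more flexibility and energy than insole
  deltas <- do.call(rbind, lapply(names(mets), function(id)
    compute_deltas(mets[[id]], cycles = c(1, 300), specimen_id = id)))
  dg <- grp[deltas$specimen_id]
  expect_gt(median(deltas$delta_flexibility_um_per_N[dg == "obese"]),
            median(deltas$delta_flexibility_um_per_N[dg == "insole"]))
  expect_gt(median(deltas$delta_energy_J[dg == "obese"]),
            median(deltas$delta_energy_J[dg == "insole"]))
})
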
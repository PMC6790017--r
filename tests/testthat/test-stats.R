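test_that("group summaries match the textbook t-interval", {
  s <- summarize_group(c(0.2, 0.2, 0.2))
  expect_equal(s$mean, 0.2)
  expect_equal(s$sd, 0)
  expect_equal(c(s$ci_lo, s$ci_hi), c(0.2, 0.2))

  set.seed(42)
  for (rep in 1:5) {
    x <- rnorm(sample(3:12, 1), 10, 2)
    s <- summarize_group(x)
    hw <- qt(0.975, length(x) - 1) * sd(x) / sqrt(length(x))
    expect_equal(s$ci_lo, mean(x) - hw, tolerance = 1e-12)
    expect_equal(s$ci_hi, mean(x) + hw, tolerance = 1e-12)
  }

  expect_warning(s1 <- summarize_group(5), "undefined")
  expect_false(s1$ci_defined)

  set.seed(42)
  x <- rnorm(20)
  sb <- summarize_group(x, method = "bootstrap", B = 500)
  expect_lte(sb$ci_lo, mean(x)); expect_gte(sb$ci_hi, mean(x))
})

test_that("normality screen flags skew, stays quiet under the null, guards n", {
  set.seed(42)
  skew <- rexp(300)^2
  expect_equal(normality_screen(skew)$verdict, "non-normal")
  expect_equal(normality_screen(skew, method = "lilliefors")$verdict,
               "non-normal")
  rej <- mean(vapply(1:150, function(i)
    normality_screen(rnorm(60))$verdict == "non-normal", logical(1)))
  expect_lte(rej, 0.08)   # at worst the nominal level
  expect_error(normality_screen(c(1, 2)), "n >= 3")
  expect_warning(out <- normality_screen(rep(1, 10)), "degenerate")
  expect_equal(out$verdict, "degenerate")
})

test_that("Kruskal-Wallis statistic matches the hand rank computation", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- rep(c("a", "b", "c"), each = 3)
  res <- between_group_test(x, g)
  omni <- res[res$comparison == "omnibus", ]
  # H = 12/(N(N+1)) * sum(R_j^2 / n_j) - 3(N+1) on the ranks
  R <- tapply(rank(x), g, sum)
  H <- 12 / (9 * 10) * sum(R^2 / 3) - 3 * 10
  expect_equal(omni$statistic, H, tolerance = 1e-12)
  expect_equal(H, 7.2)
  # maximal separation opens the gate: pairwise rows present, Bonferroni x3
  pw <- res[res$comparison != "omnibus", ]
  expect_equal(nrow(pw), 3)
  expect_equal(pw$p_adjusted, pmin(1, pw$p * 3))
  expect_true(all(pw$p_adjusted >= pw$p))
})

test_that("pairwise tests are gatekept by the omnibus result", {
  set.seed(42)
  x <- rnorm(18); g <- rep(c("a", "b", "c"), 6)    # null: no group effect
  res <- between_group_test(x, g)
  if (res$p[res$comparison == "omnibus"] >= 0.05) {
    expect_equal(nrow(res), 1)                      # suppressed
  }
  res2 <- between_group_test(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p, 1)
  expect_error(between_group_test(1:5, c("a", "a", "a", "a", "b")), "n >= 2")
})

test_that("Friedman trend statistic matches the hand rank computation", {
  # 3 blocks x 3 treatments, identical ordering in every block
  m <- rbind(c(3, 2, 1), c(6, 5, 4), c(9, 8, 7))
  res <- within_group_trend_test(m)
  # Q = 12/(n k (k+1)) * sum(R_j^2) - 3 n (k+1), column rank sums 9, 6, 3
  Q <- 12 / (3 * 3 * 4) * sum(c(9, 6, 3)^2) - 3 * 3 * 4
  expect_equal(res$statistic, Q, tolerance = 1e-12)
  expect_lt(res$p, 0.05)

  expect_warning(res0 <- within_group_trend_test(matrix(7, 4, 5)), "degenerate")
  expect_equal(res0$p, 1)

  long <- data.frame(specimen_id = rep(c("s1", "s2"), each = 3),
                     cycle = rep(c(1, 2, 3), 2), value = rnorm(6))
  expect_equal(nrow(within_group_trend_test(long)), 1)
  expect_error(within_group_trend_test(long[-2, ]), "missing checkpoint 2")
})

test_that("low-arch onset is the first checkpoint whose CI upper bound is below 0.21", {
  # deterministic series built from the calibrated group trajectories with
  # fixed CI half-widths equal to the generator's offset calibration
  cp <- default_checkpoints()
  mk <- function(g, hw) {
    tr <- generator_params(g)$trajectory
    mean <- eval_trajectory(tr, cp)
    data.frame(group = g, cycle = cp, metric = "bai_wb", n = 6, mean = mean,
               sd = NA, ci_lo = mean - hw, ci_hi = mean + hw,
               ci_defined = TRUE)
  }
  series <- rbind(mk("normal", 0.005), mk("obese", 0.0065), mk("insole", 0.009))
  onset <- flag_low_arch_onset(series)
  expect_equal(onset$onset_cycle[onset$group == "obese"], 1000)
  expect_equal(onset$onset_cycle[onset$group == "insole"], 6000)
  expect_true(is.na(onset$onset_cycle[onset$group == "normal"]))
})

test_that("cohort battery runs end to end on a small cohort", {
  coh <- simulate_cohort(default_cohort_params(total_cycles = 120),
                         n_per_group = 3, master_seed = 21)
  mets <- cohort_metrics(coh)
  st <- suppressWarnings(cohort_stats(mets, coh$manifest,
                                      checkpoints = c(1, seq(20, 120, 20))))
  expect_s3_class(st$series, "group_series")
  expect_equal(sort(unique(st$series$group)), c("insole", "normal", "obese"))
  expect_equal(nrow(st$trend_tests), 9)           # 3 groups x 3 metrics
  expect_true(all(st$series$ci_lo <= st$series$mean + 1e-12))
  expect_true(all(st$series$mean <= st$series$ci_hi + 1e-12))
  expect_equal(nrow(st$delta), 9)
  d <- tempfile()
  write_stats_report(st, d, header = "seed: 21")
  expect_true(file.exists(file.path(d, "report.txt")))
  expect_match(readLines(file.path(d, "report.txt"))[1], "seed: 21")
})
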
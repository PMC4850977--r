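test_that("critical points match t-table values and the normal limit", {
  expect_equal(t_critical(0.05, 46), 2.01, tolerance = 0.005)
  expect_equal(t_critical(0.05, 35), 2.03, tolerance = 0.005)
  expect_equal(t_critical(0.05, 10000), 1.96, tolerance = 0.005)
  expect_error(t_critical(0, 10), "alpha")
  expect_error(t_critical(0.05, 0), "df")
})

test_that("pooled t reproduces a hand-computed shifted-group example", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  # s^2 = 1 in both groups -> Sp = 1; t = -10 / sqrt(2/3)
  r <- pooled_t(a, b)
  expect_equal(r$statistic, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$pooled_sd, 1)
  expect_true(r$reject)

  same <- pooled_t(c(5, 6, 7), c(5, 6, 7))
  expect_equal(same$statistic, 0)
  expect_false(same$reject)

  # degenerate variance: equal means tolerated, unequal means rejected
  expect_equal(pooled_t(c(2, 2), c(2, 2))$statistic, 0)
  expect_error(pooled_t(c(2, 2), c(3, 3)), "undefined")
  expect_error(pooled_t(1, 1:3), "at least 2")
})

test_that("pooled and Welch t agree with stats::t.test as an oracle", {
  set.seed(71)
  for (i in 1:10) {
    a <- rnorm(sample(4:20, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(4:20, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 2))
    expect_equal(pooled_t(a, b)$statistic,
                 unname(t.test(a, b, var.equal = TRUE)$statistic),
                 tolerance = 1e-12)
    w <- welch_t(a, b)
    ref <- t.test(a, b)
    expect_equal(w$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(w$df_exact, unname(ref$parameter), tolerance = 1e-9)
    expect_identical(w$df, floor(w$df_exact))
  }
})

test_that("pooled and Welch statistics coincide at equal group sizes", {
  set.seed(72)
  for (i in 1:10) {
    n <- sample(3:25, 1)
    a <- rnorm(n, sd = runif(1, 0.2, 3))
    b <- rnorm(n, mean = runif(1, -2, 2), sd = runif(1, 0.2, 3))
    expect_equal(pooled_t(a, b)$statistic, welch_t(a, b)$statistic,
                 tolerance = 1e-12)
  }
  # equal variances and equal n: Welch df collapses to n_A + n_B - 2 exactly
  a <- c(1, 2, 3, 4); b <- a + 10
  expect_equal(welch_t(a, b)$df_exact, length(a) + length(b) - 2,
               tolerance = 1e-12)
})

test_that("swapping group labels negates t but never changes the decision", {
  set.seed(73)
  for (i in 1:8) {
    a <- rnorm(12); b <- rnorm(15, mean = 0.5)
    for (fn in list(pooled_t, welch_t)) {
      ab <- fn(a, b); ba <- fn(b, a)
      expect_equal(ab$statistic, -ba$statistic, tolerance = 1e-12)
      expect_identical(ab$reject, ba$reject)
      expect_equal(ab$critical, ba$critical, tolerance = 1e-12)
    }
  }
})

test_that("reference turn table reproduces the published asymmetry tests", {
  t4 <- load_fixture("table4")
  res <- asymmetry_analysis(t4)

  dur <- res$duration_s
  expect_true(dur$normality$L$normal)
  expect_true(dur$normality$R$normal)
  expect_true(dur$variance$equal)
  expect_identical(dur$test$variant, "pooled")
  expect_equal(abs(dur$test$statistic), 4.27, tolerance = 0.005)
  expect_identical(dur$test$df, 46)
  expect_equal(dur$test$critical, 2.01, tolerance = 0.005)
  expect_true(dur$test$reject)

  rat <- res$max_pressure_ratio
  expect_true(rat$normality$L$normal)
  expect_true(rat$normality$R$normal)
  expect_false(rat$variance$equal)
  expect_identical(rat$test$variant, "welch")
  expect_identical(rat$test$df, 35)
  expect_equal(rat$test$critical, 2.03, tolerance = 0.005)
  expect_true(rat$test$reject)
})

test_that("identical symmetric sides retain both null hypotheses", {
  set.seed(74)
  base <- data.frame(trial = rep(1:4, each = 6), turn = rep(1:6, 4),
                     side = rep(c("R", "L"), 12),
                     duration_s = rep(rnorm(12, 2, 0.3), 2),
                     max_pressure_ratio = rep(runif(12, 0.7, 0.9), 2))
  # construct exactly matched L/R samples
  base$duration_s[base$side == "L"] <- base$duration_s[base$side == "R"]
  base$max_pressure_ratio[base$side == "L"] <-
    base$max_pressure_ratio[base$side == "R"]
  res <- asymmetry_analysis(base)
  expect_false(res$duration_s$test$reject)
  expect_false(res$max_pressure_ratio$test$reject)
})

test_that("turn-table construction flags trials with wrong segment counts", {
  cfg <- noiseless_config(
    n_trials = 3, seed = 99,
    profiles = list(pelvis = location_profile("pelvis", 1, 0)))
  s <- simulate_session(cfg)
  segs <- list(); ratios <- list()
  for (key in names(s$trials)) {
    tr <- s$trials[[key]]
    segs[[key]] <- zero_crossing_segments(tr$traces$pelvis, 0)
    ratios[[key]] <- resample_to(
      foot_pressure_ratio(tr$insole_left, tr$insole_right), 100)
  }
  # corrupt one trial's segments
  segs[[2]] <- segs[[2]][-1, ]
  tt <- build_turn_table(segs, ratios, 6)
  expect_identical(attr(tt, "excluded"), names(s$trials)[2])
  expect_identical(nrow(tt), 12L)
  expect_true(all(tt$max_pressure_ratio >= 0.5 & tt$max_pressure_ratio <= 1))
  # symmetric loading throughout -> max ratios 0.5
  flat <- lapply(ratios, function(r) ski_ts(rep(0, length(r$values)), 100))
  tt0 <- build_turn_table(segs[-2], flat[-2], 6)
  expect_equal(tt0$max_pressure_ratio, rep(0.5, 12))
})

test_that("adaptation analysis matches the published correlation", {
  t6 <- load_fixture("table6")
  res <- adaptation_analysis(t6$attempt, t6$total_duration_s)
  expect_equal(res$r, -0.696, tolerance = 5e-4)
  expect_identical(res$n, 8L)
  expect_equal(res$df, 6)
  expect_equal(sign(res$slope), sign(res$r))
  expect_lt(res$p_value, 0.06)

  lin <- adaptation_analysis(1:6, seq(14, 9, by = -1))
  expect_equal(lin$r, -1, tolerance = 1e-12)
  expect_error(adaptation_analysis(1:5, rep(3, 5)), "constant")
  expect_error(adaptation_analysis(1:5, c(10, NA, NA, NA, 9)), ">= 3")
})

test_that("branched asymmetry test keeps its nominal type-I error", {
  set.seed(75)
  cfg <- simulation_config(
    n_trials = 8, adaptation_slope_s_per_trial = 0,
    mean_duration_right_s = 1.88, mean_duration_left_s = 1.88,
    outer_foot_peak_fraction_left_turns = 0.835,
    outer_foot_peak_fraction_right_turns = 0.835,
    peak_fraction_sd_left_turns = 0.07, peak_fraction_sd_right_turns = 0.07,
    location_profiles = pelvis_only_profiles())
  rejections <- replicate(1000, {
    tt <- simulate_turn_table(cfg)
    res <- asymmetry_analysis(tt)
    c(res$duration_s$test$reject, res$max_pressure_ratio$test$reject)
  })
  for (rate in rowMeans(rejections)) {
    expect_gte(rate, 0.02)
    expect_lte(rate, 0.09)
  }
})
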
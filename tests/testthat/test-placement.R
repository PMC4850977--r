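test_that("pattern correlation matches the summation oracle and edge cases", {
  f <- c(1, 2, 3, 4)
  expect_equal(pattern_correlation(f, f), 1)
  expect_equal(pattern_correlation(f, -f), -1)
  # frozen from the oracle: Sxy = 4.5, Sxx = 5, Syy = 4.75
  expect_equal(pattern_correlation(f, c(1, 2, 2, 4)), 0.9234, tolerance = 1e-3)

  set.seed(17)
  for (i in 1:20) {
    a <- rnorm(sample(3:50, 1))
    b <- rnorm(length(a)) + 0.3 * a
    expect_equal(pattern_correlation(a, b), pearson_oracle(a, b),
                 tolerance = 1e-12)
  }
  expect_error(pattern_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pattern_correlation(1:4, 1:5), "lengths")
  expect_error(pattern_correlation(1:2, 2:1), "3 samples")
})

test_that("correlation table orders locations by signal fidelity", {
  cfg <- noiseless_config(n_trials = 1, seed = 19)
  ct1 <- correlation_table(simulate_session(cfg))
  # single trial: median equals that trial's value
  expect_equal(ct1$median, ct1[[2]])
  # noiseless: correlation limited only by the waveform-shape mismatch
  # between the half-sine roll and raised-cosine loading, cor(sin, sin^2)
  shape_r <- (4 / (3 * pi)) / sqrt(0.5 * 3 / 8)
  expect_equal(ct1$median[ct1$location == "pelvis"], shape_r,
               tolerance = 0.01)

  cfg2 <- simulation_config(n_trials = 4, seed = 23)
  ct <- correlation_table(simulate_session(cfg2))
  expect_true(all(ct$median >= -1 & ct$median <= 1))
  expect_lt(ct$median[ct$location == "hand_R"],
            ct$median[ct$location == "pelvis"])
  # medians column is consistent with its own row cells
  cells <- as.matrix(ct[, grep("^attempt_", names(ct))])
  expect_equal(ct$median, apply(cells, 1, median))
})

test_that("centroid linkage reproduces the exhaustive oracle merge-by-merge", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(3:6, 1)
    coords <- round(runif(n), 3)
    labels <- paste0("loc", seq_len(n))
    d2 <- outer(coords, coords, function(a, b) (a - b)^2)
    dend <- skiturns:::centroid_linkage(d2, labels)
    oracle <- centroid_oracle(coords)
    for (step in seq_len(n - 1L)) {
      expect_identical(sort(dend$members[[step]]), oracle[[step]]$members)
      expect_equal(dend$height[step], oracle[[step]]$height,
                   tolerance = 1e-12)
    }
  }
})

test_that("reference-mode clustering joins the best location to the reference first", {
  tab <- data.frame(location = c("pelvis", "hand_L"),
                    mean = c(0.9, 0.1), median = c(0.9, 0.1))
  class(tab) <- c("correlation_table", "data.frame")
  dend <- cluster_locations(tab)
  # leaves: reference (0), pelvis (0.1), hand_L (0.9); first merge at 0.1
  expect_equal(dend$height[1], 0.1)
  expect_identical(sort(dend$labels[dend$members[[1]]]),
                   c("foot_pressure", "pelvis"))
  # merge heights are non-decreasing for scalar centroid linkage
  expect_true(all(diff(dend$height) >= -1e-12))

  tab_eq <- data.frame(location = c("a", "b", "c"),
                       mean = 0.5, median = c(0.5, 0.5, 0.5))
  class(tab_eq) <- c("correlation_table", "data.frame")
  dend_eq <- cluster_locations(tab_eq)
  expect_equal(dend_eq$height[1], 0)

  # in reference mode, when the reference first takes part in a merge, the
  # cluster it joins contains the argmax-median location (it is the leaf
  # nearest the reference coordinate 0)
  cfg <- simulation_config(n_trials = 3, seed = 29)
  ct <- correlation_table(simulate_session(cfg))
  dd <- cluster_locations(ct)
  ref_step <- which(vapply(dd$members, function(m)
    "foot_pressure" %in% dd$labels[m], logical(1)))[1]
  expect_true(ct$location[which.max(ct$median)] %in%
                dd$labels[dd$members[[ref_step]]])

  expect_error(cluster_locations(tab[0, ]), "valid median|2 leaves")
  nw <- dendrogram_newick(dend)
  expect_match(nw, "^\\(.*\\);$")
  expect_match(nw, "pelvis")
  expect_s3_class(as.hclust(dend), "hclust")
})

test_that("zero-crossing segmentation counts sign runs and honors conventions", {
  s <- ski_ts(c(1, 2, -1, -2, 3, 4), rate_hz = 1)
  seg <- zero_crossing_segments(s, 0)
  expect_identical(nrow(seg), 3L)
  expect_identical(seg$side, c("R", "L", "R"))

  pos <- ski_ts(abs(rnorm(50)) + 0.1, rate_hz = 10)
  expect_identical(nrow(zero_crossing_segments(pos, 0)), 1L)

  z <- ski_ts(rep(0, 20), rate_hz = 10)
  expect_identical(nrow(zero_crossing_segments(z, 0)), 0L)

  # a zero sample closes the preceding segment
  s0 <- ski_ts(c(1, 1, 0, -1, -1), rate_hz = 1)
  seg0 <- zero_crossing_segments(s0, 0)
  expect_identical(seg0$end, c(3L, 5L))
  expect_identical(seg0$side, c("R", "L"))

  # a short opposite-sign blip is absorbed, not counted as a turn
  v <- c(rep(1, 100), -0.2, -0.1, rep(1, 100), rep(-1, 150))
  blip <- ski_ts(v, rate_hz = 100)
  expect_identical(nrow(zero_crossing_segments(blip, 0)), 4L)
  seg_m <- zero_crossing_segments(blip, min_duration_s = 0.5)
  expect_identical(nrow(seg_m), 2L)
  expect_identical(seg_m$side, c("R", "L"))
  expect_identical(sum(seg_m$end - seg_m$start + 1L), length(v))
})

test_that("a seeded noisy seven-turn pelvis trace yields seven segments", {
  cfg <- simulation_config(n_trials = 1, turns_per_trial = 7, seed = 8,
                           mean_duration_right_s = 2, mean_duration_left_s = 2,
                           location_profiles = pelvis_only_profiles())
  s <- simulate_session(cfg)
  trace <- moving_average(s$trials[[1]]$traces$pelvis, 5)
  seg <- zero_crossing_segments(trace, min_duration_s = 0.5)
  expect_identical(nrow(seg), 7L)
  expect_equal(turn_detection_measure(nrow(seg), 7), 100L)
})

test_that("turn-detection measure rounds to integer percent", {
  expect_identical(turn_detection_measure(7, 7), 100L)
  expect_identical(turn_detection_measure(9, 7), 129L)
  expect_identical(turn_detection_measure(0, 7), 0L)
  expect_identical(turn_detection_measure(6, 7), 86L)
  expect_error(turn_detection_measure(5, 0), "actual")
  # 100 iff detected == actual
  for (d in 0:14)
    expect_identical(turn_detection_measure(d, 7) == 100L, d == 7L)
})

test_that("published summary tables rank the pelvis first", {
  rep <- rank_locations(published_cor_table(), published_det_table())
  expect_identical(rep$selected, "pelvis")
  expect_true(all(c("pelvis", "shank_R", "foot_L", "foot_R") %in%
                    rep$candidates))
  expect_false("thigh_L" %in% rep$candidates)   # 129% in one trial
  expect_false("lower_spine" %in% rep$candidates) # missed turns
  # pelvis outranks the equally-perfect shank/feet by median correlation
  expect_gt(rep$ranking$median_correlation[1],
            max(rep$ranking$median_correlation[rep$ranking$location %in%
                                                 c("foot_L", "shank_R")]))
})

test_that("ranking tie rules: flags, median, then midline before paired", {
  ct <- data.frame(location = c("pelvis", "upper_spine", "shank_R"),
                   mean = c(0.9, 0.9, 0.9), median = c(0.9, 0.92, 0.9))
  class(ct) <- c("correlation_table", "data.frame")
  dt <- data.frame(location = c("pelvis", "upper_spine", "shank_R"),
                   attempt_1 = c(100L, 100L, 100L))
  dt$average <- 100
  class(dt) <- c("detection_table", "data.frame")
  rep <- rank_locations(ct, dt)
  # higher median wins between two perfect locations
  expect_identical(rep$selected, "upper_spine")
  # equal medians: midline beats the paired placement
  expect_identical(rep$ranking$location[2:3], c("pelvis", "shank_R"))

  # all below threshold -> empty candidate list, report still emitted
  ct$median <- c(0.5, 0.55, 0.5)
  rep2 <- rank_locations(ct, dt)
  expect_length(rep2$candidates, 0)
  expect_true(is.na(rep2$selected))
})
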
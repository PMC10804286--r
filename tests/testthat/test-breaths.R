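test_that("sinusoidal flow segments into breaths with closed-form features", {
  fs <- 1000
  flow <- make_sine_flow(2.5, 60, fs)
  b <- segment_breaths(flow, fs)
  expect_equal(nrow(b), 150)
  f <- breath_features(flow, b, fs)
  expect_true(all(abs(f$ti - 0.2) <= 1 / fs + 1e-9))
  expect_true(all(abs(f$te - 0.2) <= 2 / fs + 1e-9))
  expect_equal(mean(f$vt), 1 / (pi * 2.5), tolerance = 1e-3)
  expect_equal(mean(f$mean_insp_flow), 2 / pi, tolerance = 1e-3)
  expect_equal(mean(f$v_i_max), 1, tolerance = 1e-3)
  expect_equal(mean(f$inst_rr), 150, tolerance = 1e-3)
})

test_that("a DC offset below the hysteresis band does not change the count", {
  fs <- 1000
  flow <- make_sine_flow(2.5, 60, fs)
  n0 <- nrow(segment_breaths(flow, fs, hysteresis = 0.1))
  n1 <- nrow(segment_breaths(flow + 0.02, fs, hysteresis = 0.1))
  expect_equal(n1, n0)
})

test_that("flat zero flow yields an empty breath list, not an error", {
  out <- segment_breaths(numeric(5000), 1000)
  expect_s3_class(out, "data.frame")
  expect_equal(nrow(out), 0)
})

test_that("segmentation count matches the generator truth table", {
  for (seed in c(2, 12)) {
    gen <- generate_recording(quiet_config(seed = seed, duration = 90,
                                           breath = list(rate_cv = 0.1)))
    fl <- get_channel(gen$recording, "flow")
    expect_equal(nrow(segment_breaths(fl)), nrow(gen$truth$breath_table))
  }
  # zero cycle variability: exact count by construction
  gen0 <- generate_recording(quiet_config(seed = 3, duration = 60,
                                          breath = list(rate_cv = 0),
                                          sniff = list(prob = 0)))
  expect_equal(nrow(gen0$truth$breath_table), 150)
  expect_equal(nrow(segment_breaths(get_channel(gen0$recording, "flow"))), 150)
})

test_that("tidal volume matches a fine-grid quadrature oracle", {
  fs <- 1000
  f_wave <- function(t) 1.3 * sin(pi * t / 0.16)^1  # half-sine inspiration
  t_coarse <- seq(0, 0.16, by = 1 / fs)
  insp <- f_wave(t_coarse)
  flow <- c(insp, -0.5 * exp(-(seq(0, 0.24, by = 1 / fs)) / 0.08))
  bounds <- data.frame(t_start = 0, t_insp_end = 0.16, t_end = 0.4,
                       i_start = 1L, i_insp_end = length(insp),
                       i_end = length(flow))
  feats <- breath_features(flow, bounds, fs)
  t_fine <- seq(0, 0.16, by = 1 / (100 * fs))
  vt_oracle <- sum(f_wave(t_fine)) / (100 * fs)
  expect_equal(feats$vt, vt_oracle, tolerance = 1e-3)
  expect_equal(feats$v_i_max, 1.3, tolerance = 1e-4)
})

test_that("flow landmarks collapse onto the plateau height for clipped inspiration", {
  fs <- 1000
  m <- 160
  insp <- pmin(sin(pi * (0:(m - 1)) / m), 0.7)
  flow <- c(insp, -insp[m:1])  # symmetric return, boundaries known
  bounds <- data.frame(t_start = 0, t_insp_end = (m - 1) / fs,
                       t_end = (2 * m - 1) / fs,
                       i_start = 1L, i_insp_end = m, i_end = 2L * m)
  f <- breath_features(flow, bounds, fs)
  expect_equal(f$v_imax1, 0.7, tolerance = 1e-6)
  expect_equal(f$v_i50, 0.7, tolerance = 1e-6)
  expect_equal(f$v_imax2, 0.7, tolerance = 1e-6)
  expect_true(f$v_i50 <= f$v_i_max + 1e-12)
})

test_that("analysis-window selection follows the REM-all / NREM-sampled rule", {
  # no REM at all -> no REM windows
  h1 <- hypnogram(rep(c("W", "NREM"), each = 360))
  w1 <- select_analysis_windows(h1)
  expect_false(any(w1$stage == "REM"))
  # 6 h of continuous NREM -> exactly 12 stretches of 20 s
  h2 <- hypnogram(rep("NREM", 6 * 720))
  w2 <- select_analysis_windows(h2)
  expect_equal(sum(w2$stage == "NREM"), 12)
  expect_true(all(w2$t_end - w2$t_start == 20))
  # fragmented NREM with no 20-s run -> block contributes nothing
  h3 <- hypnogram(rep(c("NREM", "W", "NREM", "W"), 180)[1:720])
  w3 <- select_analysis_windows(h3)
  expect_equal(nrow(w3[w3$stage == "NREM", ]), 0)
  # every REM epoch is covered by some REM window
  h4 <- hypnogram(rep(c("W", "NREM", "REM"), each = 240))
  w4 <- select_analysis_windows(h4)
  rem_cov <- sum(w4$t_end[w4$stage == "REM"] - w4$t_start[w4$stage == "REM"])
  expect_equal(rem_cov, 240 * 5)
})

test_that("ventilation aggregation is permutation invariant and flags empty stages", {
  gen <- generate_recording(quiet_config(seed = 6, duration = 60))
  fl <- get_channel(gen$recording, "flow")
  b <- breath_features(fl, segment_breaths(fl), hyp = gen$truth$hypnogram_true)
  s1 <- aggregate_ventilation(b)
  s2 <- aggregate_ventilation(b[sample.int(nrow(b)), ])
  expect_equal(s1, s2)
  missing_stages <- s1$group[s1$flagged_empty]
  expect_true(all(s1$n[s1$group %in% missing_stages] == 0))
  # identical breaths: summary equals the single-breath values
  bb <- b[rep(5, 20), ]
  s3 <- aggregate_ventilation(bb)
  row <- s3[s3$group == bb$stage[1], ]
  expect_equal(row$vt_median, b$vt[5])
  expect_equal(row$inst_ve_mean, b$inst_ve[5])
})

test_that("mean instantaneous VE matches total volume over window duration", {
  gen <- generate_recording(quiet_config(seed = 8, duration = 60,
                                         breath = list(rate_cv = 0.05)))
  fl <- get_channel(gen$recording, "flow")
  b <- breath_features(fl, segment_breaths(fl))
  span <- max(b$t_end) - min(b$t_start)
  ve_direct <- sum(b$vt) / span * 60
  expect_equal(mean(b$inst_ve), ve_direct, tolerance = 0.01)
})
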
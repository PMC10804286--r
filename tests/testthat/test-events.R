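test_that("injected apneas are detected with accurate onset and duration", {
  cfg <- synth_config(seed = 7, duration = 600, hypnogram = rem_heavy(),
                      apnea = list(rate = c(W = 0, NREM = 0, REM = 30),
                                   duration_mean = 1.2, duration_sd = 0.3,
                                   duration_min = 0.8))
  gen <- generate_recording(cfg)
  tr <- gen$truth
  expect_gt(nrow(tr$apnea_events), 0)
  fl <- get_channel(gen$recording, "flow")
  b <- breath_features(fl, segment_breaths(fl), hyp = tr$hypnogram_true)
  ev <- detect_apneas(fl, b, tr$hypnogram_true)
  expect_equal(nrow(ev), nrow(tr$apnea_events))
  for (k in seq_len(nrow(tr$apnea_events))) {
    i <- which.min(abs(ev$t_start - tr$apnea_events$t_start[k]))
    expect_lt(abs(ev$t_start[i] - tr$apnea_events$t_start[k]), 0.1)
    expect_lt(abs(ev$duration[i] - tr$apnea_events$duration[k]), 0.1)
    expect_gte(ev$magnitude[i], 90)
  }
})

test_that("sub-threshold dips are rejected by duration and depth rules", {
  fs <- 1000
  flow <- make_sine_flow(2.5, 60, fs)
  hyp <- hypnogram(rep("REM", 12))
  score <- function(f, ...) {
    b <- breath_features(f, segment_breaths(f, fs, hysteresis = 0.05), fs,
                         hyp = hyp)
    detect_apneas(f, b, hyp, sample_rate = fs, ...)
  }
  # 95% reduction but only 0.3 s (< 0.7 s and < 2 cycles): rejected
  f1 <- flow
  f1[(30 * fs):(30.3 * fs)] <- f1[(30 * fs):(30.3 * fs)] * 0.05
  expect_equal(nrow(score(f1)), 0)
  # 85% reduction for 2 s (< 90% depth): rejected
  f2 <- flow
  f2[(30 * fs):(32 * fs)] <- f2[(30 * fs):(32 * fs)] * 0.15
  expect_equal(nrow(score(f2)), 0)
  # positive control: 95% reduction for 1.2 s is scored
  f3 <- flow
  f3[(30 * fs + 1):(31.2 * fs)] <- f3[(30 * fs + 1):(31.2 * fs)] * 0.02
  ev <- score(f3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration, 1.2, tolerance = 0.1)
  expect_equal(ev$stage, "REM")
})

test_that("the duration rule uses either clause by default, both on request", {
  fs <- 1000
  flow <- make_sine_flow(1, 60, fs)  # 60 breaths/min: 2 cycles = 2 s
  hyp <- hypnogram(rep("NREM", 12))
  f <- flow
  f[(30 * fs + 1):(31 * fs)] <- f[(30 * fs + 1):(31 * fs)] * 0.02  # 1 s event
  b <- breath_features(f, segment_breaths(f, fs, hysteresis = 0.05), fs)
  # either: min(2 cycles, 0.7) = 0.7 s -> accepted
  expect_equal(nrow(detect_apneas(f, b, hyp, sample_rate = fs)), 1)
  # both: max(2 cycles, 0.7) = 2 s -> rejected
  expect_equal(nrow(detect_apneas(f, b, hyp, sample_rate = fs,
                                  duration_rule = "both")), 0)
})

test_that("apnea index is events per hour of stage and scales with stage time", {
  ev <- data.frame(kind = "apnea", t_start = c(10, 20, 30),
                   duration = 1, stage = "REM", magnitude = 95)
  hyp_half <- hypnogram(rep("REM", 360))      # 0.5 h REM
  expect_equal(apnea_index(ev, hyp_half, "REM"), 6)
  hyp_full <- hypnogram(rep("REM", 720))      # 1 h REM
  expect_equal(apnea_index(ev, hyp_full, "REM"), 3)
  expect_equal(apnea_index(ev[0, ], hyp_full, "REM"), 0)
  expect_warning(idx <- apnea_index(ev, hyp_full, "NREM"), "undefined")
  expect_true(is.na(idx))
})

test_that("desaturation scoring honors depth, duration and sleep rules", {
  fs <- 10
  n <- 600 * fs
  spo2 <- rep(96, n)
  hyp <- hypnogram(c(rep("W", 24), rep("NREM", 96)))  # 120 s W, 480 s sleep
  breaths <- data.frame(ttot = rep(0.4, 50))
  dip <- function(x, t0, dur, depth) {
    x[(t0 * fs):((t0 + dur) * fs)] <- 96 - depth
    x
  }
  # 6% dip during sleep, 10 s: scored
  s1 <- dip(spo2, 300, 10, 6)
  r1 <- detect_desaturations(s1, hyp, breaths, sample_rate = fs)
  expect_equal(nrow(r1$events), 1)
  expect_equal(r1$events$stage, "NREM")
  expect_equal(r1$odi, 1 / (480 / 3600))
  # 3% dip: not scored
  r2 <- detect_desaturations(dip(spo2, 300, 10, 3), hyp, breaths,
                             sample_rate = fs)
  expect_equal(nrow(r2$events), 0)
  # 6% dip during wake: scored as an event but excluded from the ODI
  s3 <- dip(spo2, 30, 10, 6)
  r3 <- detect_desaturations(s3, hyp, breaths, sample_rate = fs)
  expect_equal(r3$events$stage, "W")
  expect_equal(r3$odi, 0)
  # too-short dip (< 2 breath cycles): not scored
  s4 <- spo2
  s4[(300 * fs):(300 * fs + 5)] <- 90   # 0.5 s < 0.8 s
  r4 <- detect_desaturations(s4, hyp, breaths, sample_rate = fs)
  expect_equal(nrow(r4$events), 0)
})

test_that("generator desaturations are scored and sub-threshold ones are not", {
  cfg <- synth_config(seed = 31, duration = 600, hypnogram = rem_heavy(),
                      apnea = list(rate = c(W = 0, NREM = 0, REM = 25)))
  gen <- generate_recording(cfg)
  tr <- gen$truth
  expect_gt(nrow(tr$desat_events), 0)
  fl <- get_channel(gen$recording, "flow")
  b <- breath_features(fl, segment_breaths(fl), hyp = tr$hypnogram_true)
  res <- detect_desaturations(get_channel(gen$recording, "spo2"),
                              tr$hypnogram_true, b)
  expect_equal(nrow(res$events), nrow(tr$desat_events))
  # sub-threshold depths never cross the 4% line
  cfg2 <- synth_config(seed = 31, duration = 600, hypnogram = rem_heavy(),
                       spo2 = list(desat_depth_mean = 2, desat_depth_sd = 0),
                       apnea = list(rate = c(W = 0, NREM = 0, REM = 25)))
  gen2 <- generate_recording(cfg2)
  b2 <- local({
    fl2 <- get_channel(gen2$recording, "flow")
    breath_features(fl2, segment_breaths(fl2), hyp = gen2$truth$hypnogram_true)
  })
  res2 <- detect_desaturations(get_channel(gen2$recording, "spo2"),
                               gen2$truth$hypnogram_true, b2)
  expect_equal(nrow(res2$events), 0)
})
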
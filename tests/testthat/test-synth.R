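test_that("invalid configurations are rejected", {
  expect_error(synth_config(duration = 5), "duration")
  expect_error(synth_config(breath = list(rate = -10)), "rate")
  expect_error(synth_config(breath = list(ti_fraction = 1.2)), "ti_fraction")
  expect_error(synth_config(flow_limitation = list(plateau_severity = 2)),
               "plateau_severity")
  expect_error(synth_config(sniff = list(prob = 1.5)), "probabilities")
  expect_error(synth_config(metabolism = list(rer = -1)), "rer")
  expect_error(synth_config(hypnogram = list(bout_mean = c(W = 3, NREM = 160,
                                                           REM = 60))),
               "bout-duration")
})

test_that("identical configurations give bit-identical recordings", {
  cfg <- synth_config(seed = 14, duration = 60)
  g1 <- generate_recording(cfg)
  g2 <- generate_recording(cfg)
  expect_identical(g1$recording$channels$flow$samples,
                   g2$recording$channels$flow$samples)
  expect_identical(g1$recording$channels$eeg$samples,
                   g2$recording$channels$eeg$samples)
  expect_identical(g1$truth$breath_table, g2$truth$breath_table)
  g3 <- generate_recording(synth_config(seed = 15, duration = 60))
  expect_false(identical(g1$recording$channels$flow$samples,
                         g3$recording$channels$flow$samples))
})

test_that("the volume channel is the running integral of flow", {
  gen <- generate_recording(quiet_config(seed = 2, duration = 30))
  fs <- gen$recording$channels$flow$sample_rate
  integ <- cumsum(gen$recording$channels$flow$samples) / fs
  expect_lt(max(abs(integ - gen$recording$channels$volume$samples)), 1e-6)
})

test_that("an independent threshold scan reproduces the truth breath count", {
  cfg <- quiet_config(seed = 3, duration = 60, breath = list(rate_cv = 0),
                      sniff = list(prob = 0))
  gen <- generate_recording(cfg)
  flow <- gen$recording$channels$flow$samples
  # oracle: denoise with a short running mean, then count upward crossings
  # of half the typical peak
  sm <- as.numeric(stats::filter(flow, rep(1 / 25, 25), sides = 2))
  sm[is.na(sm)] <- 0
  thr <- 0.5 * quantile(sm, 0.98, names = FALSE)
  crossings <- sum(sm[-1] >= thr & sm[-length(sm)] < thr)
  expect_equal(crossings, nrow(gen$truth$breath_table))
})

test_that("degenerate breath configurations produce pure half-sine trains", {
  cfg <- quiet_config(seed = 4, duration = 30,
                      breath = list(rate_cv = 0, amplitude_noise_sd = 0),
                      sniff = list(prob = 0),
                      flow_limitation = list(prob_rem = 0, plateau_severity = 0))
  gen <- generate_recording(cfg)
  expect_true(all(gen$truth$breath_table$label == "normal"))
  bt <- gen$truth$breath_table[1, ]
  fs <- cfg$sample_rate
  insp <- gen$recording$channels$flow$samples[
    (bt$t_start * fs + 1):(bt$t_insp_end * fs)]
  m <- length(insp)
  expect_equal(insp, bt$amp_true * sin(pi * (0:(m - 1)) / m), tolerance = 1e-12)
})

test_that("full clipping flattens the middle half of flow-limited inspiration", {
  cfg <- quiet_config(seed = 5, duration = 120, hypnogram = rem_heavy(),
                      breath = list(amplitude_noise_sd = 0),
                      sniff = list(prob = 0),
                      flow_limitation = list(prob_rem = 1, plateau_severity = 1))
  gen <- generate_recording(cfg)
  bt <- gen$truth$breath_table
  flb <- bt[bt$label == "flow_limited", ][1, ]
  fs <- cfg$sample_rate
  insp <- gen$recording$channels$flow$samples[
    (flb$t_start * fs + 1):(flb$t_insp_end * fs)]
  m <- length(insp)
  mid <- insp[ceiling(0.25 * m):floor(0.75 * m)]
  expect_lt(max(mid) - min(mid), 1e-9)
  # obstruction loses volume: no renormalization
  expect_lt(flb$vt_true, 0.15)
})

test_that("sniff breaths have inspiration scaled by ti_scale", {
  cfg <- quiet_config(seed = 6, duration = 120, breath = list(rate_cv = 0),
                      sniff = list(prob = 0.2, ti_scale = 0.4))
  gen <- generate_recording(cfg)
  bt <- gen$truth$breath_table
  ti <- bt$t_insp_end - bt$t_start
  expect_equal(median(ti[bt$label == "sniff"]) /
                 median(ti[bt$label == "normal"]), 0.4, tolerance = 0.05)
})

test_that("apnea injection preserves effort while silencing flow", {
  cfg <- synth_config(seed = 7, duration = 300, hypnogram = rem_heavy(),
                      apnea = list(rate = c(W = 0, NREM = 0, REM = 40)))
  gen <- generate_recording(cfg)
  tr <- gen$truth
  expect_gt(nrow(tr$apnea_events), 0)
  fs <- cfg$sample_rate
  flow <- gen$recording$channels$flow$samples
  effort <- gen$recording$channels$effort$samples
  rms <- function(x) sqrt(mean(x^2))
  for (k in seq_len(nrow(tr$apnea_events))) {
    t0 <- tr$apnea_events$t_start[k]
    t1 <- t0 + tr$apnea_events$duration[k]
    ev <- (round(t0 * fs) + 1):round(t1 * fs)
    pre <- (max(1, round((t0 - 10) * fs))):round(t0 * fs)
    expect_lt(rms(flow[ev]), 0.05 * rms(flow[pre]))
    expect_gt(rms(effort[ev]), 0.5 * rms(effort[pre]))
  }
})

test_that("zero apnea rate leaves channels untouched", {
  cfg <- quiet_config(seed = 8, duration = 60)
  gen <- generate_recording(cfg)
  expect_equal(nrow(gen$truth$apnea_events), 0)
})

test_that("impossible apnea placements error after bounded retries", {
  cfg <- synth_config(seed = 9, duration = 60, hypnogram = rem_heavy(),
                      apnea = list(rate = c(W = 0, NREM = 0, REM = 600),
                                   duration_mean = 20, duration_sd = 1,
                                   duration_min = 15))
  hyp <- generate_hypnogram(cfg)$hypnogram
  bt <- generate_breath_train(cfg, hyp, seed = NULL)
  expect_error(inject_apneas(bt$flow, bt$effort, bt$breath_table, hyp, cfg,
                             max_tries = 20),
               "non-overlapping")
})

test_that("SpO2 trace honors baseline, depth and sub-threshold rules", {
  cfg <- quiet_config(seed = 10, duration = 120,
                      spo2 = list(noise_sd = 0.3))
  # no events: bounded noise around baseline
  sp0 <- generate_spo2(data.frame(t_start = numeric(), duration = numeric(),
                                  stage = character()),
                       cfg, 120 * cfg$sample_rate, seed = 1)
  expect_gte(min(sp0$spo2), 96 - 3 * 0.3 - 1e-9)
  expect_equal(nrow(sp0$desat_events), 0)
  # a 6% event crosses baseline - 4 for a contiguous stretch
  cfg6 <- quiet_config(seed = 10, duration = 120,
                       spo2 = list(desat_depth_mean = 6, desat_depth_sd = 0,
                                   noise_sd = 0))
  ap <- data.frame(t_start = 30, duration = 1, stage = "REM")
  sp6 <- generate_spo2(ap, cfg6, 120 * cfg6$sample_rate, seed = 1)
  expect_true(any(sp6$spo2 <= 96 - 4))
  # a 2% event never reaches the 4% scoring threshold
  cfg2 <- quiet_config(seed = 10, duration = 120,
                       spo2 = list(desat_depth_mean = 2, desat_depth_sd = 0,
                                   noise_sd = 0))
  sp2 <- generate_spo2(ap, cfg2, 120 * cfg2$sample_rate, seed = 1)
  expect_false(any(sp2$spo2 <= 96 - 4))
  expect_true(all(sp2$spo2 > 0 & sp2$spo2 <= 100))
})

test_that("EEG band structure and EMG tone follow the stage signatures", {
  cfg <- quiet_config(seed = 11, duration = 60)
  hyp_n <- hypnogram(rep("NREM", 12))
  en <- generate_eeg_emg(hyp_n, cfg, seed = 3)
  f <- epoch_features(en$eeg, en$emg, cfg$sample_rate)
  expect_true(all(f$p_low > f$p_high))
  hyp_w <- hypnogram(rep("W", 12))
  hyp_r <- hypnogram(rep("REM", 12))
  ew <- generate_eeg_emg(hyp_w, cfg, seed = 3)
  er <- generate_eeg_emg(hyp_r, cfg, seed = 3)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(ew$emg), rms(er$emg))
  e1 <- generate_eeg_emg(hyp_w, cfg, seed = 5)
  e2 <- generate_eeg_emg(hyp_w, cfg, seed = 5)
  expect_identical(e1$eeg, e2$eeg)
  bad <- hyp_w
  bad$stages[3] <- "REM"  # fine
  expect_error(generate_eeg_emg(structure(list(epoch_len = 5,
                                               stages = c("W", "X"),
                                               source = "external"),
                                          class = "wbp_hypnogram"),
                                cfg, seed = 1),
               "unknown stage")
})

test_that("hypnogram generation honors forced weights, length and determinism", {
  cfg_w <- quiet_config(seed = 12, duration = 3600,
                        hypnogram = list(transition = list(W = c(W = 1)),
                                         bout_mean = c(W = 120, NREM = 160,
                                                       REM = 60)))
  h <- generate_hypnogram(cfg_w)
  expect_equal(length(h$hypnogram$stages), 720)
  expect_true(all(h$hypnogram$stages == "W"))
  cfg_m <- quiet_config(seed = 13, duration = 1800)
  h1 <- generate_hypnogram(cfg_m)
  h2 <- generate_hypnogram(cfg_m)
  expect_identical(h1$hypnogram$stages, h2$hypnogram$stages)
  # REM entered only from NREM under the default weights
  s <- h1$hypnogram$stages
  into_rem <- which(s[-1] == "REM" & s[-length(s)] != "REM") + 1
  expect_true(all(s[into_rem - 1] == "NREM"))
})

test_that("CO2 protocol scales plateau minute ventilation by the gain", {
  cfg <- synth_config(seed = 20, co2_protocol = list(c(0, 300), c(8, 300)),
                      hcvr_gain = 10,
                      hypnogram = list(transition = list(W = c(W = 1)),
                                       bout_mean = c(W = 600, NREM = 160,
                                                     REM = 60)),
                      apnea = list(rate = c(W = 0, NREM = 0, REM = 0)))
  gen <- generate_recording(cfg)
  fl <- get_channel(gen$recording, "flow")
  b <- breath_features(fl, segment_breaths(fl), hyp = gen$truth$hypnogram_true)
  ve0 <- mean(b$inst_ve[b$t_start >= 120 & b$t_start < 300])
  ve8 <- mean(b$inst_ve[b$t_start >= 420 & b$t_start < 600])
  expect_equal(ve8 - ve0, 80, tolerance = 0.05 * 80)
})

test_that("Poisson activity totals fall in the expected interval", {
  cfg <- quiet_config(seed = 21, duration = 60 * 66,
                      metabolism = list(activity_rate = 6))
  mt <- generate_metabolic_traces(cfg, seed = cfg$seed)
  total <- sum(mt$activity)
  lam <- 6 * 66
  expect_gte(total, qpois(0.005, lam))
  expect_lte(total, qpois(0.995, lam))
  cfg0 <- quiet_config(seed = 21, duration = 60 * 66,
                       metabolism = list(activity_rate = 0))
  expect_equal(sum(generate_metabolic_traces(cfg0, seed = 1)$activity), 0)
})
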
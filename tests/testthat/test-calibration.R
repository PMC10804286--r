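test_that("saturated vapor pressure matches steam-table values and is monotone", {
  # 37 degC: published steam-table value ~47.07 mm Hg
  expect_equal(saturated_vapor_pressure(310.15), 47.07, tolerance = 0.005)
  expect_lt(saturated_vapor_pressure(303), saturated_vapor_pressure(310))
  expect_error(saturated_vapor_pressure(373.15), "range")
  expect_error(saturated_vapor_pressure(250), "range")
})

test_that("Drorbaugh-Fenn factor equals an independent arithmetic oracle on a grid", {
  grid <- expand.grid(
    t_b = seq(35, 39, length.out = 5),
    t_c = seq(24, 31, length.out = 5),
    p_b = c(680, 740, 760, 770),
    rh = c(0.5, 0.9)
  )
  svp_oracle <- function(tc_deg) 10^(8.07131 - 1730.63 / (233.426 + tc_deg))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    ctx <- calibration_context(g$t_b, g$t_c, humidity = g$rh, barometric = g$p_b,
                               calibration_volume = 0.05,
                               calibration_deflection = 1)
    # independent evaluation with its own grouping of the same closed form
    tb_k <- 273.15 + g$t_b
    tc_k <- 273.15 + g$t_c
    ph2o_tb <- svp_oracle(g$t_b)
    ph2o_tc <- g$rh * svp_oracle(g$t_c)
    oracle <- 1 / (1 - (tc_k / tb_k) * ((g$p_b - ph2o_tb) / (g$p_b - ph2o_tc)))
    expect_equal(drorbaugh_fenn_factor(ctx), oracle, tolerance = 1e-12)
    expect_gt(drorbaugh_fenn_factor(ctx), 1)
  }
})

test_that("degenerate chamber conditions raise the documented error", {
  ctx <- calibration_context(30, 30, humidity = 1, barometric = 760,
                             calibration_volume = 0.05,
                             calibration_deflection = 1)
  expect_error(drorbaugh_fenn_factor(ctx), class = "wbp_degenerate_conditions")
})

test_that("a warmer body gives a larger pressure signal per volume (smaller factor)", {
  # raising body temperature increases both the numerator and, via the body
  # vapor-pressure term, the denominator even faster: F falls monotonically
  f_at <- function(tb) {
    drorbaugh_fenn_factor(calibration_context(tb, 29, humidity = 0.9,
                                              barometric = 760,
                                              calibration_volume = 0.05,
                                              calibration_deflection = 1))
  }
  vals <- vapply(c(35, 36, 37, 38, 39), f_at, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("pressure-to-volume conversion is exactly linear", {
  ctx <- calibration_context(37, 29, humidity = 0.9, barometric = 760,
                             calibration_volume = 0.05,
                             calibration_deflection = 2)
  f <- drorbaugh_fenn_factor(ctx)
  p1 <- sin(seq(0, 10, length.out = 500))
  p2 <- cos(seq(0, 10, length.out = 500))
  expect_equal(pressure_to_volume(3 * p1 - 2 * p2, ctx),
               3 * pressure_to_volume(p1, ctx) - 2 * pressure_to_volume(p2, ctx),
               tolerance = 1e-12)
  # constant deflection equal to the calibration deflection reads V_K * F
  expect_equal(pressure_to_volume(rep(2, 10), ctx), rep(0.05 * f, 10))
  expect_equal(pressure_to_volume(rep(0, 10), ctx), rep(0, 10))
})

test_that("volume differentiation is exact for linear and accurate for sine", {
  fs <- 1000
  expect_equal(differentiate_volume(rep(3, 100), fs), rep(0, 100))
  t <- (0:999) / fs
  lin <- differentiate_volume(5 * t, fs)
  expect_equal(lin[2:999], rep(5, 998))
  v <- sin(2 * pi * 2.5 * t)
  truth <- 2 * pi * 2.5 * cos(2 * pi * 2.5 * t)
  d <- differentiate_volume(v, fs)
  interior <- 2:999
  rms_err <- sqrt(mean((d[interior] - truth[interior])^2)) /
    sqrt(mean(truth[interior]^2))
  expect_lt(rms_err, 1e-3)
  expect_error(differentiate_volume(c(1, 2), fs), "3 samples")
})

test_that("generated pressure channel round-trips to the emitted volume", {
  gen <- generate_recording(quiet_config(seed = 4, duration = 60,
                                         breath = list(amplitude_noise_sd = 0)))
  rec <- gen$recording
  env <- rec$meta
  ctx <- calibration_context(env$body_temp, env$chamber_temp, env$room_temp,
                             env$humidity, env$barometric,
                             env$calibration_volume, env$calibration_deflection)
  vol <- pressure_to_volume(get_channel(rec, "chamber_pressure"), ctx)
  truth_vol <- get_channel(rec, "volume")$samples
  scale <- max(abs(truth_vol))
  expect_lt(max(abs(vol$samples - truth_vol)) / scale, 1e-3)
})
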
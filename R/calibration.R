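# Chamber-pressure -> tidal-volume calibration.
#
# Whole-body plethysmography infers tidal volume from the pressure swing a
# breath produces in a sealed chamber: inspired air is warmed to body
# temperature and saturated with water vapor, so the thoracic gas expands
# relative to chamber conditions. The Drorbaugh-Fenn barometric relation
# scales the pressure deflection of a known calibration injection by a
# gas-conditions factor
#
#   F = T_B (P_B - P_H2O_TC) /
#       [ T_B (P_B - P_H2O_TC) - T_C (P_B - P_H2O_TB) ]
#
# with T_B body (rectal) and T_C chamber temperature in kelvin, P_B
# barometric pressure, P_H2O_TB saturated water vapor pressure at body
# temperature and P_H2O_TC the chamber water vapor pressure (relative
# humidity times the saturated value at T_C). Tidal volume is then
# V(t) = (P(t) / P_K) * V_K * F for a calibration injection of V_K mL
# producing deflection P_K.

#' Saturated water vapor pressure (Antoine equation)
#'
#' Antoine form `log10(P[mm Hg]) = A - B / (C + T[degC])` with the standard
#' water constants for 1-100 degC: A = 8.07131, B = 1730.63, C = 233.426.
#' Validated for the physiological range only; temperatures outside
#' (270, 320) K are rejected.
#'
#' @param temp_k temperature in kelvin.
#' @return saturated vapor pressure in mm Hg.
#' @export
saturated_vapor_pressure <- function(temp_k) {
  stopifnot(is.numeric(temp_k))
  if (any(temp_k <= 270 | temp_k >= 320)) {
    stop("temperature out of validated range (270, 320) K")
  }
  tc <- temp_k - 273.15
  10^(8.07131 - 1730.63 / (233.426 + tc))
}

#' Build a calibration context
#'
#' Collects the chamber/animal conditions and the calibration injection
#' needed by the Drorbaugh-Fenn conversion. Temperatures are given in degC
#' (as recorded at the bench) and stored in kelvin; vapor pressures are
#' derived via [saturated_vapor_pressure()].
#'
#' @param body_temp,chamber_temp,room_temp temperatures in degC.
#' @param humidity chamber relative humidity, fraction in `[0, 1]`.
#' @param barometric barometric pressure in mm Hg, in (500, 800).
#' @param calibration_volume injected calibration volume V_K in mL, > 0.
#' @param calibration_deflection pressure deflection P_K produced by the
#'   injection, in the units of the pressure channel, > 0.
#' @return an object of class `wbp_calibration`.
#' @export
calibration_context <- function(body_temp, chamber_temp, room_temp = chamber_temp,
                                humidity, barometric,
                                calibration_volume, calibration_deflection) {
  t_b <- body_temp + 273.15
  t_c <- chamber_temp + 273.15
  t_r <- room_temp + 273.15
  for (tk in c(t_b, t_c, t_r)) {
    if (tk <= 270 || tk >= 320) stop("temperature out of range (270, 320) K")
  }
  stopifnot(humidity >= 0, humidity <= 1)
  if (barometric <= 500 || barometric >= 800) {
    stop("barometric pressure out of range (500, 800) mm Hg")
  }
  stopifnot(calibration_volume > 0, calibration_deflection > 0)
  structure(
    list(
      v_k = calibration_volume, p_k = calibration_deflection,
      t_b = t_b, t_c = t_c, t_r = t_r, rh = humidity, p_b = barometric,
      p_h2o_tb = saturated_vapor_pressure(t_b),
      p_h2o_tc = humidity * saturated_vapor_pressure(t_c)
    ),
    class = "wbp_calibration"
  )
}

#' Drorbaugh-Fenn conversion factor
#'
#' Computes the dimensionless factor F above. For physiological inputs
#' (body warmer and wetter than the chamber) F > 1. A vanishing denominator
#' (body and chamber at the same temperature with saturated chamber air)
#' makes the barometric method degenerate and raises an error of class
#' `wbp_degenerate_conditions`.
#'
#' @param ctx a [calibration_context()].
#' @return the conversion factor, dimensionless.
#' @export
drorbaugh_fenn_factor <- function(ctx) {
  stopifnot(inherits(ctx, "wbp_calibration"))
  num <- ctx$t_b * (ctx$p_b - ctx$p_h2o_tc)
  den <- num - ctx$t_c * (ctx$p_b - ctx$p_h2o_tb)
  if (!is.finite(den) || abs(den) < 1e-9 * abs(num) || den < 0) {
    stop(structure(
      class = c("wbp_degenerate_conditions", "error", "condition"),
      list(message = paste0(
        "degenerate chamber conditions: Drorbaugh-Fenn denominator ",
        format(den), " (body and chamber gas states too similar)"),
        call = sys.call(-1))
    ))
  }
  num / den
}

#' Convert a chamber-pressure channel to tidal volume
#'
#' `V(t) = (P(t) / P_K) * V_K * F`; exactly linear in the pressure signal.
#'
#' @param pressure a `wbp_channel` with role `chamber_pressure` (or a bare
#'   numeric vector).
#' @param ctx a [calibration_context()].
#' @return a `wbp_channel` of role `volume` in mL (or a numeric vector if
#'   the input was bare).
#' @export
pressure_to_volume <- function(pressure, ctx) {
  f <- drorbaugh_fenn_factor(ctx)
  scale <- ctx$v_k * f / ctx$p_k
  if (inherits(pressure, "wbp_channel")) {
    ts_channel(pressure$samples * scale, "volume", "mL", pressure$sample_rate)
  } else {
    as.numeric(pressure) * scale
  }
}

#' Differentiate a volume channel into airflow
#'
#' Second-order central difference on interior samples, one-sided first
#' differences at the two edges. Optional zero-phase Butterworth low-pass
#' smoothing (4th order, forward-backward), off by default; murine
#' breathing lives well below the default 20 Hz cutoff.
#'
#' @param volume a `wbp_channel` of role `volume` (or numeric vector, in
#'   which case `sample_rate` must be supplied).
#' @param sample_rate Hz; taken from the channel when omitted.
#' @param smooth apply the low-pass after differentiation?
#' @param cutoff_hz low-pass cutoff in Hz.
#' @return a `wbp_channel` of role `flow` in mL/s (or a numeric vector).
#' @export
differentiate_volume <- function(volume, sample_rate = NULL, smooth = FALSE,
                                 cutoff_hz = 20) {
  if (inherits(volume, "wbp_channel")) {
    v <- volume$samples
    fs <- volume$sample_rate
  } else {
    v <- as.numeric(volume)
    if (is.null(sample_rate)) stop("sample_rate required for bare vectors")
    fs <- sample_rate
  }
  n <- length(v)
  if (n < 3) stop("need >= 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) * fs / 2
  d[1] <- (v[2] - v[1]) * fs
  d[n] <- (v[n] - v[n - 1]) * fs
  if (smooth) {
    bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
    d <- as.numeric(signal::filtfilt(bf, d))
  }
  if (inherits(volume, "wbp_channel")) {
    ts_channel(d, "flow", "mL/s", fs)
  } else {
    d
  }
}
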
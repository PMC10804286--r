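# Open-circuit indirect calorimetry on the CLAMS 11-min sampling grid.
#
# With inflow rate F and gas fractions measured at the inlet and outlet,
# the Haldane transformation accounts for the inequality of inflow and
# outflow volumes via the inert-gas balance:
#
#   H    = (1 - FiO2_in - FiCO2_in) / (1 - FiO2_out - FiCO2_out)
#   VO2  = F * (FiO2_in  - FiO2_out  * H)
#   VCO2 = F * (FiCO2_out * H - FiCO2_in)
#
# and RER = VCO2 / VO2. Gas rates are reported in mL/h (optionally
# mass-normalized); they are converted to mL/min only inside the
# ventilation/metabolism coupling ratios.

#' Haldane-corrected open-circuit gas exchange rates
#'
#' @param fio2_in,fio2_out,fico2_in,fico2_out gas fractions in (0, 1)
#'   (vectors are recycled to a common length).
#' @param flow_rate circuit flow in mL/min.
#' @return list of vectors `vo2`, `vco2` in mL/min.
#' @export
open_circuit_rates <- function(fio2_in, fio2_out, fico2_in, fico2_out,
                               flow_rate) {
  stopifnot(flow_rate > 0)
  fr <- cbind(fio2_in, fio2_out, fico2_in, fico2_out)
  if (any(fr <= 0 | fr >= 1)) stop("gas fractions must lie in (0, 1)")
  if (any(fio2_in + fico2_in >= 1) || any(fio2_out + fico2_out >= 1)) {
    stop("gas fractions sum to >= 1")
  }
  h <- (1 - fio2_in - fico2_in) / (1 - fio2_out - fico2_out)
  list(vo2 = flow_rate * (fio2_in - fio2_out * h),
       vco2 = flow_rate * (fico2_out * h - fico2_in))
}

#' Bin rates onto the sampling grid
#'
#' Per-bin means on a fixed grid (default 11 min, the CLAMS collection
#' interval), with a light/dark phase label from the configured lights-on
#' window.
#'
#' @param t sample times, seconds.
#' @param rates named list/data frame of numeric vectors aligned with `t`.
#' @param bin_s grid step in seconds.
#' @param lights_on `c(start_s, end_s)` of the light phase within the
#'   24-h day (seconds from midnight modulo 86400); bins are labeled by
#'   their start time.
#' @param t0_clock recording start as seconds from midnight.
#' @return data frame: `bin_start`, `phase`, one mean column per rate.
#' @export
sample_grid <- function(t, rates, bin_s = 660,
                        lights_on = c(7, 19) * 3600, t0_clock = 10 * 3600) {
  stopifnot(length(t) >= 1, max(t) >= bin_s)
  bins <- floor(t / bin_s)
  starts <- sort(unique(bins)) * bin_s
  out <- data.frame(bin_start = starts)
  clock <- (t0_clock + starts) %% 86400
  out$phase <- ifelse(clock >= lights_on[1] & clock < lights_on[2],
                      "light", "dark")
  for (nm in names(rates)) {
    out[[nm]] <- as.numeric(tapply(rates[[nm]], bins, mean))
  }
  out
}

#' Activity counts per bin and in total
#'
#' @param activity a `wbp_channel` (impulse counts per sample) or numeric
#'   vector with `sample_rate`.
#' @param bin_s grid step in seconds.
#' @param sample_rate Hz for bare vectors.
#' @return list: `per_bin` data frame (`bin_start`, `count`) and `total`.
#' @export
activity_counts <- function(activity, bin_s = 660, sample_rate = NULL) {
  if (inherits(activity, "wbp_channel")) {
    sample_rate <- activity$sample_rate
    activity <- activity$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required for bare vectors")
  t <- (seq_along(activity) - 1) / sample_rate
  bins <- floor(t / bin_s)
  per_bin <- data.frame(
    bin_start = sort(unique(bins)) * bin_s,
    count = as.numeric(tapply(activity, bins, sum))
  )
  list(per_bin = per_bin, total = sum(activity))
}

#' Metabolic summary of a recording
#'
#' Runs the open-circuit computation over the gas-fraction channels, bins
#' everything on the 11-min grid and reports mL/h rates with the exact RER
#' identity per bin.
#'
#' @param rec a [wbp_recording()] with `fio2_in`, `fio2_out`, `fico2_in`,
#'   `fico2_out` channels (fractions) and `flow_rate` in `meta` (mL/min).
#' @param mass_g optional body mass for mL/kg/h normalization.
#' @return list: `bins` (data frame with `vo2`, `vco2`, `rer` per bin, mL/h),
#'   `vo2`, `vco2`, `rer` (whole-recording means), `activity_total`.
#' @export
metabolic_summary <- function(rec, mass_g = NULL) {
  chs <- lapply(c("fio2_in", "fio2_out", "fico2_in", "fico2_out"),
                function(r) get_channel(rec, r))
  flow_rate <- rec$meta$flow_rate
  if (is.null(flow_rate)) stop("recording meta lacks 'flow_rate' (mL/min)")
  fs <- chs[[1]]$sample_rate
  t <- (seq_along(chs[[1]]$samples) - 1) / fs
  rates <- open_circuit_rates(chs[[1]]$samples, chs[[2]]$samples,
                              chs[[3]]$samples, chs[[4]]$samples, flow_rate)
  bins <- sample_grid(t, list(vo2 = rates$vo2 * 60, vco2 = rates$vco2 * 60))
  bins$rer <- bins$vco2 / bins$vo2
  act <- get_channel(rec, "activity", required = FALSE)
  vo2 <- mean(bins$vo2); vco2 <- mean(bins$vco2)
  norm <- if (!is.null(mass_g)) 1000 / mass_g else 1
  list(bins = bins, vo2 = vo2 * norm, vco2 = vco2 * norm, rer = vco2 / vo2,
       activity_total = if (!is.null(act)) sum(act$samples) else NA_real_)
}

#' Ventilation/metabolism coupling ratios
#'
#' Dimensionless VE/VO2 and VE/VCO2 with both numerator and denominator in
#' mL/min, on matched time support.
#'
#' @param ve_ml_min minute ventilation, mL/min.
#' @param vo2_ml_h,vco2_ml_h gas exchange rates, mL/h.
#' @return list `ve_over_vo2`, `ve_over_vco2`; zero denominators yield `NA`
#'   with a warning.
#' @export
coupling_ratios <- function(ve_ml_min, vo2_ml_h, vco2_ml_h) {
  vo2_mlmin <- vo2_ml_h / 60
  vco2_mlmin <- vco2_ml_h / 60
  bad <- vo2_mlmin == 0 | vco2_mlmin == 0
  if (any(bad)) warning("zero metabolic rate; coupling ratio undefined")
  list(
    ve_over_vo2 = ifelse(vo2_mlmin == 0, NA_real_, ve_ml_min / vo2_mlmin),
    ve_over_vco2 = ifelse(vco2_mlmin == 0, NA_real_, ve_ml_min / vco2_mlmin)
  )
}
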
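# Hypercapnic ventilatory response (HCVR).
#
# Animals breathe graded inspired CO2 (0-8%); after a 60 s transition the
# ventilatory response plateaus, and the HCVR is the least-squares slope of
# minute ventilation on inspired CO2 percentage during wakefulness.

#' Plateau minute ventilation over one CO2-level window
#'
#' Averages instantaneous minute ventilation over breaths starting from
#' `settle_s` after the gas switch to the window end, restricted to wake
#' epochs.
#'
#' @param breaths output of [breath_features()] with stages attached.
#' @param window `c(t_start, t_end)` of the CO2 level, seconds; must span
#'   at least `min_window_s`.
#' @param settle_s transition time excluded after the switch.
#' @param min_window_s minimal admissible window length.
#' @param wake_only restrict to breaths in wake epochs.
#' @return mean VE in mL/min; `NA` with a warning when no eligible breaths.
#' @export
plateau_ventilation <- function(breaths, window, settle_s = 60,
                                min_window_s = 90, wake_only = TRUE) {
  stopifnot(length(window) == 2, window[2] > window[1])
  if (window[2] - window[1] < min_window_s) {
    stop("CO2-level window must span >= ", min_window_s, " s")
  }
  sel <- breaths$t_start >= window[1] + settle_s & breaths$t_start < window[2]
  if (wake_only) sel <- sel & breaths$stage == "W"
  if (!any(sel)) {
    warning("no eligible (wake) breaths in window [", window[1], ", ",
            window[2], ")")
    return(NA_real_)
  }
  mean(breaths$inst_ve[sel])
}

#' HCVR slope by ordinary least squares
#'
#' @param levels inspired CO2 percentages (>= 2 distinct values).
#' @param ve plateau minute ventilation per level, mL/min.
#' @return an object of class `wbp_hcvr`: `levels`, `ve_per_level`, `slope`
#'   (mL/min per %CO2), `intercept`, `r_squared`.
#' @export
hcvr_slope <- function(levels, ve) {
  stopifnot(length(levels) == length(ve), length(levels) >= 2)
  keep <- is.finite(levels) & is.finite(ve)
  levels <- levels[keep]; ve <- ve[keep]
  if (length(unique(levels)) < 2) stop("need >= 2 distinct CO2 levels")
  if (length(levels) == 2) {
    # exact difference quotient for the common two-level protocol
    slope <- (ve[2] - ve[1]) / (levels[2] - levels[1])
    intercept <- ve[1] - slope * levels[1]
    r2 <- 1
  } else {
    fit <- stats::lm(ve ~ levels)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    ss_tot <- sum((ve - mean(ve))^2)
    r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  }
  structure(list(levels = levels, ve_per_level = ve, slope = slope,
                 intercept = intercept, r_squared = r2),
            class = "wbp_hcvr")
}

#' @export
print.wbp_hcvr <- function(x, ...) {
  cat(sprintf("<wbp_hcvr> slope %.3f mL/min/%%CO2, intercept %.2f, R^2 %.4f (%d levels)\n",
              x$slope, x$intercept, x$r_squared, length(x$levels)))
  invisible(x)
}

#' Compute the HCVR from a recording with a CO2 protocol
#'
#' Reads the protocol (list of `(co2_pct, duration_s)` steps) from the
#' recording metadata, computes the plateau VE of each level and fits the
#' slope.
#'
#' @param breaths output of [breath_features()] with stages attached.
#' @param protocol list of `c(co2_pct, duration_s)` in recording order.
#' @param settle_s transition exclusion per level, seconds.
#' @param wake_only restrict plateau VE to wake breaths.
#' @return a `wbp_hcvr` object (see [hcvr_slope()]).
#' @export
hcvr_from_protocol <- function(breaths, protocol, settle_s = 60,
                               wake_only = TRUE) {
  stopifnot(length(protocol) >= 2)
  t0 <- 0
  levels <- numeric(0); ve <- numeric(0)
  for (step in protocol) {
    lev <- step[1]; dur <- step[2]
    ve <- c(ve, plateau_ventilation(breaths, c(t0, t0 + dur),
                                    settle_s = settle_s,
                                    wake_only = wake_only))
    levels <- c(levels, lev)
    t0 <- t0 + dur
  }
  res <- hcvr_slope(levels, ve)
  res$plateau_windows <- protocol
  res
}
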
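# Apnea and oxygen-desaturation scoring.
#
# Apneas: >= 90% reduction in airflow lasting two or more breath cycles or
# >= 0.7 s at the baseline respiratory rate. The airflow reference is the
# running median of the maximal inspiratory flow of the preceding 10
# breaths. Candidate quiet intervals are found by thresholding |flow| at
# 10% of that reference; their boundaries are snapped to the enclosing
# breath boundaries so the naturally quiet late-expiratory tail of the
# preceding breath does not inflate event duration.
#
# Desaturations: >= 4% drop of SpO2 below a running baseline (90th
# percentile of the preceding 120 s), lasting at least two local breath
# cycles; the ODI is desaturations per hour of total sleep (NREM + REM).

#' Detect apneas in a flow signal
#'
#' @param flow a `wbp_channel` or numeric vector (mL/s).
#' @param breaths output of [breath_features()] on the same signal.
#' @param hyp a [hypnogram()]; each event gets the stage of its onset epoch.
#' @param baseline_rr baseline respiratory rate (breaths/min); when `NULL`,
#'   the median instantaneous rate over all breaths.
#' @param sample_rate Hz for bare vectors.
#' @param depth_frac flow-reduction threshold as residual fraction (0.10 =
#'   "\eqn{\ge} 90% reduction").
#' @param duration_rule `"either"` (default) accepts an event lasting at
#'   least `min(2 * 60 / baseline_rr, 0.7)` s, i.e. either clause of the
#'   scoring definition suffices; `"both"` requires the max of the two.
#' @return data frame of events: `kind`, `t_start`, `duration`, `stage`,
#'   `magnitude` (% flow reduction).
#' @export
detect_apneas <- function(flow, breaths, hyp, baseline_rr = NULL,
                          sample_rate = NULL, depth_frac = 0.10,
                          duration_rule = c("either", "both")) {
  duration_rule <- match.arg(duration_rule)
  if (inherits(flow, "wbp_channel")) {
    sample_rate <- flow$sample_rate
    flow <- flow$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required for bare vectors")
  fs <- sample_rate
  if (nrow(breaths) < 1) stop("no baseline breaths available")
  if (is.null(baseline_rr)) baseline_rr <- stats::median(breaths$inst_rr)
  stopifnot(baseline_rr > 0)
  cyc <- 60 / baseline_rr
  dur_min <- if (duration_rule == "either") min(2 * cyc, 0.7) else max(2 * cyc, 0.7)

  # running local baseline: median v_i_max of the preceding 10 breaths,
  # held piecewise-constant between breath onsets
  vmax <- breaths$v_i_max
  nb <- length(vmax)
  base_b <- vapply(seq_len(nb), function(k) {
    lo <- max(1, k - 10)
    hi <- max(1, k - 1)
    stats::median(vmax[lo:hi])
  }, 0)
  base_t <- stats::approx(breaths$t_start, base_b,
                          xout = (seq_along(flow) - 1) / fs,
                          method = "constant", rule = 2)$y

  quiet <- abs(flow) <= depth_frac * base_t
  r <- rle(quiet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  te_med <- stats::median(breaths$te)
  events <- list()
  for (ci in cand) {
    t0 <- (starts[ci] - 1) / fs
    t1 <- ends[ci] / fs
    # a segmented breath's t_end runs to the next inspiration onset, so an
    # apnea gap is swallowed by the preceding breath's "expiration"; snap
    # the event start to that breath's expected expiratory end
    # (t_insp_end + median Te) and the event end to the next onset
    nxt <- which(breaths$t_start > t0 & breaths$t_start <= t1 + 2 / fs)
    if (length(nxt)) t1 <- min(t1, min(breaths$t_start[nxt]))
    prev <- which(breaths$t_insp_end <= t0 & breaths$t_start <= t0)
    if (length(prev)) {
      est_end <- breaths$t_insp_end[prev[length(prev)]] + te_med
      t0 <- min(max(t0, est_end), t1)
    }
    dur <- t1 - t0
    if (dur < dur_min) next
    sl <- max(1, floor(t0 * fs) + 1):min(length(flow), ceiling(t1 * fs))
    resid <- max(abs(flow[sl]))
    basel <- max(base_t[sl])
    events[[length(events) + 1]] <- data.frame(
      kind = "apnea", t_start = t0, duration = dur,
      stage = stage_at(hyp, t0),
      magnitude = 100 * (1 - resid / basel)
    )
  }
  if (length(events) == 0) {
    return(data.frame(kind = character(), t_start = numeric(),
                      duration = numeric(), stage = character(),
                      magnitude = numeric()))
  }
  do.call(rbind, events)
}

#' Per-hour apnea index by stage
#'
#' @param events output of [detect_apneas()].
#' @param hyp a [hypnogram()].
#' @param stage stage label, e.g. `"REM"`.
#' @return events per hour of that stage; `NA` with a warning when the
#'   stage does not occur.
#' @export
apnea_index <- function(events, hyp, stage) {
  hours <- sum(hyp$stages == stage) * hyp$epoch_len / 3600
  if (hours == 0) {
    warning("no time spent in stage ", stage, "; index undefined")
    return(NA_real_)
  }
  sum(events$kind == "apnea" & events$stage == stage) / hours
}

#' Detect oxygen desaturations and compute the ODI
#'
#' The SpO2 baseline is the 90th percentile over the preceding 120 s,
#' evaluated on a 10 Hz decimated copy of the signal (desaturation
#' dynamics are far slower than breathing). An event is a maximal interval
#' with SpO2 at or below `baseline - 4` lasting at least two local breath
#' cycles. Only events starting in sleep count toward the ODI, whose
#' denominator is hours of total sleep.
#'
#' @param spo2 a `wbp_channel` (%) or numeric vector.
#' @param hyp a [hypnogram()].
#' @param breaths output of [breath_features()] (for the local cycle
#'   length); `NULL` falls back to 0.4 s cycles.
#' @param sample_rate Hz for bare vectors.
#' @param drop_pct required depth below baseline, percentage points.
#' @param baseline_window_s,baseline_quantile running-baseline parameters.
#' @return list: `events` (data frame like [detect_apneas()]'s, with
#'   `magnitude` = maximal drop below baseline) and `odi` (events/h sleep;
#'   `NA` flagged with a warning when there is no sleep).
#' @export
detect_desaturations <- function(spo2, hyp, breaths = NULL, sample_rate = NULL,
                                 drop_pct = 4, baseline_window_s = 120,
                                 baseline_quantile = 0.9) {
  if (inherits(spo2, "wbp_channel")) {
    sample_rate <- spo2$sample_rate
    spo2 <- spo2$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required for bare vectors")
  fs_d <- 10
  dec <- max(1L, round(sample_rate / fs_d))
  x <- spo2[seq(1, length(spo2), by = dec)]
  fs_d <- sample_rate / dec
  n <- length(x)
  win <- round(baseline_window_s * fs_d)
  base <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - win)
    hi <- max(1, i - 1)
    stats::quantile(x[lo:hi], baseline_quantile, names = FALSE)
  }, 0)
  cyc <- if (!is.null(breaths) && nrow(breaths) > 0) {
    stats::median(breaths$ttot)
  } else 0.4
  low <- x <= base - drop_pct
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values)
  events <- list()
  for (ci in cand) {
    t0 <- (starts[ci] - 1) / fs_d
    dur <- r$lengths[ci] / fs_d
    if (dur < 2 * cyc) next
    sl <- starts[ci]:ends[ci]
    events[[length(events) + 1]] <- data.frame(
      kind = "desaturation", t_start = t0, duration = dur,
      stage = stage_at(hyp, t0),
      magnitude = max(base[sl] - x[sl])
    )
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), t_start = numeric(), duration = numeric(),
               stage = character(), magnitude = numeric())
  sleep_h <- sum(hyp$stages %in% c("NREM", "REM")) * hyp$epoch_len / 3600
  odi <- if (sleep_h > 0) {
    sum(events$stage %in% c("NREM", "REM")) / sleep_h
  } else {
    warning("no sleep in hypnogram; ODI undefined")
    NA_real_
  }
  list(events = events, odi = odi)
}
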
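# Sleep staging in 5-s epochs from EEG band powers and EMG amplitude.
#
# The staging rules are an automated rendering of the standard visual
# criteria: wake = low-amplitude fast (~10-20 Hz) EEG with high EMG tone;
# NREM = high-amplitude slow (~2-5 Hz) EEG with EMG well below wake; REM =
# low-amplitude mixed theta (~5-10 Hz) EEG with EMG at or below NREM.
# Externally scored hypnograms are first-class inputs throughout the
# pipeline, so nothing downstream depends on this stager.

STAGES <- c("W", "NREM", "REM")

#' Construct a hypnogram
#'
#' @param stages character vector of `"W"`, `"NREM"`, `"REM"` per epoch.
#' @param epoch_len epoch length in seconds (fixed at 5 for scoring).
#' @param source `"scored"` (this package) or `"external"`.
#' @return an object of class `wbp_hypnogram`.
#' @export
hypnogram <- function(stages, epoch_len = 5, source = "scored") {
  stages <- as.character(stages)
  if (length(stages) == 0) stop("hypnogram must be nonempty")
  bad <- setdiff(unique(stages), STAGES)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  structure(list(epoch_len = epoch_len, stages = stages, source = source),
            class = "wbp_hypnogram")
}

#' @export
print.wbp_hypnogram <- function(x, ...) {
  tab <- table(factor(x$stages, levels = STAGES))
  cat(sprintf("<wbp_hypnogram> %d x %gs epochs (%s): W=%d NREM=%d REM=%d\n",
              length(x$stages), x$epoch_len, x$source,
              tab["W"], tab["NREM"], tab["REM"]))
  invisible(x)
}

hypnogram_duration <- function(hyp) length(hyp$stages) * hyp$epoch_len

#' Stage label at a time point
#'
#' @param hyp a [hypnogram()].
#' @param t time(s) in seconds from recording start.
#' @return stage label(s); `"unknown"` outside the hypnogram span.
#' @export
stage_at <- function(hyp, t) {
  idx <- floor(t / hyp$epoch_len) + 1
  out <- rep("unknown", length(t))
  ok <- idx >= 1 & idx <= length(hyp$stages)
  out[ok] <- hyp$stages[idx[ok]]
  out
}

band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  freq <- (seq_len(n) - 1) * fs / n
  sum(sp[freq >= lo & freq <= hi & freq <= fs / 2])
}

#' Per-epoch EEG/EMG features
#'
#' Band powers over the stage-defining bands (2-5, 5-10, 10-20 Hz) from the
#' EEG periodogram, total EEG RMS, and EMG RMS after a 30 Hz high-pass.
#'
#' @param eeg,emg `wbp_channel`s (or numeric vectors sharing `sample_rate`).
#' @param sample_rate Hz, taken from the channels when omitted.
#' @param epoch_len epoch length in seconds.
#' @return data frame with one row per complete epoch: `epoch`, `t_start`,
#'   `p_low`, `p_theta`, `p_high`, `eeg_rms`, `emg_rms`.
#' @export
epoch_features <- function(eeg, emg, sample_rate = NULL, epoch_len = 5) {
  if (inherits(eeg, "wbp_channel")) {
    sample_rate <- eeg$sample_rate
    eeg <- eeg$samples
  }
  if (inherits(emg, "wbp_channel")) emg <- emg$samples
  if (is.null(sample_rate)) stop("sample_rate required for bare vectors")
  fs <- sample_rate
  npe <- round(epoch_len * fs)
  n_ep <- floor(length(eeg) / npe)
  if (n_ep < 1) stop("signals shorter than one epoch")
  bf <- signal::butter(4, min(30 / (fs / 2), 0.99), type = "high")
  emg_hp <- as.numeric(signal::filtfilt(bf, emg))
  out <- data.frame(epoch = seq_len(n_ep))
  out$t_start <- (out$epoch - 1) * epoch_len
  feats <- t(vapply(seq_len(n_ep), function(i) {
    sl <- ((i - 1) * npe + 1):(i * npe)
    e <- eeg[sl]
    c(p_low = band_power(e, fs, 2, 5),
      p_theta = band_power(e, fs, 5, 10),
      p_high = band_power(e, fs, 10, 20),
      eeg_rms = sqrt(mean(e^2)),
      emg_rms = sqrt(mean(emg_hp[sl]^2)))
  }, numeric(5)))
  cbind(out, as.data.frame(feats))
}

#' Self-calibrate staging thresholds from a recording's features
#'
#' Wake epochs are anchored by their EEG signature (dominant 10-20 Hz
#' power, per the wake criteria); the EMG wake/sleep threshold is the
#' log-midpoint between the median EMG RMS of those epochs and of the
#' rest. This stays robust when wake is a minority of the recording and
#' the EMG histogram's deepest valley separates REM from NREM instead of
#' sleep from wake. The EEG amplitude split for NREM vs REM is the
#' geometric mean of the 20th and 80th percentile of EEG RMS over the
#' sleep-like epochs.
#'
#' @param features output of [epoch_features()].
#' @return list with `emg_thr` and `eeg_amp_thr`.
#' @export
calibrate_stage_thresholds <- function(features) {
  le <- log(features$emg_rms + 1e-12)
  wake_like <- features$p_high > features$p_low &
    features$p_high > features$p_theta
  emg_thr <- if (any(wake_like) && any(!wake_like)) {
    exp((stats::median(le[wake_like]) + stats::median(le[!wake_like])) / 2)
  } else if (all(wake_like)) {
    exp(min(le)) / 2   # uniformly wake-like: everything scores W
  } else {
    exp(max(le)) * 2   # no wake cluster: everything scores as sleep
  }
  sleep <- features$emg_rms <= emg_thr
  if (!any(sleep)) sleep <- rep(TRUE, nrow(features))
  q <- stats::quantile(features$eeg_rms[sleep], c(0.2, 0.8), names = FALSE)
  eeg_amp_thr <- sqrt(max(q[1], 1e-12) * max(q[2], 1e-12))
  list(emg_thr = emg_thr, eeg_amp_thr = eeg_amp_thr)
}

#' Stage epochs from features
#'
#' Decision rules, applied per epoch: high EMG -> W; low EMG with dominant
#' slow power and high EEG amplitude -> NREM; low EMG with dominant theta
#' and low amplitude -> REM; anything ambiguous inherits the previous
#' epoch's stage (first epoch defaults to W).
#'
#' @param features output of [epoch_features()].
#' @param thresholds output of [calibrate_stage_thresholds()]; calling with
#'   `NULL` is an error (staging must be calibrated).
#' @return a [hypnogram()] with `source = "scored"`.
#' @export
stage_epochs <- function(features, thresholds) {
  if (is.null(thresholds)) stop("staging thresholds not calibrated")
  n <- nrow(features)
  stages <- character(n)
  prev <- "W"
  for (i in seq_len(n)) {
    f <- features[i, ]
    s <- if (f$emg_rms > thresholds$emg_thr) {
      "W"
    } else if (f$p_low >= f$p_theta && f$eeg_rms >= thresholds$eeg_amp_thr) {
      "NREM"
    } else if (f$p_theta >= f$p_low && f$eeg_rms < thresholds$eeg_amp_thr) {
      "REM"
    } else {
      prev
    }
    stages[i] <- s
    prev <- s
  }
  hypnogram(stages, source = "scored")
}

#' Score a recording's sleep stages
#'
#' Convenience wrapper: features -> self-calibration -> staging. If the
#' recording already carries an external hypnogram pass it through instead.
#'
#' @param rec a [wbp_recording()] with `eeg` and `emg` channels.
#' @return a [hypnogram()].
#' @export
score_sleep <- function(rec) {
  feats <- epoch_features(get_channel(rec, "eeg"), get_channel(rec, "emg"))
  stage_epochs(feats, calibrate_stage_thresholds(feats))
}

#' Sleep-architecture summary
#'
#' Totals and bout structure: a bout is a maximal run of one stage. Total
#' sleep time is NREM + REM time.
#'
#' @param hyp a [hypnogram()].
#' @return list with `total_time_s`, `total_sleep_s`, and per-stage
#'   `time_s`, `bout_n`, `bout_mean_s`, plus the `bouts` table.
#' @export
architecture_summary <- function(hyp) {
  stopifnot(inherits(hyp, "wbp_hypnogram"))
  r <- rle(hyp$stages)
  bouts <- data.frame(
    stage = r$values,
    t_start = (cumsum(r$lengths) - r$lengths) * hyp$epoch_len,
    duration = r$lengths * hyp$epoch_len
  )
  per_stage <- lapply(STAGES, function(s) {
    b <- bouts[bouts$stage == s, , drop = FALSE]
    list(time_s = sum(b$duration), bout_n = nrow(b),
         bout_mean_s = if (nrow(b)) mean(b$duration) else NA_real_)
  })
  names(per_stage) <- STAGES
  list(
    total_time_s = hypnogram_duration(hyp),
    total_sleep_s = per_stage$NREM$time_s + per_stage$REM$time_s,
    stages = per_stage,
    bouts = bouts
  )
}
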
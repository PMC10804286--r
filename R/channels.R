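#' @keywords internal
"_PACKAGE"

#' Recognized channel roles
#'
#' Channel roles understood by the pipeline. Channels with any other role
#' string are carried through I/O untouched with role `"other"`.
#'
#' @export
CHANNEL_ROLES <- c(
  "chamber_pressure", "flow", "volume", "eeg", "emg", "spo2", "effort",
  "fio2_in", "fio2_out", "fico2_in", "fico2_out", "fico2_inspired",
  "activity", "other"
)

#' Construct a time-series channel
#'
#' A channel is a uniformly sampled real-valued signal with a role, a unit
#' and a sample rate. All channels of a recording start at time 0; sample
#' `i` covers `[(i-1)/sample_rate, i/sample_rate)` (half-open intervals,
#' seconds from recording start).
#'
#' @param samples numeric vector; all values must be finite.
#' @param role one of [CHANNEL_ROLES] (unknown strings are mapped to
#'   `"other"` with a warning).
#' @param unit nonempty unit string (e.g. `"mL/s"`, `"%"`, `"a.u."`).
#' @param sample_rate sampling rate in Hz, > 0.
#' @param name optional display name; defaults to the role.
#' @return an object of class `wbp_channel`.
#' @export
ts_channel <- function(samples, role, unit, sample_rate, name = role) {
  stopifnot(is.numeric(samples), length(samples) >= 1)
  if (!all(is.finite(samples))) {
    stop("channel '", role, "': all samples must be finite")
  }
  if (!is.character(unit) || !nzchar(unit)) {
    stop("channel '", role, "': unit must be a nonempty string")
  }
  if (!is.numeric(sample_rate) || sample_rate <= 0) {
    stop("channel '", role, "': sample_rate must be > 0")
  }
  if (!role %in% CHANNEL_ROLES) {
    warning("unknown channel role '", role, "' kept as 'other'")
    name <- role
    role <- "other"
  }
  structure(
    list(name = name, role = role, unit = unit,
         sample_rate = as.numeric(sample_rate),
         samples = as.numeric(samples)),
    class = "wbp_channel"
  )
}

channel_duration <- function(ch) length(ch$samples) / ch$sample_rate

#' @export
print.wbp_channel <- function(x, ...) {
  cat(sprintf("<wbp_channel> %s [%s] %g Hz, %d samples (%.1f s)\n",
              x$name, x$unit, x$sample_rate, length(x$samples),
              channel_duration(x)))
  invisible(x)
}

#' Construct a recording
#'
#' Bundles a set of channels (keyed by role) with the environmental and
#' calibration metadata needed downstream. Metadata fields required only by
#' specific operations (e.g. the Drorbaugh-Fenn conversion) are checked at
#' the point of use, not here.
#'
#' @param channels named list of [ts_channel()] objects, names = roles.
#' @param meta named list; recognized fields: `body_temp`, `chamber_temp`,
#'   `room_temp` (deg C), `humidity` (fraction), `barometric` (mm Hg),
#'   `calibration_volume` (mL), `calibration_deflection` (pressure units),
#'   `animal_mass` (g), `start_time` (ISO-8601 string). Extra fields are
#'   preserved.
#' @return an object of class `wbp_recording`.
#' @export
wbp_recording <- function(channels, meta = list()) {
  stopifnot(is.list(channels), length(channels) >= 1)
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    names(channels) <- vapply(channels, function(ch) ch$role, "")
  }
  ok <- vapply(channels, inherits, TRUE, what = "wbp_channel")
  if (!all(ok)) stop("all channels must be wbp_channel objects")
  durs <- vapply(channels, channel_duration, 0)
  # metabolic channels run on their own coarse grid; require the fast
  # channels (>= 1 Hz) to agree to within one sample of the slowest of them
  fast <- durs[vapply(channels, function(ch) ch$sample_rate >= 1, TRUE)]
  if (length(fast) > 1) {
    tol <- 1 / min(vapply(channels[names(fast)], function(ch) ch$sample_rate, 0))
    if (diff(range(fast)) > tol + 1e-9) {
      stop("channel durations disagree by more than one sample: ",
           paste(sprintf("%s=%.4fs", names(fast), fast), collapse = ", "))
    }
  }
  structure(list(channels = channels, meta = meta), class = "wbp_recording")
}

#' @export
print.wbp_recording <- function(x, ...) {
  cat(sprintf("<wbp_recording> %d channels\n", length(x$channels)))
  for (ch in x$channels) print(ch)
  invisible(x)
}

#' Fetch a channel by role
#'
#' @param rec a [wbp_recording()].
#' @param role channel role string.
#' @param required error (naming the role) if missing; otherwise NULL.
#' @return a `wbp_channel` or NULL.
#' @export
get_channel <- function(rec, role, required = TRUE) {
  ch <- rec$channels[[role]]
  if (is.null(ch) && required) {
    stop("recording has no '", role, "' channel")
  }
  ch
}
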
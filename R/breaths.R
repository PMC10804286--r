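# Breath segmentation and per-breath features.
#
# Convention: positive flow = inspiration (invertible via `invert_sign`).
# A breath runs from one onset of inspiration to the next; inspiration ends
# at the positive-to-negative flow transition. Boundaries are detected by
# signed zero crossings with a hysteresis band so that noise riding on the
# zero line does not fragment breaths.

#' Segment a flow signal into breaths
#'
#' Zero-crossing segmentation with hysteresis: the signal must exceed
#' `+hysteresis` to open inspiration and fall below `-hysteresis` to open
#' expiration; the breath boundary is then refined backwards to the actual
#' sign change. The default band is `max(3 * sigma_n, 0.05 * A95)` where
#' `sigma_n` is the robust per-sample noise SD (`mad(diff(flow)) / sqrt(2)`)
#' and `A95` the 95th percentile of `|flow|`; the floor keeps tiny
#' oscillations (e.g. residual flow during an obstructive apnea) from being
#' segmented as breaths even on noiseless signals.
#'
#' @param flow a `wbp_channel` of role `flow`, or numeric vector (mL/s).
#' @param sample_rate Hz; taken from the channel when omitted.
#' @param hysteresis override the hysteresis band (flow units).
#' @param invert_sign set `TRUE` if inspiration is negative in the raw data.
#' @return data frame with one row per complete breath: `t_start`,
#'   `t_insp_end`, `t_end` (seconds, half-open `[t_start, t_end)`), plus
#'   the sample indices `i_start`, `i_insp_end`, `i_end`.
#' @export
segment_breaths <- function(flow, sample_rate = NULL, hysteresis = NULL,
                            invert_sign = FALSE) {
  if (inherits(flow, "wbp_channel")) {
    sample_rate <- flow$sample_rate
    flow <- flow$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required for bare vectors")
  fs <- sample_rate
  if (length(flow) < 2 * fs) stop("flow signal must be >= 2 s long")
  if (invert_sign) flow <- -flow
  empty <- data.frame(t_start = numeric(), t_insp_end = numeric(),
                      t_end = numeric(), i_start = integer(),
                      i_insp_end = integer(), i_end = integer())
  if (all(flow == 0)) return(empty)
  if (is.null(hysteresis)) {
    sigma_n <- stats::mad(diff(flow)) / sqrt(2)
    hysteresis <- max(3 * sigma_n,
                      0.05 * stats::quantile(abs(flow), 0.95, names = FALSE))
  }
  # hysteresis state: +1 once flow >= +band, -1 once flow <= -band,
  # carried forward in between
  state <- integer(length(flow))
  state[flow >= hysteresis] <- 1L
  state[flow <= -hysteresis] <- -1L
  known <- which(state != 0L)
  if (length(known) == 0) return(empty)
  filled <- state
  filled[filled == 0L] <- NA_integer_
  idx <- cummax(ifelse(is.na(filled), 0L, seq_along(filled)))
  filled[idx > 0] <- state[known][findInterval(idx[idx > 0], known)]
  filled[idx == 0] <- filled[known[1]]

  up <- which(diff(filled) == 2L) + 1L    # -1 -> +1: inspiration onset
  # refine each onset backwards to the zero crossing (first positive sample)
  refine_up <- vapply(up, function(i) {
    j <- as.integer(i)
    while (j > 1 && flow[j - 1] > 0) j <- j - 1L
    j
  }, 0L)
  # a recording that opens mid/at inspiration: treat the first positive-flow
  # sample as the first onset so edge breaths are not dropped
  if (filled[known[1]] == 1L) {
    first_pos <- which(flow > 0)[1]
    if (!is.na(first_pos) && (length(refine_up) == 0 || first_pos < refine_up[1])) {
      refine_up <- c(first_pos, refine_up)
    }
  }
  refine_up <- unique(refine_up)
  if (length(refine_up) < 1) return(empty)
  # close the trailing breath at the final sample if its expiration started
  ends <- c(refine_up[-1], length(flow))
  breaths <- lapply(seq_along(refine_up), function(k) {
    i0 <- refine_up[k]
    i1 <- ends[k]
    if (i1 - i0 < 2) return(NULL)
    seg <- filled[i0:(i1 - 1)]
    dn <- which(diff(seg) == -2L)  # +1 -> -1 within the breath
    if (length(dn) == 0) return(NULL)
    ie <- i0 + dn[1]               # first sample of the -1 state
    # refine to the zero crossing (first non-positive sample)
    while (ie > i0 + 1 && flow[ie - 1] <= 0) ie <- ie - 1
    c(i0, ie, i1)
  })
  breaths <- do.call(rbind, breaths)
  if (is.null(breaths)) return(empty)
  data.frame(
    t_start = (breaths[, 1] - 1) / fs,
    t_insp_end = (breaths[, 2] - 1) / fs,
    t_end = (breaths[, 3] - 1) / fs,
    i_start = breaths[, 1], i_insp_end = breaths[, 2], i_end = breaths[, 3]
  )
}

#' Per-breath timing, volume and flow-landmark features
#'
#' For each segmented breath computes inspiratory/expiratory timing, tidal
#' volume (trapezoidal integral of inspiratory flow), the maximal
#' inspiratory flow `v_i_max`, the landmark flows `v_imax1` (peak over the
#' first half of inspiration), `v_i50` (flow at mid-inspiration) and
#' `v_imax2` (peak over the second half), mean inspiratory flow `VT/Ti`,
#' and the instantaneous rate and minute ventilation.
#'
#' @param flow a `wbp_channel` or numeric vector (mL/s).
#' @param bounds data frame from [segment_breaths()].
#' @param sample_rate Hz; taken from the channel when omitted.
#' @param hyp optional [hypnogram()] used to attach a stage per breath.
#' @return data frame (one row per breath): timing columns from `bounds`
#'   plus `ti`, `te`, `ttot`, `vt`, `v_i_max`, `v_imax1`, `v_i50`,
#'   `v_imax2`, `mean_insp_flow`, `inst_rr`, `inst_ve`, `stage`, `label`.
#' @export
breath_features <- function(flow, bounds, sample_rate = NULL, hyp = NULL) {
  if (inherits(flow, "wbp_channel")) {
    sample_rate <- flow$sample_rate
    flow <- flow$samples
  }
  if (is.null(sample_rate)) stop("sample_rate required for bare vectors")
  fs <- sample_rate
  n <- nrow(bounds)
  feat <- matrix(NA_real_, n, 8)
  for (k in seq_len(n)) {
    i0 <- bounds$i_start[k]; ie <- bounds$i_insp_end[k]
    if (ie - i0 < 1) stop("zero-length inspiration in breath ", k)
    insp <- flow[i0:ie]
    ti <- (ie - i0) / fs
    vt <- sum((insp[-1] + insp[-length(insp)]) / 2) / fs
    vmax <- max(insp)
    mid <- (length(insp) + 1) / 2           # fractional mid-inspiration index
    v_i50 <- stats::approx(seq_along(insp), insp, xout = mid)$y
    v1 <- max(insp[seq_len(floor(mid))])
    v2 <- max(insp[ceiling(mid):length(insp)])
    feat[k, ] <- c(ti, vt, vmax, v1, v_i50, v2, vt / ti, 0)
  }
  out <- cbind(bounds, data.frame(
    ti = feat[, 1],
    te = bounds$t_end - bounds$t_insp_end,
    ttot = bounds$t_end - bounds$t_start,
    vt = pmax(feat[, 2], 0),
    v_i_max = feat[, 3], v_imax1 = feat[, 4], v_i50 = feat[, 5],
    v_imax2 = feat[, 6], mean_insp_flow = feat[, 7]
  ))
  out$inst_rr <- 60 / out$ttot
  out$inst_ve <- out$vt * out$inst_rr
  out$stage <- if (is.null(hyp)) "unknown" else stage_at(hyp, out$t_start)
  out$label <- "normal"
  out$index <- seq_len(n)
  out
}

#' Select per-stage analysis windows
#'
#' Respiratory signals are analyzed from all REM periods, and from NREM
#' sampled periodically: one 20-s stretch per 30-min block, taken from the
#' first NREM run of at least 20 s in that block (`nrem_mode = "first"`;
#' `"centered"` takes the 20 s centred on that run instead). Wake is
#' excluded (the hypercapnic-response module handles wake separately).
#'
#' @param hyp a [hypnogram()].
#' @param nrem_stretch_s NREM stretch length, seconds.
#' @param nrem_block_s sampling block length, seconds.
#' @param nrem_mode `"first"` or `"centered"` placement within the run.
#' @return data frame of windows: `stage`, `t_start`, `t_end`.
#' @export
select_analysis_windows <- function(hyp, nrem_stretch_s = 20,
                                    nrem_block_s = 1800,
                                    nrem_mode = c("first", "centered")) {
  nrem_mode <- match.arg(nrem_mode)
  arch <- architecture_summary(hyp)
  bouts <- arch$bouts
  rem <- bouts[bouts$stage == "REM", , drop = FALSE]
  win <- if (nrow(rem)) {
    data.frame(stage = "REM", t_start = rem$t_start,
               t_end = rem$t_start + rem$duration)
  } else {
    data.frame(stage = character(), t_start = numeric(), t_end = numeric())
  }
  total <- hypnogram_duration(hyp)
  nrem <- bouts[bouts$stage == "NREM", , drop = FALSE]
  for (b0 in seq(0, total - 1e-9, by = nrem_block_s)) {
    b1 <- min(b0 + nrem_block_s, total)
    # NREM runs intersected with the block, needing >= stretch inside it
    for (j in seq_len(nrow(nrem))) {
      r0 <- max(nrem$t_start[j], b0)
      r1 <- min(nrem$t_start[j] + nrem$duration[j], b1)
      if (r1 - r0 >= nrem_stretch_s) {
        s0 <- if (nrem_mode == "first") r0 else (r0 + r1 - nrem_stretch_s) / 2
        win <- rbind(win, data.frame(stage = "NREM", t_start = s0,
                                     t_end = s0 + nrem_stretch_s))
        break
      }
    }
  }
  win[order(win$t_start), , drop = FALSE]
}

#' Restrict breaths to analysis windows
#'
#' A breath belongs to a window when its onset lies in `[t_start, t_end)`.
#'
#' @param breaths output of [breath_features()].
#' @param windows output of [select_analysis_windows()].
#' @return the subset of `breaths`, with a `window` id column.
#' @export
breaths_in_windows <- function(breaths, windows) {
  keep <- lapply(seq_len(nrow(windows)), function(w) {
    b <- breaths[breaths$t_start >= windows$t_start[w] &
                   breaths$t_start < windows$t_end[w], , drop = FALSE]
    if (nrow(b)) b$window <- w
    b
  })
  do.call(rbind, keep)
}

#' Per-stage ventilation summaries
#'
#' Medians and means of tidal volume, rate, minute ventilation, maximal
#' inspiratory flow and mean inspiratory flow per stage (optionally also
#' split by flow-limitation label). Per-100 g body-mass normalization of
#' the volume-based quantities is available and off by default.
#'
#' @param breaths output of [breath_features()] (optionally labeled).
#' @param by_label also split by the `label` column?
#' @param mass_g body mass in grams for per-100 g normalization; `NULL`
#'   (default) reports absolute values.
#' @return data frame of summaries, one row per stage (x label); stages
#'   with no breaths yield a row of `NA`s with `n = 0`.
#' @export
aggregate_ventilation <- function(breaths, by_label = FALSE, mass_g = NULL) {
  vars <- c("vt", "inst_rr", "inst_ve", "v_i_max", "mean_insp_flow")
  scale <- rep(1, length(vars))
  if (!is.null(mass_g)) scale <- ifelse(vars == "inst_rr", 1, 100 / mass_g)
  groups <- if (by_label) {
    split(breaths, list(stage = breaths$stage, label = breaths$label),
          drop = FALSE)
  } else {
    split(breaths, factor(breaths$stage,
                          levels = union(STAGES, unique(breaths$stage))))
  }
  rows <- lapply(names(groups), function(g) {
    b <- groups[[g]]
    row <- data.frame(group = g, n = nrow(b))
    for (i in seq_along(vars)) {
      v <- vars[i]
      row[[paste0(v, "_median")]] <- if (nrow(b)) stats::median(b[[v]]) * scale[i] else NA_real_
      row[[paste0(v, "_mean")]] <- if (nrow(b)) mean(b[[v]]) * scale[i] else NA_real_
    }
    row
  })
  out <- do.call(rbind, rows)
  out$flagged_empty <- out$n == 0
  out
}
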
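# Inspiratory flow-limitation classification.
#
# Partial upper-airway obstruction shows up as an early plateau of
# inspiratory airflow at its maximal level while respiratory effort keeps
# rising. Breaths resembling sniffs (unusually short inspiration) are set
# aside first so they are never called flow limited. The plateau test is
# operationalized as: (a) the near-maximal flow is reached early in
# inspiration, (b) flow over the middle 50% of inspiration is flat relative
# to the peak, and optionally (c) effort keeps rising across the plateau.

#' Flow-limitation classifier configuration
#'
#' @param sniff_z_threshold breaths with inspiration-time Z score at or
#'   below `-sniff_z_threshold` (i.e. unusually short) are flagged sniffs.
#'   The short-duration side is intended; both threshold and side are
#'   configurable via `sniff_side`.
#' @param plateau_flatness_tau maximal relative flow variation
#'   `(max - min) / v_i_max` over the middle 50% of inspiration for a
#'   plateau. The default 0.10 rejects a pure half-sine, whose mid-span
#'   variation is `1 - sin(pi/4) ~ 0.29`.
#' @param early_peak_fraction near-peak flow must first be attained at or
#'   before this fraction of inspiration.
#' @param require_effort_rise demand rising effort across the plateau when
#'   an effort channel is available.
#' @param sniff_side `"short"` flags low-Z breaths (default); `"abs"` flags
#'   `|Z| >= threshold`.
#' @return an object of class `wbp_flowlimit_config`.
#' @export
flow_limit_config <- function(sniff_z_threshold = 1.75,
                              plateau_flatness_tau = 0.10,
                              early_peak_fraction = 0.5,
                              require_effort_rise = FALSE,
                              sniff_side = c("short", "abs")) {
  stopifnot(sniff_z_threshold > 0, plateau_flatness_tau > 0,
            early_peak_fraction > 0, early_peak_fraction < 1)
  structure(list(sniff_z_threshold = sniff_z_threshold,
                 plateau_flatness_tau = plateau_flatness_tau,
                 early_peak_fraction = early_peak_fraction,
                 require_effort_rise = require_effort_rise,
                 sniff_side = match.arg(sniff_side)),
            class = "wbp_flowlimit_config")
}

#' Flag sniff breaths by short inspiration time
#'
#' Z scores of inspiration time are computed against the robust center and
#' spread (median and MAD) of the breaths in the scoring context, which
#' should be one analysis window. A degenerate spread (all Ti identical)
#' yields no sniffs; fewer than 10 breaths yields no sniffs with a warning
#' (the Z score needs a distribution).
#'
#' @param breaths output of [breath_features()] for one scoring context.
#' @param cfg a [flow_limit_config()].
#' @return logical vector of sniff flags, one per breath.
#' @export
sniff_filter <- function(breaths, cfg = flow_limit_config()) {
  n <- nrow(breaths)
  if (n < 10) {
    warning("fewer than 10 breaths in scoring context; no sniff flags")
    return(rep(FALSE, n))
  }
  ti <- breaths$ti
  ctr <- stats::median(ti)
  spread <- stats::mad(ti)
  if (spread < 1e-12) return(rep(FALSE, n))
  z <- (ti - ctr) / spread
  if (cfg$sniff_side == "short") {
    z <= -cfg$sniff_z_threshold
  } else {
    abs(z) >= cfg$sniff_z_threshold
  }
}

#' Mid-inspiratory plateau test for one breath
#'
#' @param flow_insp numeric vector: flow over inspiration (first to last
#'   inspiratory sample), mL/s.
#' @param cfg a [flow_limit_config()].
#' @param effort_insp optional effort over the same samples (a.u.).
#' @return list: `is_flow_limited`, `flatness` (relative variation over the
#'   middle 50%), `t_peak_frac` (fraction of Ti at which near-peak flow is
#'   first attained), `degenerate`.
#' @export
detect_plateau <- function(flow_insp, cfg = flow_limit_config(),
                           effort_insp = NULL) {
  m <- length(flow_insp)
  if (m < 4) stop("inspiration must span >= 4 samples")
  # running-mean denoise over ~Ti/10 before shape testing; per-sample noise
  # would otherwise dominate the (max - min) flatness statistic
  w <- max(1L, round(m / 10))
  if (w > 1) {
    padded <- c(rep(flow_insp[1], w), flow_insp, rep(flow_insp[m], w))
    sm <- stats::filter(padded, rep(1 / w, w), sides = 2)
    flow_insp <- as.numeric(sm[(w + 1):(w + m)])
  }
  vmax <- max(flow_insp)
  vt_proxy <- sum(flow_insp)
  if (vmax <= 0 || vt_proxy <= 0) {
    return(list(is_flow_limited = FALSE, flatness = NA_real_,
                t_peak_frac = NA_real_, degenerate = TRUE))
  }
  tau <- cfg$plateau_flatness_tau
  # first attainment of near-peak flow (within the flatness tolerance)
  t_peak_frac <- (which(flow_insp >= (1 - tau) * vmax)[1] - 1) / (m - 1)
  mid <- flow_insp[max(1, ceiling(0.25 * m)):floor(0.75 * m)]
  # trimmed range (5th-95th percentile) rather than max - min: robust to
  # residual noise tails and to smoothing blur at the plateau onset
  flatness <- diff(stats::quantile(mid, c(0.05, 0.95), names = FALSE)) / vmax
  ok <- t_peak_frac <= cfg$early_peak_fraction && flatness <= tau
  if (ok && cfg$require_effort_rise && !is.null(effort_insp)) {
    i0 <- max(1, ceiling(0.25 * m)); i1 <- floor(0.75 * m)
    ok <- effort_insp[i1] > effort_insp[i0]
  }
  list(is_flow_limited = ok, flatness = flatness,
       t_peak_frac = t_peak_frac, degenerate = FALSE)
}

#' Classify breaths as sniff / flow-limited / normal
#'
#' Sniffs are flagged first (per scoring window when a `window` column is
#' present, else over the full breath set) and excluded from plateau
#' testing. Every breath receives exactly one label.
#'
#' @param flow a `wbp_channel` or numeric flow vector the breaths index into.
#' @param breaths output of [breath_features()] (optionally windowed via
#'   [breaths_in_windows()]).
#' @param cfg a [flow_limit_config()].
#' @param effort optional effort channel / vector aligned with `flow`.
#' @param sample_rate Hz for bare vectors.
#' @return `breaths` with `label` filled in plus `flatness` and
#'   `t_peak_frac` columns; attribute `"fl_fraction"` holds the per-stage
#'   flow-limited fraction among non-sniff breaths.
#' @export
classify_breaths <- function(flow, breaths, cfg = flow_limit_config(),
                             effort = NULL, sample_rate = NULL) {
  if (inherits(flow, "wbp_channel")) {
    sample_rate <- flow$sample_rate
    flow <- flow$samples
  }
  if (inherits(effort, "wbp_channel")) effort <- effort$samples
  n <- nrow(breaths)
  if (n == 0) return(breaths)
  grp <- if ("window" %in% names(breaths)) breaths$window else rep(1L, n)
  sniff <- rep(FALSE, n)
  for (g in unique(grp)) {
    sel <- grp == g
    sniff[sel] <- withCallingHandlers(
      sniff_filter(breaths[sel, , drop = FALSE], cfg),
      warning = function(w) invokeRestart("muffleWarning")
    )
  }
  breaths$label <- ifelse(sniff, "sniff", "normal")
  breaths$flatness <- NA_real_
  breaths$t_peak_frac <- NA_real_
  for (k in which(!sniff)) {
    i0 <- breaths$i_start[k]; ie <- breaths$i_insp_end[k]
    if (ie - i0 + 1 < 4) next
    eff <- if (!is.null(effort)) effort[i0:ie] else NULL
    res <- detect_plateau(flow[i0:ie], cfg, eff)
    breaths$flatness[k] <- res$flatness
    breaths$t_peak_frac[k] <- res$t_peak_frac
    if (isTRUE(res$is_flow_limited)) breaths$label[k] <- "flow_limited"
  }
  nonsniff <- breaths[breaths$label != "sniff", , drop = FALSE]
  fl_frac <- vapply(split(nonsniff, nonsniff$stage), function(b) {
    mean(b$label == "flow_limited")
  }, 0)
  attr(breaths, "fl_fraction") <- fl_frac
  breaths
}
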
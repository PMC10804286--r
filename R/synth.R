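# Synthetic multichannel recording generator.
#
# Produces plethysmography-style recordings with full ground truth: a
# semi-Markov hypnogram, a breath train (half-sine inspiration,
# exponential-decay expiration) with sniffs and REM-predominant
# flow-limited breaths, injected obstructive apneas with preserved effort,
# an SpO2 channel with lagged first-order desaturations, stage-signature
# EEG/EMG, CO2-challenge scaling of minute ventilation, and CLAMS-style
# gas/activity traces on an 11-min grid. One global random stream is
# seeded once per recording; sub-generators draw in the fixed order
# hypnogram -> breaths -> apneas -> SpO2 -> EEG/EMG -> metabolic.

#' Synthetic-recording configuration
#'
#' Defaults describe a resting obese mouse: 150 breaths/min with 10% cycle
#' variability, 0.15 mL tidal volume, inspiration 40% of the cycle;
#' occasional sniffs; flow limitation in 30% of REM breaths at severity
#' 0.9 with effort gain 1.5; obstructive apneas predominantly in REM
#' (20/h) with smaller NREM rates; SpO2 baseline 96% with ~6% lagged
#' desaturations after each apnea; wake/NREM/REM bouts of 120/160/60 s;
#' HCVR gain 7.5 mL/min per %CO2; VO2 90 mL/h at RER 0.85 with 2 beam
#' breaks/min; chamber at 29 degC, 90% humidity, body 37 degC, 760 mm Hg.
#'
#' @param seed integer seed for the recording's single random stream.
#' @param duration recording length in seconds (>= 10).
#' @param sample_rate Hz for the signal channels.
#' @param ... named overrides for the nested defaults, e.g.
#'   `breath = list(rate = 120)` (unnamed fields keep their defaults).
#' @return an object of class `wbp_synth_config`.
#' @export
synth_config <- function(seed = 1L, duration = 600, sample_rate = 1000, ...) {
  defaults <- list(
    breath = list(rate = 150, rate_cv = 0.1, tidal_volume = 0.15,
                  ti_fraction = 0.4, amplitude_noise_sd = 0.05),
    sniff = list(prob = 0.02, ti_scale = 0.4),
    flow_limitation = list(prob_rem = 0.3, plateau_severity = 0.9,
                           effort_gain = 1.5),
    apnea = list(rate = c(W = 0, NREM = 2, REM = 20),
                 duration_mean = 1.2, duration_sd = 0.3, duration_min = 0.8),
    spo2 = list(baseline = 96, desat_depth_mean = 6, desat_depth_sd = 0.5,
                desat_lag = 5, desat_tau = 1.5, desat_hold = 8,
                noise_sd = 0.3, extra_desat_rate = 0),
    hypnogram = list(
      bout_mean = c(W = 120, NREM = 160, REM = 60),
      transition = list(W = c(NREM = 1),
                        NREM = c(W = 0.6, REM = 0.4),
                        REM = c(W = 0.8, NREM = 0.2))),
    eeg = list(amp = c(W = 1, NREM = 3, REM = 1),
               emg_rms = c(W = 3, NREM = 1, REM = 0.4),
               band = list(W = c(10, 20), NREM = c(2, 5), REM = c(5, 10)),
               noise_sd = 0.15),
    co2_protocol = NULL,        # list of c(co2_pct, duration_s)
    hcvr_gain = 7.5,            # mL/min per %CO2
    ve_tau = 15,                # s, first-order VE transition
    metabolism = list(vo2 = 90, rer = 0.85, activity_rate = 2,
                      flow_rate = 500, fio2_in = 0.2093, fico2_in = 4e-04,
                      noise_sd = 0),
    environment = list(body_temp = 37, chamber_temp = 29, room_temp = 23,
                       humidity = 0.9, barometric = 760,
                       calibration_volume = 0.05, calibration_deflection = 1,
                       animal_mass = 45)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg <- defaults
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(defaults[[nm]]) && is.list(over[[nm]])) {
      utils::modifyList(defaults[[nm]], over[[nm]])
    } else {
      over[[nm]]
    }
  }
  cfg$seed <- as.integer(seed)
  cfg$duration <- duration
  cfg$sample_rate <- sample_rate
  validate_synth_config(cfg)
  structure(cfg, class = "wbp_synth_config")
}

validate_synth_config <- function(cfg) {
  if (!is.numeric(cfg$duration) || cfg$duration < 10) {
    stop("invalid configuration: duration must be >= 10 s")
  }
  if (cfg$sample_rate <= 0) stop("invalid configuration: sample_rate must be > 0")
  b <- cfg$breath
  if (b$rate <= 0) stop("invalid configuration: breath rate must be > 0")
  probs <- c(cfg$sniff$prob, cfg$flow_limitation$prob_rem)
  if (any(probs < 0 | probs > 1)) stop("invalid configuration: probabilities must lie in [0, 1]")
  fl <- cfg$flow_limitation
  if (fl$plateau_severity < 0 || fl$plateau_severity > 1) {
    stop("invalid configuration: plateau_severity must lie in [0, 1]")
  }
  if (b$ti_fraction <= 0 || b$ti_fraction >= 1) {
    stop("invalid configuration: ti_fraction must lie in (0, 1)")
  }
  if (cfg$metabolism$rer <= 0) stop("invalid configuration: rer must be > 0")
  if (cfg$spo2$baseline <= 80 || cfg$spo2$baseline > 100) {
    stop("invalid configuration: spo2 baseline must lie in (80, 100]")
  }
  if (any(cfg$hypnogram$bout_mean <= 5)) {
    stop("invalid configuration: bout-duration means must exceed 5 s")
  }
  invisible(cfg)
}

#' Generate a semi-Markov hypnogram
#'
#' Bout durations are gamma-distributed (shape 2) around the per-stage
#' means, rounded to whole 5-s epochs with a one-epoch floor; successor
#' stages follow the configured transition weights. By convention REM is
#' entered only from NREM (enforced by the default weights).
#'
#' @param config a [synth_config()].
#' @param seed seed this call; `NULL` (used internally) draws from the
#'   current stream.
#' @return list: `hypnogram` (a [hypnogram()]) and `bouts` data frame.
#' @export
generate_hypnogram <- function(config, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  hcfg <- config$hypnogram
  n_epochs <- floor(config$duration / 5)
  stages <- character(0)
  cur <- "W"
  while (length(stages) < n_epochs) {
    mean_s <- hcfg$bout_mean[[cur]]
    dur_s <- stats::rgamma(1, shape = 2, scale = mean_s / 2)
    n_ep <- max(1L, round(dur_s / 5))
    stages <- c(stages, rep(cur, n_ep))
    w <- hcfg$transition[[cur]]
    cur <- sample(names(w), 1, prob = w)
  }
  hyp <- hypnogram(stages[seq_len(n_epochs)], source = "external")
  r <- rle(hyp$stages)
  bouts <- data.frame(stage = r$values,
                      t_start = (cumsum(r$lengths) - r$lengths) * 5,
                      duration = r$lengths * 5)
  list(hypnogram = hyp, bouts = bouts)
}

# per-breath minute-ventilation multiplier from the CO2 protocol:
# piecewise targets 1 + gain * level / VE_base approached first-order with
# time constant ve_tau at each gas switch
co2_multiplier <- function(config) {
  proto <- config$co2_protocol
  ve_base <- config$breath$tidal_volume * config$breath$rate
  if (is.null(proto)) return(function(t) rep(1, length(t)))
  tau <- config$ve_tau
  t_sw <- cumsum(c(0, vapply(proto, `[`, 0, 2)))
  targets <- 1 + config$hcvr_gain * vapply(proto, `[`, 0, 1) / ve_base
  m_at_sw <- numeric(length(proto))
  m_at_sw[1] <- targets[1]
  if (length(proto) > 1) {
    for (k in 2:length(proto)) {
      m_at_sw[k] <- targets[k - 1] +
        (m_at_sw[k - 1] - targets[k - 1]) * exp(-(t_sw[k] - t_sw[k - 1]) / tau)
    }
  }
  function(t) {
    k <- pmin(findInterval(t, t_sw), length(proto))
    k[k < 1] <- 1
    targets[k] + (m_at_sw[k] - targets[k]) * exp(-(t - t_sw[k]) / tau)
  }
}

#' Generate the breath train
#'
#' Builds flow (mL/s), volume (mL, running integral of flow) and effort
#' (a.u.) channels breath by breath: half-sine inspiration scaled to the
#' target tidal volume, exponential-decay expiration returning the volume
#' to baseline, sniffs with inspiration time scaled by `ti_scale`, and
#' flow-limited breaths (REM only by default) with inspiratory flow
#' hard-clipped at `A * (1 - 0.35 * plateau_severity)` -- at severity 1 the
#' whole middle 50% of inspiration sits on the plateau -- without volume
#' renormalization (obstructed breaths lose volume). The effort channel is
#' the unclipped inspiratory drive, rising monotonically through
#' inspiration and amplified by `effort_gain` on flow-limited breaths.
#'
#' @param config a [synth_config()].
#' @param hyp a [hypnogram()] assigning stages.
#' @param seed seed this call; `NULL` draws from the current stream.
#' @return list: `flow`, `volume`, `effort` (numeric channels at
#'   `config$sample_rate`) and `breath_table` (truth: `index`, `t_start`,
#'   `t_insp_end`, `t_end`, `stage`, `label`, `vt_true`, `amp_true`).
#' @export
generate_breath_train <- function(config, hyp, seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  validate_synth_config(config)
  fs <- config$sample_rate
  b <- config$breath
  fl <- config$flow_limitation
  n <- round(config$duration * fs)
  flow <- numeric(n)
  effort <- numeric(n)
  period <- 60 / b$rate
  mult <- co2_multiplier(config)
  clip_frac <- 1 - 0.35 * fl$plateau_severity
  rows <- vector("list", ceiling(config$duration / period * 2))
  nb <- 0L
  cursor <- 1L
  while (cursor < n) {
    t0 <- (cursor - 1) / fs
    # bounded (uniform) cycle-length jitter with SD rate_cv * period;
    # keeps cycle durations physiological and the breath count stable
    ttot <- period * (1 + b$rate_cv * sqrt(3) * stats::runif(1, -1, 1))
    stage <- stage_at(hyp, t0)
    if (stage == "unknown") stage <- "W"
    is_sniff <- stats::runif(1) < config$sniff$prob
    is_fl <- !is_sniff && stage == "REM" &&
      stats::runif(1) < fl$prob_rem && fl$plateau_severity > 0
    ti <- b$ti_fraction * ttot * if (is_sniff) config$sniff$ti_scale else 1
    te <- ttot - ti
    n_ti <- max(4L, round(ti * fs))
    n_te <- max(4L, round(te * fs))
    if (cursor + n_ti + n_te - 1 > n) break
    vt_target <- b$tidal_volume * mult(t0)
    amp <- pi * vt_target / (2 * (n_ti / fs))
    insp <- amp * sin(pi * (0:(n_ti - 1)) / n_ti)
    if (is_fl) insp <- pmin(insp, amp * clip_frac)
    vt_actual <- sum(insp) / fs
    tau_n <- n_te / 3
    decay <- exp(-(0:(n_te - 1)) / tau_n)
    expf <- -decay * (vt_actual * fs / sum(decay))
    egain <- if (is_fl) fl$effort_gain else 1
    eff_i <- amp * egain * (1 - cos(pi * (0:(n_ti - 1)) / n_ti)) / 2
    eff_e <- amp * egain * exp(-(0:(n_te - 1)) / (n_te / 4))
    sl <- cursor:(cursor + n_ti + n_te - 1)
    flow[sl] <- c(insp, expf)
    effort[sl] <- c(eff_i, eff_e)
    nb <- nb + 1L
    rows[[nb]] <- data.frame(
      index = nb, t_start = t0, t_insp_end = t0 + n_ti / fs,
      t_end = t0 + (n_ti + n_te) / fs, stage = stage,
      label = if (is_sniff) "sniff" else if (is_fl) "flow_limited" else "normal",
      vt_true = vt_actual, amp_true = amp
    )
    cursor <- cursor + n_ti + n_te
  }
  if (b$amplitude_noise_sd > 0) {
    amp_nom <- pi * b$tidal_volume / (2 * b$ti_fraction * period)
    flow <- flow + stats::rnorm(n, sd = b$amplitude_noise_sd * amp_nom)
  }
  list(flow = flow, volume = cumsum(flow) / fs, effort = effort,
       breath_table = do.call(rbind, rows[seq_len(nb)]))
}

#' Inject obstructive apneas
#'
#' Draws a Poisson number of events per stage (`rate` events/h of stage
#' time), places each on a uniformly chosen run of whole breaths of that
#' stage so the event spans at least the drawn duration, suppresses flow
#' to 2% of its amplitude over the event while leaving effort untouched,
#' and removes the suppressed breaths from the truth table. Overlapping or
#' adjacent (< 2 breaths apart) placements are re-drawn; after `max_tries`
#' failures an error is raised.
#'
#' @param flow,effort channels from [generate_breath_train()].
#' @param breath_table truth table from [generate_breath_train()].
#' @param hyp the [hypnogram()] used for stage time.
#' @param config a [synth_config()].
#' @param seed seed this call; `NULL` draws from the current stream.
#' @param max_tries placement retries per event.
#' @return list: `flow`, `effort`, `breath_table` (suppressed breaths
#'   removed), `apnea_events` (`t_start`, `duration`, `stage`).
#' @export
inject_apneas <- function(flow, effort, breath_table, hyp, config,
                          seed = NULL, max_tries = 200) {
  if (!is.null(seed)) set.seed(seed)
  fs <- config$sample_rate
  acfg <- config$apnea
  bt <- breath_table
  events <- list()
  occupied <- rep(FALSE, nrow(bt))
  for (stage in STAGES) {
    rate <- acfg$rate[[stage]]
    if (is.null(rate) || rate == 0) next
    hours <- sum(hyp$stages == stage) * hyp$epoch_len / 3600
    n_ev <- stats::rpois(1, rate * hours)
    for (e in seq_len(n_ev)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        dur <- max(acfg$duration_min,
                   stats::rnorm(1, acfg$duration_mean, acfg$duration_sd))
        elig <- which(bt$stage == stage & !occupied & bt$index > 10)
        if (length(elig) == 0) break
        j <- elig[sample.int(length(elig), 1)]
        jj <- j
        while (jj < nrow(bt) &&
               bt$t_end[jj] - bt$t_start[j] < dur) jj <- jj + 1
        if (bt$t_end[jj] - bt$t_start[j] < dur) next
        span <- max(1, j - 2):min(nrow(bt), jj + 2)
        if (any(occupied[span])) next
        occupied[j:jj] <- TRUE
        i0 <- round(bt$t_start[j] * fs) + 1
        i1 <- round(bt$t_end[jj] * fs)
        flow[i0:i1] <- flow[i0:i1] * 0.02
        events[[length(events) + 1]] <- data.frame(
          t_start = bt$t_start[j], duration = bt$t_end[jj] - bt$t_start[j],
          stage = stage
        )
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place non-overlapping apnea events after ",
             max_tries, " retries")
      }
    }
  }
  apnea_events <- if (length(events)) do.call(rbind, events) else
    data.frame(t_start = numeric(), duration = numeric(), stage = character())
  list(flow = flow, effort = effort,
       breath_table = bt[!occupied, , drop = FALSE],
       apnea_events = apnea_events)
}

#' Generate the SpO2 channel
#'
#' Baseline plus bounded smoothed noise; each apnea (after `desat_lag`)
#' and each independently injected desaturation drives a first-order dip
#' of the configured depth held for `desat_hold` seconds beyond the event.
#'
#' @param apnea_events truth events from [inject_apneas()].
#' @param config a [synth_config()].
#' @param n_samples,hyp channel length and hypnogram (for extra sleep
#'   desaturations at `extra_desat_rate`).
#' @param seed seed this call; `NULL` draws from the current stream.
#' @return list: `spo2` (numeric, %) and `desat_events` truth
#'   (`t_start`, `depth`).
#' @export
generate_spo2 <- function(apnea_events, config, n_samples, hyp = NULL,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  scfg <- config$spo2
  fs <- config$sample_rate
  n <- n_samples
  drive <- numeric(n)
  desats <- list()
  add_dip <- function(t0, dur, depth) {
    i0 <- max(1, round((t0 + scfg$desat_lag) * fs))
    i1 <- min(n, round((t0 + scfg$desat_lag + dur + scfg$desat_hold) * fs))
    if (i0 < i1) drive[i0:i1] <<- pmax(drive[i0:i1], depth)
    data.frame(t_start = t0 + scfg$desat_lag, depth = depth)
  }
  if (nrow(apnea_events)) {
    for (k in seq_len(nrow(apnea_events))) {
      depth <- max(0.5, stats::rnorm(1, scfg$desat_depth_mean,
                                     scfg$desat_depth_sd))
      desats[[length(desats) + 1]] <-
        add_dip(apnea_events$t_start[k], apnea_events$duration[k], depth)
    }
  }
  if (scfg$extra_desat_rate > 0 && !is.null(hyp)) {
    sleep_ep <- which(hyp$stages %in% c("NREM", "REM"))
    sleep_h <- length(sleep_ep) * hyp$epoch_len / 3600
    n_extra <- stats::rpois(1, scfg$extra_desat_rate * sleep_h)
    for (k in seq_len(n_extra)) {
      ep <- sleep_ep[sample.int(length(sleep_ep), 1)]
      t0 <- (ep - 1) * hyp$epoch_len + stats::runif(1, 0, hyp$epoch_len)
      depth <- max(0.5, stats::rnorm(1, scfg$desat_depth_mean,
                                     scfg$desat_depth_sd))
      desats[[length(desats) + 1]] <- add_dip(t0, 0, depth)
    }
  }
  alpha <- 1 / (scfg$desat_tau * fs)
  target <- scfg$baseline - drive
  spo2 <- as.numeric(stats::filter(alpha * target, 1 - alpha,
                                   method = "recursive",
                                   init = scfg$baseline))
  if (scfg$noise_sd > 0) {
    gain <- sqrt(alpha / (2 - alpha))
    raw <- stats::rnorm(n, sd = scfg$noise_sd / gain)
    noise <- as.numeric(stats::filter(alpha * raw, 1 - alpha,
                                      method = "recursive", init = 0))
    noise <- pmin(pmax(noise, -3 * scfg$noise_sd), 3 * scfg$noise_sd)
    spo2 <- spo2 + noise
  }
  spo2 <- pmin(pmax(spo2, 1e-6), 100)
  desat_events <- if (length(desats)) do.call(rbind, desats) else
    data.frame(t_start = numeric(), depth = numeric())
  list(spo2 = spo2, desat_events = desat_events)
}

#' Generate stage-signature EEG and EMG channels
#'
#' Per bout, EEG is band-limited Gaussian noise in the stage's defining
#' band (wake ~10-20 Hz low amplitude, NREM ~2-5 Hz high amplitude, REM
#' ~5-10 Hz low amplitude) rescaled to the stage RMS, plus broadband
#' background; EMG is >30 Hz noise with RMS ordered wake > NREM >= REM.
#'
#' @param hyp a [hypnogram()].
#' @param config a [synth_config()].
#' @param seed seed this call; `NULL` draws from the current stream.
#' @return list of numeric channels `eeg`, `emg` at `config$sample_rate`.
#' @export
generate_eeg_emg <- function(hyp, config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ecfg <- config$eeg
  fs <- config$sample_rate
  bad <- setdiff(unique(hyp$stages), names(ecfg$band))
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  r <- rle(hyp$stages)
  eeg <- numeric(0)
  emg <- numeric(0)
  hp <- signal::butter(4, min(30 / (fs / 2), 0.99), type = "high")
  for (k in seq_along(r$values)) {
    stage <- r$values[k]
    n_s <- r$lengths[k] * hyp$epoch_len * fs
    band <- ecfg$band[[stage]]
    bp <- signal::butter(2, band / (fs / 2), type = "pass")
    x <- as.numeric(signal::filtfilt(bp, stats::rnorm(n_s)))
    x <- x / sqrt(mean(x^2)) * ecfg$amp[[stage]]
    x <- x + stats::rnorm(n_s, sd = ecfg$noise_sd)
    m <- as.numeric(signal::filtfilt(hp, stats::rnorm(n_s)))
    m <- m / sqrt(mean(m^2)) * ecfg$emg_rms[[stage]]
    eeg <- c(eeg, x)
    emg <- c(emg, m)
  }
  list(eeg = eeg, emg = emg)
}

#' Generate CLAMS-style metabolic traces
#'
#' Inverts the Haldane-corrected open-circuit equations so that the
#' emitted inflow/outflow gas fractions reproduce the configured VO2 and
#' RER exactly (up to the configured per-bin noise); activity is a Poisson
#' impulse stream at `activity_rate` beam breaks/min on a 1 Hz channel.
#' Gas fractions are sampled once per 11-min bin.
#'
#' @param config a [synth_config()].
#' @param duration seconds; must cover at least one 660-s bin.
#' @param seed seed this call; `NULL` draws from the current stream.
#' @return list: `times` (bin starts, s), `fio2_in`, `fio2_out`,
#'   `fico2_in`, `fico2_out` (fractions per bin), `activity` (1 Hz counts),
#'   `vo2_true` (mL/h), `rer_true`.
#' @export
generate_metabolic_traces <- function(config, duration = config$duration,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- config$metabolism
  stopifnot(m$vo2 > 0)
  if (m$rer <= 0.5 || m$rer >= 1.5) {
    warning("configured RER ", m$rer, " outside the physiological (0.5, 1.5)")
  }
  nbins <- floor(duration / 660)
  if (nbins < 1) stop("duration must cover at least one 660-s bin")
  noise <- function() 1 + m$noise_sd * stats::rnorm(nbins)
  vo2 <- m$vo2 / 60 * noise()    # mL/min per bin
  vco2 <- m$rer * m$vo2 / 60 * noise()
  a <- vo2 / m$flow_rate
  bq <- vco2 / m$flow_rate
  h <- 1 - a + bq
  fio2_out <- (m$fio2_in - a) / h
  fico2_out <- (bq + m$fico2_in) / h
  n_sec <- floor(duration)
  activity <- stats::rpois(n_sec, m$activity_rate / 60)
  list(times = (seq_len(nbins) - 1) * 660,
       fio2_in = rep(m$fio2_in, nbins), fio2_out = fio2_out,
       fico2_in = rep(m$fico2_in, nbins), fico2_out = fico2_out,
       activity = activity, vo2_true = m$vo2, rer_true = m$rer)
}

#' Generate a full synthetic recording with ground truth
#'
#' Composes the sub-generators in a fixed order on a single random stream
#' seeded from `config$seed`, so identical configurations give
#' bit-identical recordings. The chamber-pressure channel is derived from
#' the volume channel by inverting the Drorbaugh-Fenn conversion for the
#' configured environment, so the calibration module round-trips exactly.
#' Metabolic channels are included when the recording covers at least one
#' 11-min bin.
#'
#' @param config a [synth_config()].
#' @return list: `recording` (a [wbp_recording()]) and `truth` (list with
#'   `breath_table`, `apnea_events`, `desat_events`, `hypnogram_true`,
#'   `hcvr_gain_true`, `vo2_true`, `rer_true`).
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "wbp_synth_config"))
  if (!is.null(config$co2_protocol)) {
    config$duration <- sum(vapply(config$co2_protocol, `[`, 0, 2))
  }
  set.seed(config$seed)
  fs <- config$sample_rate
  hypg <- generate_hypnogram(config, seed = NULL)
  hyp <- hypg$hypnogram
  bt <- generate_breath_train(config, hyp, seed = NULL)
  ap <- inject_apneas(bt$flow, bt$effort, bt$breath_table, hyp, config,
                      seed = NULL)
  n <- length(ap$flow)
  sp <- generate_spo2(ap$apnea_events, config, n, hyp = hyp, seed = NULL)
  ee <- generate_eeg_emg(hyp, config, seed = NULL)
  env <- config$environment
  ctx <- calibration_context(env$body_temp, env$chamber_temp, env$room_temp,
                             env$humidity, env$barometric,
                             env$calibration_volume, env$calibration_deflection)
  f <- drorbaugh_fenn_factor(ctx)
  volume <- cumsum(ap$flow) / fs
  pressure <- volume * ctx$p_k / (ctx$v_k * f)
  channels <- list(
    chamber_pressure = ts_channel(pressure, "chamber_pressure", "a.u.", fs),
    flow = ts_channel(ap$flow, "flow", "mL/s", fs),
    volume = ts_channel(volume, "volume", "mL", fs),
    effort = ts_channel(ap$effort, "effort", "a.u.", fs),
    eeg = ts_channel(ee$eeg, "eeg", "a.u.", fs),
    emg = ts_channel(ee$emg, "emg", "a.u.", fs),
    spo2 = ts_channel(sp$spo2, "spo2", "%", fs)
  )
  mt <- NULL
  if (config$duration >= 660) {
    mt <- generate_metabolic_traces(config, seed = NULL)
    channels$fio2_in <- ts_channel(mt$fio2_in, "fio2_in", "fraction", 1 / 660)
    channels$fio2_out <- ts_channel(mt$fio2_out, "fio2_out", "fraction", 1 / 660)
    channels$fico2_in <- ts_channel(mt$fico2_in, "fico2_in", "fraction", 1 / 660)
    channels$fico2_out <- ts_channel(mt$fico2_out, "fico2_out", "fraction", 1 / 660)
    channels$activity <- ts_channel(mt$activity, "activity", "count", 1)
  }
  if (!is.null(config$co2_protocol)) {
    lv <- unlist(lapply(config$co2_protocol, function(s) rep(s[1], ceiling(s[2]))))
    channels$fico2_inspired <-
      ts_channel(lv[seq_len(floor(config$duration))] / 100,
                 "fico2_inspired", "fraction", 1)
  }
  meta <- c(env, list(flow_rate = config$metabolism$flow_rate,
                      start_time = "2026-01-01T10:00:00",
                      co2_protocol = config$co2_protocol))
  rec <- wbp_recording(channels, meta)
  truth <- list(
    breath_table = ap$breath_table,
    apnea_events = ap$apnea_events,
    desat_events = sp$desat_events,
    hypnogram_true = hyp,
    hcvr_gain_true = config$hcvr_gain,
    vo2_true = if (is.null(mt)) NA_real_ else mt$vo2_true,
    rer_true = if (is.null(mt)) NA_real_ else mt$rer_true
  )
  list(recording = rec, truth = truth)
}
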
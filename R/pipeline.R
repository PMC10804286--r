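# End-to-end orchestration: synthetic (or on-disk) recording -> calibration
# -> breath segmentation/features -> staging -> flow-limitation labels ->
# event scoring -> HCVR -> metabolic summary, with all derived tables
# written as delimited text plus a JSON run manifest carrying the config
# hash. Deterministic given the config (including its seed): outputs carry
# no timestamps, so a rerun is byte-identical.

#' Assemble a pipeline configuration
#'
#' @param synth a [synth_config()] for generated input, or `NULL` when
#'   reading a recording from disk.
#' @param input_path native-container directory (used when `synth` is NULL).
#' @param flow_limit a [flow_limit_config()].
#' @param use_true_hypnogram use the generator's hypnogram instead of
#'   scoring EEG/EMG (only meaningful with synthetic input).
#' @param from_pressure start from the chamber-pressure channel via the
#'   Drorbaugh-Fenn conversion instead of the emitted flow channel.
#' @param score_events,score_odi,do_hcvr,do_metabolism stage toggles;
#'   `do_hcvr`/`do_metabolism` default to "when the input supports it".
#' @return an object of class `wbp_pipeline_config`.
#' @export
pipeline_config <- function(synth = synth_config(), input_path = NULL,
                            flow_limit = flow_limit_config(),
                            use_true_hypnogram = FALSE,
                            from_pressure = FALSE,
                            score_events = TRUE, score_odi = TRUE,
                            do_hcvr = NA, do_metabolism = NA) {
  structure(list(synth = synth, input_path = input_path,
                 flow_limit = flow_limit,
                 use_true_hypnogram = use_true_hypnogram,
                 from_pressure = from_pressure,
                 score_events = score_events, score_odi = score_odi,
                 do_hcvr = do_hcvr, do_metabolism = do_metabolism),
            class = "wbp_pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Run the full analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for the result tables (`NULL` skips
#'   writing). On a stage failure the tables produced so far are kept and
#'   the error is re-raised with stage context.
#' @return list: `breaths` (labeled breath table), `hypnogram`, `windows`,
#'   `events`, `odi`, `apnea_index_rem`, `ventilation` (per-stage summary),
#'   `hcvr`, `metabolism`, `truth` (synthetic input only), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "wbp_pipeline_config"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  result <- list(manifest = list(package_version = as.character(
    utils::packageVersion("wbpsleep")), config_hash = config_hash(config)))
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  stage <- "input"
  tryCatch({
    truth <- NULL
    if (!is.null(config$synth)) {
      gen <- generate_recording(config$synth)
      rec <- gen$recording
      truth <- gen$truth
    } else {
      if (is.null(config$input_path)) stop("neither synth config nor input_path given")
      rec <- read_recording(config$input_path)
    }
    result$truth <- truth

    stage <- "calibration"
    if (config$from_pressure) {
      env <- rec$meta
      for (f in c("body_temp", "chamber_temp", "humidity", "barometric",
                  "calibration_volume", "calibration_deflection")) {
        if (is.null(env[[f]])) stop("conversion requires meta field '", f, "'")
      }
      ctx <- calibration_context(env$body_temp, env$chamber_temp,
                                 env$room_temp %||% env$chamber_temp,
                                 env$humidity, env$barometric,
                                 env$calibration_volume,
                                 env$calibration_deflection)
      vol <- pressure_to_volume(get_channel(rec, "chamber_pressure"), ctx)
      flow_ch <- differentiate_volume(vol)
    } else {
      flow_ch <- get_channel(rec, "flow")
    }

    stage <- "staging"
    hyp <- if (config$use_true_hypnogram && !is.null(truth)) {
      truth$hypnogram_true
    } else if (!is.null(rec$channels$eeg)) {
      score_sleep(rec)
    } else if (!is.null(truth)) {
      truth$hypnogram_true
    } else {
      stop("no EEG/EMG channels and no external hypnogram")
    }
    result$hypnogram <- hyp
    emit("hypnogram.csv", function(p) write_hypnogram(hyp, p))

    stage <- "breaths"
    bounds <- segment_breaths(flow_ch)
    breaths <- breath_features(flow_ch, bounds, hyp = hyp)

    stage <- "classify"
    windows <- select_analysis_windows(hyp)
    result$windows <- windows
    wb <- breaths_in_windows(breaths, windows)
    if (!is.null(wb) && nrow(wb)) {
      wb <- classify_breaths(flow_ch, wb, config$flow_limit,
                             effort = rec$channels$effort)
      breaths$label[match(wb$index, breaths$index)] <- wb$label
    }
    result$breaths <- breaths
    result$fl_fraction <- if (!is.null(wb)) attr(wb, "fl_fraction") else NULL
    result$ventilation <- aggregate_ventilation(
      if (!is.null(wb) && nrow(wb)) wb else breaths)
    emit("breath_table.csv", function(p) write_breath_table(breaths, p))

    stage <- "events"
    if (config$score_events) {
      events <- detect_apneas(flow_ch, breaths, hyp)
      if (config$score_odi) {
        spo2 <- get_channel(rec, "spo2", required = FALSE)
        if (is.null(spo2)) stop("ODI requested but recording has no 'spo2' channel")
        des <- detect_desaturations(spo2, hyp, breaths)
        events <- rbind(events, des$events)
        result$odi <- des$odi
      }
      result$events <- events
      result$apnea_index_rem <- if (any(hyp$stages == "REM")) {
        apnea_index(events, hyp, "REM")
      } else NA_real_
      emit("events.csv", function(p) write_events(events, p))
    }

    stage <- "hcvr"
    proto <- rec$meta$co2_protocol
    do_hcvr <- if (is.na(config$do_hcvr)) !is.null(proto) else config$do_hcvr
    if (do_hcvr) {
      if (is.null(proto)) stop("HCVR requested but no CO2 protocol in metadata")
      result$hcvr <- hcvr_from_protocol(breaths, proto)
    }

    stage <- "metabolism"
    do_met <- if (is.na(config$do_metabolism)) {
      !is.null(rec$channels$fio2_out)
    } else config$do_metabolism
    if (do_met) {
      result$metabolism <- metabolic_summary(rec)
    }

    stage <- "summary"
    summ <- list(
      n_breaths = nrow(breaths),
      ventilation = result$ventilation,
      fl_fraction = as.list(result$fl_fraction),
      apnea_index_rem = result$apnea_index_rem,
      odi = result$odi,
      hcvr_slope = if (!is.null(result$hcvr)) result$hcvr$slope else NULL,
      vo2 = if (!is.null(result$metabolism)) result$metabolism$vo2 else NULL,
      rer = if (!is.null(result$metabolism)) result$metabolism$rer else NULL,
      manifest = result$manifest
    )
    emit("summary.json", function(p) {
      jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
    })
    emit("manifest.json", function(p) {
      jsonlite::write_json(result$manifest, p, auto_unbox = TRUE, pretty = TRUE)
    })
    result
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
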
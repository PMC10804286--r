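#!/usr/bin/env Rscript
# Breath-by-breath analysis of the phenotyping night: chamber pressure ->
# tidal volume (Drorbaugh-Fenn) -> airflow -> segmented breaths with
# timing, volume and inspiratory flow landmarks. Writes the breath table
# and per-stage ventilation summaries under results/.

suppressPackageStartupMessages(library(wbpsleep))
dir.create("results", showWarnings = FALSE)

rec <- read_recording("results/data/night")
hyp <- read_hypnogram("results/data/night_truth_hypnogram.csv")

env <- rec$meta
ctx <- calibration_context(env$body_temp, env$chamber_temp, env$room_temp,
                           env$humidity, env$barometric,
                           env$calibration_volume, env$calibration_deflection)
message(sprintf("Drorbaugh-Fenn conversion factor: %.2f", drorbaugh_fenn_factor(ctx)))

vol <- pressure_to_volume(get_channel(rec, "chamber_pressure"), ctx)
flow <- differentiate_volume(vol)
bounds <- segment_breaths(flow)
breaths <- breath_features(flow, bounds, hyp = hyp)
message(sprintf("Segmented %d breaths (median RR %.0f /min, median VT %.3f mL)",
                nrow(breaths), median(breaths$inst_rr), median(breaths$vt)))

windows <- select_analysis_windows(hyp)
wb <- breaths_in_windows(breaths, windows)
message(sprintf("Analysis windows: %d REM, %d NREM 20-s stretches",
                sum(windows$stage == "REM"), sum(windows$stage == "NREM")))

write_breath_table(breaths, "results/breath_table.csv")
data.table::fwrite(windows, "results/analysis_windows.csv")
data.table::fwrite(aggregate_ventilation(wb), "results/ventilation_by_stage.csv")
message("Wrote results/breath_table.csv, analysis_windows.csv, ventilation_by_stage.csv")
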
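#!/usr/bin/env Rscript
# Flow-limitation classification and respiratory event scoring of the
# phenotyping night: sniff/flow-limited/normal labels inside the analysis
# windows, apneas (>= 90% airflow reduction, >= 2 cycles or >= 0.7 s) with
# per-stage indices, and the oxygen desaturation index.

suppressPackageStartupMessages(library(wbpsleep))

rec <- read_recording("results/data/night")
hyp <- read_hypnogram("results/data/night_truth_hypnogram.csv")
flow <- get_channel(rec, "flow")
breaths <- breath_features(flow, segment_breaths(flow), hyp = hyp)
windows <- select_analysis_windows(hyp)
wb <- breaths_in_windows(breaths, windows)

wb <- classify_breaths(flow, wb, effort = get_channel(rec, "effort"))
frac <- attr(wb, "fl_fraction")
message(sprintf("Flow-limited fraction of non-sniff breaths: REM %.2f, NREM %.2f",
                frac[["REM"]], if ("NREM" %in% names(frac)) frac[["NREM"]] else 0))
data.table::fwrite(wb, "results/breaths_labeled.csv")
data.table::fwrite(aggregate_ventilation(wb, by_label = TRUE),
                   "results/ventilation_by_stage_label.csv")

events <- detect_apneas(flow, breaths, hyp)
rem_idx <- apnea_index(events, hyp, "REM")
nrem_idx <- apnea_index(events, hyp, "NREM")
message(sprintf("Apnea index: REM %.1f/h, NREM %.1f/h (%d events)",
                rem_idx, nrem_idx, nrow(events)))

des <- detect_desaturations(get_channel(rec, "spo2"), hyp, breaths)
message(sprintf("ODI: %.1f desaturations (>=4%%) per hour of sleep", des$odi))

write_events(rbind(events, des$events), "results/events.csv")
data.table::fwrite(data.frame(apnea_index_rem = rem_idx,
                              apnea_index_nrem = nrem_idx, odi = des$odi),
                   "results/event_indices.csv")
message("Wrote results/breaths_labeled.csv, events.csv, event_indices.csv")
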
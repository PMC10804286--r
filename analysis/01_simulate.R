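#!/usr/bin/env Rscript
# Generate the synthetic study recordings used by the downstream analysis
# steps: a 1-h sleep recording with REM-predominant flow limitation and
# obstructive apneas (the "phenotyping night"), a wake CO2-challenge run,
# and a 22-h calorimetry trace. Each recording is written to results/data/
# in the native container together with its ground truth tables.

suppressPackageStartupMessages(library(wbpsleep))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

message("Simulating the phenotyping night (1 h, apneas + flow limitation)...")
night_cfg <- synth_config(
  seed = 20260101, duration = 3600,
  hypnogram = list(bout_mean = c(W = 60, NREM = 180, REM = 120),
                   transition = list(W = c(NREM = 1),
                                     NREM = c(W = 0.4, REM = 0.6),
                                     REM = c(W = 0.7, NREM = 0.3))),
  flow_limitation = list(prob_rem = 0.3, plateau_severity = 0.9),
  apnea = list(rate = c(W = 0, NREM = 2, REM = 20))
)
night <- generate_recording(night_cfg)
write_recording(night$recording, "results/data/night")
write_breath_table(night$truth$breath_table, "results/data/night_truth_breaths.csv")
write_events(cbind(kind = "apnea", night$truth$apnea_events, magnitude = NA),
             "results/data/night_truth_apneas.csv")
write_hypnogram(night$truth$hypnogram_true, "results/data/night_truth_hypnogram.csv")

message("Simulating the wake hypercapnic challenge (0% -> 8% CO2)...")
hcvr_cfg <- synth_config(
  seed = 20260102, co2_protocol = list(c(0, 300), c(8, 300)), hcvr_gain = 7.5,
  hypnogram = list(transition = list(W = c(W = 1)),
                   bout_mean = c(W = 600, NREM = 160, REM = 60)),
  apnea = list(rate = c(W = 0, NREM = 0, REM = 0))
)
hcvr_rec <- generate_recording(hcvr_cfg)
write_recording(hcvr_rec$recording, "results/data/hcvr")

message("Simulating the calorimetry day (22 h on the 11-min grid)...")
met_cfg <- synth_config(
  seed = 20260103, duration = 22 * 3600,
  metabolism = list(vo2 = 90, rer = 0.85, activity_rate = 2, noise_sd = 0.03)
)
met <- generate_metabolic_traces(met_cfg, seed = met_cfg$seed)
data.table::fwrite(
  data.frame(t_s = met$times, fio2_in = met$fio2_in, fio2_out = met$fio2_out,
             fico2_in = met$fico2_in, fico2_out = met$fico2_out),
  "results/data/calorimetry_fractions.csv")
data.table::fwrite(data.frame(t_s = seq_along(met$activity) - 1,
                              beam_breaks = met$activity),
                   "results/data/calorimetry_activity.csv")

message("True REM apnea count: ", sum(night$truth$apnea_events$stage == "REM"),
        "; true HCVR gain: ", hcvr_cfg$hcvr_gain,
        " mL/min/%CO2; true VO2: ", met$vo2_true, " mL/h (RER ",
        met$rer_true, ")")
message("Done: recordings under results/data/")
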
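#!/usr/bin/env Rscript
# Hypercapnic ventilatory response from the wake CO2 challenge and
# ventilation/metabolism coupling from the calorimetry day.

suppressPackageStartupMessages(library(wbpsleep))

## HCVR: slope of plateau VE on inspired CO2 during wakefulness
rec <- read_recording("results/data/hcvr")
hyp <- hypnogram(rep("W", floor(sum(sapply(rec$meta$co2_protocol, `[`, 2)) / 5)),
                 source = "external")
flow <- get_channel(rec, "flow")
breaths <- breath_features(flow, segment_breaths(flow), hyp = hyp)
res <- hcvr_from_protocol(breaths, rec$meta$co2_protocol)
message(sprintf("HCVR: %.2f mL/min per %%CO2 (baseline VE %.1f, VE at 8%% %.1f mL/min)",
                res$slope, res$ve_per_level[1], res$ve_per_level[2]))
data.table::fwrite(data.frame(co2_pct = res$levels, ve_ml_min = res$ve_per_level),
                   "results/hcvr_levels.csv")
data.table::fwrite(data.frame(slope = res$slope, intercept = res$intercept,
                              r_squared = res$r_squared),
                   "results/hcvr_fit.csv")

## calorimetry: VO2/VCO2/RER on the 11-min grid + coupling with VE
fr <- data.table::fread("results/data/calorimetry_fractions.csv")
rates <- open_circuit_rates(fr$fio2_in, fr$fio2_out, fr$fico2_in, fr$fico2_out,
                            flow_rate = 500)
bins <- sample_grid(fr$t_s, list(vo2 = rates$vo2 * 60, vco2 = rates$vco2 * 60))
bins$rer <- bins$vco2 / bins$vo2
act <- data.table::fread("results/data/calorimetry_activity.csv")
counts <- activity_counts(act$beam_breaks, sample_rate = 1)
message(sprintf("VO2 %.1f mL/h, VCO2 %.1f mL/h, RER %.3f; %d beam breaks",
                mean(bins$vo2), mean(bins$vco2), mean(bins$rer), counts$total))

# couple the night's sleeping VE to the metabolic rates
vent <- data.table::fread("results/ventilation_by_stage.csv")
ve_sleep <- mean(vent$inst_ve_mean[vent$group %in% c("NREM", "REM")], na.rm = TRUE)
cr <- coupling_ratios(ve_sleep, mean(bins$vo2), mean(bins$vco2))
message(sprintf("VE/VO2 = %.1f, VE/VCO2 = %.1f (sleep VE %.1f mL/min)",
                cr$ve_over_vo2, cr$ve_over_vco2, ve_sleep))
data.table::fwrite(bins, "results/metabolic_bins.csv")
data.table::fwrite(data.frame(ve_sleep_ml_min = ve_sleep,
                              ve_over_vo2 = cr$ve_over_vo2,
                              ve_over_vco2 = cr$ve_over_vco2,
                              activity_total = counts$total),
                   "results/coupling.csv")
message("Wrote results/hcvr_*.csv, metabolic_bins.csv, coupling.csv")
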
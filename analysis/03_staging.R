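#!/usr/bin/env Rscript
# Automated sleep staging of the phenotyping night from EEG band powers and
# EMG tone, compared against the generator's hypnogram, plus the sleep
# architecture summary.

suppressPackageStartupMessages(library(wbpsleep))

rec <- read_recording("results/data/night")
truth <- read_hypnogram("results/data/night_truth_hypnogram.csv")

scored <- score_sleep(rec)
acc <- mean(scored$stages == truth$stages)
message(sprintf("Epoch-by-epoch agreement with ground truth: %.1f%%", 100 * acc))

arch <- architecture_summary(scored)
message(sprintf("Total sleep %.0f min (NREM %.0f, REM %.0f); %d REM bouts of mean %.0f s",
                arch$total_sleep_s / 60, arch$stages$NREM$time_s / 60,
                arch$stages$REM$time_s / 60, arch$stages$REM$bout_n,
                arch$stages$REM$bout_mean_s))

write_hypnogram(scored, "results/hypnogram_scored.csv")
data.table::fwrite(arch$bouts, "results/sleep_bouts.csv")
summ <- data.frame(stage = c("W", "NREM", "REM"),
                   time_s = sapply(c("W", "NREM", "REM"),
                                   function(s) arch$stages[[s]]$time_s),
                   bout_n = sapply(c("W", "NREM", "REM"),
                                   function(s) arch$stages[[s]]$bout_n))
data.table::fwrite(summ, "results/sleep_architecture.csv")
message("Wrote results/hypnogram_scored.csv, sleep_bouts.csv, sleep_architecture.csv")
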
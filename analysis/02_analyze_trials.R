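#!/usr/bin/env Rscript
# Run the full biomechanical pipeline on the simulated trials from
# 01_simulate_trials.R: smoothing, attitude, energetics, pendulum-template
# mechanics, stability margins, attempt segmentation, and method
# classification. Writes per-frame metric tables and a per-trial summary
# (the synthetic analogue of a righting-methods comparison table).

library(righting)

in_dir <- "results/trials"
out_dir <- "results/metrics"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

files <- list.files(in_dir, pattern = "_landmarks\\.csv$", full.names = TRUE)
if (length(files) == 0) stop("run analysis/01_simulate_trials.R first")

summaries <- list()
for (f in files) {
  tag <- sub("_landmarks\\.csv$", "", basename(f))
  trial <- read_landmark_table(f, schema = landmark_schema())
  an <- analyze_trial(trial, robust = grepl("noisy", tag))
  write_metrics(an$frames, file.path(out_dir, paste0(tag, "_metrics.csv")))
  summaries[[tag]] <- cbind(trial = tag, an$summary)
  message(sprintf("%-22s method = %-18s attempts = %d success = %s",
                  tag, an$method, an$n_attempts, an$success))
}
summary_df <- do.call(rbind, summaries)
write_metrics(summary_df, file.path(out_dir, "trial_summaries.csv"))
message("wrote per-frame metrics and trial_summaries.csv to ", out_dir)
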
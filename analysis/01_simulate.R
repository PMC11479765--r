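#!/usr/bin/env Rscript
# Generate the synthetic cohorts every later stage consumes:
#  - an 11-recording effect-mode cohort at the schedule level (5 h each),
#    carrying the default state-dependent approach effect;
#  - a matching null-mode cohort (state parameters equalized);
#  - one full pose-level recording (20 min) for the trajectory stages.
# Outputs land in results/ as RDS intermediates plus CSV echoes.

suppressPackageStartupMessages(library(socialseq))
dir.create("results", showWarnings = FALSE)
seed <- 1

cfg <- synthetic_config()
cat("simulating 11 x 5 h effect-mode recordings (schedule level)...\n")
effect <- generate_cohort(cfg, 11, seed = seed, poses = FALSE)

cfg_null <- synthetic_config(null_mode = TRUE)
cat("simulating 11 x 5 h null-mode recordings...\n")
null <- generate_cohort(cfg_null, 11, seed = seed, poses = FALSE)

cat("simulating one 20 min pose-level recording...\n")
pose_rec <- generate_recording(synthetic_config(duration_s = 1200,
                                                rate_aggressive_per_h = 55),
                               seed = seed + 10)

saveRDS(effect, "results/cohort_effect.rds")
saveRDS(null, "results/cohort_null.rds")
saveRDS(pose_rec, "results/pose_recording.rds")
simulate_to_disk(synthetic_config(duration_s = 1200,
                                  rate_aggressive_per_h = 55),
                 n_recordings = 1, seed = seed + 10,
                 out_dir = "results/example_recording")

n_events <- sum(sapply(effect, function(r) nrow(r$bundle$events)))
cat(sprintf("done: %d labeled events across the effect cohort\n", n_events))
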
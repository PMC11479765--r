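#!/usr/bin/env Rscript
# State-dependence stage: difference-index permutation suite and the
# decision-tree state decoders with size-matched and time-randomized
# controls, on the effect cohort, with the null cohort as calibration.

suppressPackageStartupMessages(library(socialseq))
fps <- 30
pool <- function(cohort) {
  do.call(rbind, lapply(cohort, function(rec) {
    b <- rec$bundle
    trig <- b$events[b$events$label %in% c("chase", "flee"), ]
    extract_triggered_sequences(trig, episodes_to_interactions(rec), fps,
                                recording_id = b$recording_id)
  }))
}
effect <- readRDS("results/cohort_effect.rds")
null_c <- readRDS("results/cohort_null.rds")
sq <- pool(effect)
sq0 <- pool(null_c)

cat(sprintf("observed difference index %.3f (negative = aggressed majority)\n",
            difference_index(sq)))
sub <- subsample_index_distribution(sq, k = 50, n_iter = 1000, seed = 2)
cat(sprintf("50-sequence subsamples: %.1f%% of 1000 indices below zero, z = %.1f\n",
            100 * sub$frac_negative, sub$z))
sh <- identity_shuffle_null(sq, n_iter = 1000, seed = 3)
cat(sprintf("identity shuffle: z = %.1f, p = %.3g\n", sh$z, sh$p))
sh0 <- identity_shuffle_null(sq0, n_iter = 1000, seed = 3)
cat(sprintf("null cohort shuffle: index %.3f, z = %.1f, p = %.3g\n",
            sh0$observed_index, sh0$z, sh0$p))

obs <- decode_state(sq, n_iter = 1000, seed = 4)
sm <- decode_state(sq, n_iter = 1000, condition = "size_matched", seed = 5)
rec1 <- effect[[1]]
rnd <- decode_state(NULL, n_iter = 500, condition = "randomized", seed = 6,
                    events = rec1$bundle$events,
                    interactions = episodes_to_interactions(rec1),
                    recording_length = rec1$bundle$n_frames)
for (d in list(obs, sm, rnd)) print(d)

acc <- rbind(
  data.frame(condition = "observed", iteration = seq_along(obs$accuracies),
             accuracy = obs$accuracies),
  data.frame(condition = "size_matched", iteration = seq_along(sm$accuracies),
             accuracy = sm$accuracies),
  data.frame(condition = "randomized", iteration = seq_along(rnd$accuracies),
             accuracy = rnd$accuracies))
write.csv(acc, "results/decoder_accuracies.csv", row.names = FALSE)
jsonlite::write_json(
  list(observed = obs[c("mean", "sd", "z", "p", "chance")],
       size_matched = sm[c("mean", "sd", "z", "p", "chance")],
       randomized = rnd[c("mean", "sd", "z", "p", "chance")]),
  "results/decoder_summary.json", auto_unbox = TRUE, digits = NA)
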
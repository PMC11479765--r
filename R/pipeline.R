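# End-to-end orchestration: detection -> sequences -> angles/initiator ->
# three-step -> resampling -> decoding, with CSV/JSON outputs and a
# provenance record.

#' Pipeline configuration
#'
#' Collects the tunable parameters of every stage with defaults equal to
#' the published values where printed (ellipse extension 3 cm, minimum bout
#' 6 frames, stationarity threshold 0.023 cm/s, 50-sequence subsamples,
#' 1,000 iterations, 75/25 decoder splits).
#'
#' @param out_dir Output directory for tables and the run log.
#' @param extension_cm,min_frames Interaction detector parameters.
#' @param speed_threshold Initiator stationarity threshold (cm/s).
#' @param k_subsample,n_iter,seed Resampling parameters.
#' @param split Decoder training fraction.
#' @param n_decoder_iter Decoder iterations.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "socialseq_out", extension_cm = 3,
                            min_frames = 6, speed_threshold = 0.023,
                            k_subsample = 50, n_iter = 1000, seed = 1,
                            split = 0.75, n_decoder_iter = 1000) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write a synthetic cohort to disk
#'
#' Emits, per recording, the pose CSV, the event CSV, the ground-truth
#' episode CSV and the JSON sidecar, plus an echo of the generator
#' configuration.
#'
#' @param config [synthetic_config()].
#' @param n_recordings Number of recordings.
#' @param seed Master seed.
#' @param out_dir Output directory (created if needed).
#' @param poses Write pose tables (slower) or only events/ground truth.
#' @return Invisibly, the directory path.
#' @export
simulate_to_disk <- function(config, n_recordings = 11, seed = 1,
                             out_dir = "socialseq_sim", poses = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(config, n_recordings, seed, poses = poses)
  for (rec in cohort) {
    id <- rec$bundle$recording_id
    if (!is.null(rec$bundle$poses))
      write_pose_table(rec$bundle, file.path(out_dir, paste0(id, "_poses.csv.gz")))
    write_event_table(rec$bundle$events, file.path(out_dir, paste0(id, "_events.csv")))
    utils::write.csv(rec$truth$episodes,
                     file.path(out_dir, paste0(id, "_truth_episodes.csv")),
                     row.names = FALSE)
    write_sidecar(rec$bundle, file.path(out_dir, paste0(id, "_sidecar.json")))
  }
  cfg_echo <- config
  cfg_echo$arena <- unclass(cfg_echo$arena)
  jsonlite::write_json(unclass(cfg_echo)[!vapply(cfg_echo, is.data.frame, TRUE)],
                       file.path(out_dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Run the full analysis pipeline on a cohort
#'
#' @param cohort list of recordings, each a list with `bundle` (and
#'   optionally `truth`), e.g. from [generate_cohort()].
#' @param config [pipeline_config()].
#' @param use_planted_interactions Use ground-truth episodes instead of the
#'   pose-based detector (required for schedule-level cohorts).
#' @return list of result tables (sequences, summaries, index tests,
#'   decoder runs, three-step typing, fight association), also written
#'   under `config$out_dir` when it is not `NULL`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(),
                         use_planted_interactions = FALSE) {
  set.seed(config$seed)
  all_seq <- list(); all_types <- list(); fight_counts <- list()
  events_pool <- list(); interactions_pool <- list()
  for (rec in cohort) {
    b <- rec$bundle
    fps <- b$arena$fps
    si <- if (use_planted_interactions || is.null(b$poses)) {
      episodes_to_interactions(rec)
    } else {
      detect_interactions(b, min_frames = config$min_frames,
                          extension_cm = config$extension_cm)
    }
    trig <- b$events[b$events$label %in% c("chase", "flee"), , drop = FALSE]
    sq <- extract_triggered_sequences(trig, si, fps = fps,
                                      recording_id = b$recording_id)
    ts <- classify_three_step(sq, si, trig)
    ff <- fights_following(ts, b$events[b$events$label == "fight", , drop = FALSE],
                           trig, fps = fps)
    all_seq[[b$recording_id]] <- sq
    all_types[[b$recording_id]] <- ts
    fight_counts[[b$recording_id]] <- cbind(recording_id = b$recording_id,
                                            ff$counts)
    events_pool[[b$recording_id]] <- trig
    interactions_pool[[b$recording_id]] <- si
  }
  sequences <- do.call(rbind, all_seq)
  three_step <- do.call(rbind, all_types)
  rownames(sequences) <- rownames(three_step) <- NULL

  summaries <- summarize_sequences(sequences)
  hour_props <- hour_binned_state_proportions(sequences)
  k <- min(config$k_subsample,
           min(table(sequences$recording_id)))
  sub <- subsample_index_distribution(sequences, k = k,
                                      n_iter = config$n_iter)
  shuffle <- identity_shuffle_null(sequences, n_iter = config$n_iter)
  dec_obs <- decode_state(sequences, n_iter = config$n_decoder_iter,
                          condition = "observed", split = config$split)
  dec_sm <- decode_state(sequences, n_iter = config$n_decoder_iter,
                         condition = "size_matched", split = config$split)
  type_counts <- table(factor(three_step$sequence_type, levels = 1:4))

  results <- list(sequences = sequences, summaries = summaries,
                  hour_proportions = hour_props,
                  subsample_index = sub, identity_shuffle = shuffle,
                  decoder_observed = dec_obs, decoder_size_matched = dec_sm,
                  three_step = three_step, type_counts = type_counts,
                  fight_counts = do.call(rbind, fight_counts),
                  k_subsample = k)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(sequences, file.path(config$out_dir, "sequences.csv"),
                     row.names = FALSE)
    utils::write.csv(three_step, file.path(config$out_dir, "three_step.csv"),
                     row.names = FALSE)
    utils::write.csv(summaries, file.path(config$out_dir, "summaries.csv"),
                     row.names = FALSE)
    provenance <- list(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      r_version = R.version.string,
      package_version = as.character(utils::packageVersion("socialseq")),
      parameters = unclass(config),
      n_recordings = length(cohort),
      n_sequences = nrow(sequences))
    jsonlite::write_json(provenance,
                         file.path(config$out_dir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  results
}
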
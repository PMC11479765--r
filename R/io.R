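#' Read a pose table
#'
#' Pose tables are comma-separated UTF-8 files with a header row and one
#' record per mouse per frame:
#' `recording_id, mouse_id, frame, x_cm, y_cm, theta_rad, a_cm, b_cm,
#' nose_x_cm, nose_y_cm`. Frames are 0-based and must be contiguous per
#' mouse. Files may be gzip-compressed (`.gz`).
#'
#' @param path File path.
#' @param arena [arena_spec()] used for validation; its mice are inferred
#'   from the table unless `mice` is given.
#' @param mice Optional data.frame (`mouse_id`, `sex`). When omitted, sexes
#'   are guessed from the leading letter of the id (`M`/`F`).
#' @return A `recording_bundle` with trajectories only.
#' @export
read_pose_table <- function(path, arena = arena_spec(), mice = NULL) {
  poses <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(pose_columns, names(poses))
  if (length(missing))
    stop("pose table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(poses) == 0) {
    m <- if (is.null(mice)) default_mice()[0, ] else mice
    return(recording_bundle(arena, m, poses = poses, recording_id = "empty",
                            validate = FALSE))
  }
  poses <- poses[order(poses$mouse_id, poses$frame), , drop = FALSE]
  rownames(poses) <- NULL
  if (is.null(mice)) {
    ids <- unique(poses$mouse_id)
    sex <- ifelse(grepl("^[Ff]", ids), "F", "M")
    mice <- data.frame(mouse_id = ids, sex = sex, stringsAsFactors = FALSE)
  }
  recording_bundle(arena, mice, poses = poses,
                   recording_id = poses$recording_id[1])
}

#' Write a pose table
#' @param bundle A `recording_bundle` with poses.
#' @param path Output path (`.gz` suffix gives gzip output).
#' @export
write_pose_table <- function(bundle, path) {
  poses <- bundle$poses[, pose_columns]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(poses, con, row.names = FALSE)
  invisible(path)
}

#' Derive aggressor/aggressed roles for behavior events
#'
#' Chases and flights have discernible roles: the chasing male, or the male
#' being fled from, is the aggressor; the chased or fleeing male is the
#' aggressed. Walks, investigations, and fights carry no aggression roles.
#'
#' @param events data.frame with at least `label`, `actor_id`, `recipient_id`.
#' @return The events with `aggressor_id` and `aggressed_id` columns added.
#' @export
derive_roles <- function(events) {
  events$aggressor_id <- rep(NA_character_, nrow(events))
  events$aggressed_id <- rep(NA_character_, nrow(events))
  ch <- events$label == "chase"
  events$aggressor_id[ch] <- events$actor_id[ch]
  events$aggressed_id[ch] <- events$recipient_id[ch]
  fl <- events$label == "flee"
  events$aggressor_id[fl] <- events$recipient_id[fl]
  events$aggressed_id[fl] <- events$actor_id[fl]
  events
}

#' Read a behavior event table
#'
#' Event tables are CSV files with columns
#' `label, actor_id, recipient_id, start_frame, end_frame, confidence`.
#' Labels are one of chase, flee, walk, investigate, fight; `recipient_id`
#' is empty for walks. Intervals are half-open `[start_frame, end_frame)` in
#' 0-based frames. Aggression roles are derived on read and rows are sorted
#' by start frame.
#'
#' @param path File path (optionally gzip-compressed).
#' @return data.frame of events with derived roles.
#' @export
read_event_table <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", "", "-"))
  missing <- setdiff(event_columns, names(ev))
  if (length(missing))
    stop("event table is missing column(s): ", paste(missing, collapse = ", "))
  validate_events(ev)
  ev <- derive_roles(ev)
  ev <- ev[order(ev$start_frame, ev$end_frame), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Write a behavior event table
#' @param events Event data.frame.
#' @param path Output path.
#' @export
write_event_table <- function(events, path) {
  out <- events[, intersect(c(event_columns, "aggressor_id", "aggressed_id"),
                            names(events))]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE)
  invisible(path)
}

#' Write the arena/mice sidecar
#'
#' Stores the arena geometry and the sex of each mouse next to the CSV
#' tables as a small JSON file.
#'
#' @param bundle A `recording_bundle`.
#' @param path Output path.
#' @export
write_sidecar <- function(bundle, path) {
  obj <- list(arena = unclass(bundle$arena),
              mice = bundle$mice,
              recording_id = bundle$recording_id)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read the arena/mice sidecar
#' @param path JSON sidecar path.
#' @return list with `arena`, `mice`, `recording_id`.
#' @export
read_sidecar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- obj$arena
  obj$arena <- arena_spec(shape = a$shape,
                          width_cm = if (!is.null(a$width_cm)) a$width_cm else 76.2,
                          height_cm = if (!is.null(a$height_cm)) a$height_cm else 76.2,
                          diameter_cm = if (!is.null(a$diameter_cm)) a$diameter_cm else 68.6,
                          fps = a$fps)
  obj
}
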
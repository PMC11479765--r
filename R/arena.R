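#' Arena specification
#'
#' Describes the recording enclosure. The default is the square cage used for
#' group recordings (76.2 x 76.2 cm floor, filmed at 30 frames/s); a circular
#' cage is supported through `shape = "circle"` with a `diameter_cm`.
#'
#' Coordinates are in cm with the origin at the lower-left corner of the
#' bounding box, x increasing east and y increasing north. Frames are 0-based
#' and all intervals are half-open `[start, end)`.
#'
#' @param shape "rectangle" or "circle".
#' @param width_cm,height_cm Floor dimensions for a rectangular arena (cm).
#' @param diameter_cm Floor diameter for a circular arena (cm).
#' @param fps Video frame rate (frames/s).
#' @return An object of class `arena_spec`.
#' @export
arena_spec <- function(shape = c("rectangle", "circle"),
                       width_cm = 76.2, height_cm = 76.2,
                       diameter_cm = 68.6, fps = 30) {
  shape <- match.arg(shape)
  if (fps <= 0) stop("fps must be positive")
  if (shape == "rectangle") {
    if (width_cm <= 0 || height_cm <= 0) stop("arena dimensions must be positive")
    out <- list(shape = shape, width_cm = width_cm, height_cm = height_cm,
                fps = fps)
  } else {
    if (diameter_cm <= 0) stop("arena diameter must be positive")
    out <- list(shape = shape, diameter_cm = diameter_cm,
                width_cm = diameter_cm, height_cm = diameter_cm, fps = fps)
  }
  class(out) <- "arena_spec"
  out
}

#' @export
print.arena_spec <- function(x, ...) {
  if (x$shape == "rectangle") {
    cat(sprintf("arena: rectangle %.1f x %.1f cm, %g fps\n",
                x$width_cm, x$height_cm, x$fps))
  } else {
    cat(sprintf("arena: circle diameter %.1f cm, %g fps\n",
                x$diameter_cm, x$fps))
  }
  invisible(x)
}

#' Standard group composition
#'
#' @param male_ids,female_ids Identifiers for the males and females of a
#'   recording. The standard group holds two of each.
#' @return data.frame with columns `mouse_id` and `sex`.
#' @export
default_mice <- function(male_ids = c("M1", "M2"),
                         female_ids = c("F1", "F2")) {
  ids <- c(male_ids, female_ids)
  if (anyDuplicated(ids)) stop("mouse ids must be unique")
  data.frame(mouse_id = ids,
             sex = c(rep("M", length(male_ids)), rep("F", length(female_ids))),
             stringsAsFactors = FALSE)
}

#' Assemble a recording bundle
#'
#' A recording bundle groups everything known about one recording: the arena,
#' the animals, the dense per-frame pose table, and the labeled behavior
#' events.
#'
#' @param arena An [arena_spec()].
#' @param mice data.frame with `mouse_id`, `sex`.
#' @param poses Pose table (see [read_pose_table()] for the column contract).
#'   May be `NULL` for event-only (schedule-level) bundles.
#' @param events Behavior event table (see [read_event_table()]), or `NULL`.
#' @param recording_id Recording identifier.
#' @param validate Check cross-references and pose invariants.
#' @return An object of class `recording_bundle`.
#' @export
recording_bundle <- function(arena, mice, poses = NULL, events = NULL,
                             recording_id = "rec1", validate = TRUE) {
  stopifnot(inherits(arena, "arena_spec"))
  b <- list(arena = arena, mice = mice, poses = poses, events = events,
            recording_id = recording_id)
  class(b) <- "recording_bundle"
  if (validate) validate_bundle(b)
  b
}

#' @export
print.recording_bundle <- function(x, ...) {
  nf <- if (is.null(x$poses)) 0L else max(x$poses$frame) + 1L
  ne <- if (is.null(x$events)) 0L else nrow(x$events)
  cat(sprintf("recording %s: %d mice, %d frames, %d events\n",
              x$recording_id, nrow(x$mice), nf, ne))
  invisible(x)
}

pose_columns <- c("recording_id", "mouse_id", "frame", "x_cm", "y_cm",
                  "theta_rad", "a_cm", "b_cm", "nose_x_cm", "nose_y_cm")
event_columns <- c("label", "actor_id", "recipient_id", "start_frame",
                   "end_frame", "confidence")
behavior_labels <- c("chase", "flee", "walk", "investigate", "fight")

validate_poses <- function(poses, arena = NULL, tol_cm = 1) {
  missing <- setdiff(pose_columns, names(poses))
  if (length(missing))
    stop("pose table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(poses) == 0) return(invisible(poses))
  if (any(poses$b_cm <= 0) || any(poses$a_cm < poses$b_cm))
    stop("pose ellipse axes must satisfy a_cm >= b_cm > 0")
  for (id in unique(poses$mouse_id)) {
    fr <- sort(poses$frame[poses$mouse_id == id])
    gaps <- which(diff(fr) != 1L)
    if (length(gaps)) {
      miss <- paste(sprintf("%d..%d", fr[gaps] + 1L, fr[gaps + 1L] - 1L),
                    collapse = ", ")
      stop(sprintf("non-contiguous frames for mouse %s: missing %s", id, miss))
    }
  }
  lens <- table(poses$mouse_id)
  if (length(unique(as.integer(lens))) > 1L)
    stop("co-recorded mice must have trajectories of equal length")
  if (!is.null(arena)) {
    if (arena$shape == "rectangle") {
      out <- poses$x_cm < -tol_cm | poses$x_cm > arena$width_cm + tol_cm |
        poses$y_cm < -tol_cm | poses$y_cm > arena$height_cm + tol_cm
    } else {
      r <- arena$diameter_cm / 2
      out <- sqrt((poses$x_cm - r)^2 + (poses$y_cm - r)^2) > r + tol_cm
    }
    if (any(out))
      stop(sprintf("%d pose centroid(s) fall outside the arena (tolerance %g cm)",
                   sum(out), tol_cm))
  }
  invisible(poses)
}

validate_events <- function(events) {
  if (is.null(events) || nrow(events) == 0) return(invisible(events))
  bad <- setdiff(unique(events$label), behavior_labels)
  if (length(bad)) stop("unknown behavior label(s): ", paste(bad, collapse = ", "))
  if (any(events$end_frame <= events$start_frame))
    stop("behavior events must satisfy end_frame > start_frame")
  same <- !is.na(events$recipient_id) & events$actor_id == events$recipient_id
  if (any(same)) stop("behavior events must have actor_id != recipient_id")
  invisible(events)
}

validate_bundle <- function(b) {
  if (!is.null(b$poses)) {
    validate_poses(b$poses, b$arena)
    unknown <- setdiff(unique(b$poses$mouse_id), b$mice$mouse_id)
    if (length(unknown))
      stop("pose table references unknown mice: ", paste(unknown, collapse = ", "))
  }
  if (!is.null(b$events) && nrow(b$events)) {
    validate_events(b$events)
    ids <- c(b$events$actor_id, b$events$recipient_id)
    unknown <- setdiff(unique(ids[!is.na(ids)]), b$mice$mouse_id)
    if (length(unknown))
      stop("event table references unknown mice: ", paste(unknown, collapse = ", "))
    if (!is.null(b$poses)) {
      nmax <- max(b$poses$frame) + 1L
      if (any(b$events$end_frame > nmax))
        stop("event frames extend beyond the trajectory range")
    }
  }
  invisible(b)
}

male_ids_of <- function(mice) mice$mouse_id[mice$sex == "M"]
female_ids_of <- function(mice) mice$mouse_id[mice$sex == "F"]

#' Number of frames in a bundle
#' @param bundle A `recording_bundle`.
#' @export
n_frames_of <- function(bundle) {
  if (!is.null(bundle$poses) && nrow(bundle$poses))
    return(max(bundle$poses$frame) + 1L)
  if (!is.null(bundle$n_frames)) return(bundle$n_frames)
  if (!is.null(bundle$events) && nrow(bundle$events))
    return(max(bundle$events$end_frame))
  0L
}
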
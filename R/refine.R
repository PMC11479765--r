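#' Default post-hoc event refinement rules
#'
#' Candidate events emitted by a supervised behavior classifier are cleaned
#' with per-label predicate sets over duration, classifier confidence,
#' inter-mouse distances and speeds. The defaults reproduce the published
#' refinement table for the five behavior labels; every threshold is strict
#' (`>` / `<`) as printed.
#'
#' Notes on interpretation where the printed rule is terse:
#' * chase "trajectories overlapping by at least 20%" is implemented as the
#'   fraction of chase frames in which the chaser passes within
#'   `overlap_radius_cm` (2 cm) of any point of the chased male's bout path;
#' * distance rules are evaluated as bout means unless marked `at_start`;
#' * "average score"/"confidence score" is the opaque per-event `confidence`
#'   column supplied with the event table; it is never recomputed.
#'
#' @return Nested list of rules, by label.
#' @export
default_refinement_rules <- function() {
  list(
    chase = list(min_duration_frames = 6,        # duration > 6 frames
                 min_traj_overlap = 0.20,        # >= 20 % path overlap
                 overlap_radius_cm = 2,
                 min_confidence = 0.5,
                 max_male_distance_cm = 30,      # mean male-male distance < 30
                 min_chased_female_distance_cm = 15), # chased male to nearest female > 15
    flee = list(min_duration_frames = 10,
                min_confidence = 0.7,
                max_closest_animal_cm = 8),      # mean distance to closest animal < 8
    walk = list(min_duration_frames = 20,
                min_confidence = 1),             # average score > 1
    investigate = list(min_confidence = 0.11,
                       max_speed = 0.19,         # mean speed of the pair, cm/s
                       min_speed = 0.015,
                       min_male_distance_cm = 0.04),
    fight = list(min_duration_frames = 30,
                 min_confidence = 1.5,
                 min_female_distance_at_start_cm = 5,
                 min_avg_speed = 7.5)
  )
}

# per-mouse position lookup: list of n_frames x 2 matrices keyed by mouse_id
position_index <- function(poses) {
  sp <- split(poses[, c("frame", "x_cm", "y_cm")], poses$mouse_id)
  lapply(sp, function(d) {
    d <- d[order(d$frame), ]
    cbind(d$x_cm, d$y_cm)
  })
}

seg_rows <- function(start_frame, end_frame) (start_frame + 1L):end_frame

pair_distance <- function(pos, id1, id2, rows) {
  p1 <- pos[[id1]][rows, , drop = FALSE]
  p2 <- pos[[id2]][rows, , drop = FALSE]
  sqrt(rowSums((p1 - p2)^2))
}

#' Apply post-hoc refinement filters to behavior events
#'
#' Removes candidate events that fail any predicate for their label and
#' reports per-rule rejection counts. Applying the filter twice gives the
#' same result as applying it once.
#'
#' @param events Event table with derived roles.
#' @param poses Pose table covering the event frames.
#' @param mice data.frame of `mouse_id`, `sex`.
#' @param fps Frames per second.
#' @param rules Rule set, defaulting to [default_refinement_rules()].
#' @return The retained events, with a `"rejections"` attribute: a named
#'   integer vector of counts per `label:rule`.
#' @export
refine_events <- function(events, poses, mice, fps = 30,
                          rules = default_refinement_rules()) {
  if (nrow(events) == 0) {
    attr(events, "rejections") <- integer(0)
    return(events)
  }
  uses_conf <- function(r) any(grepl("confidence", names(r)))
  need_conf <- any(vapply(events$label, function(l) uses_conf(rules[[l]]), TRUE))
  if (need_conf && (is.null(events$confidence) || anyNA(events$confidence)))
    stop("refinement rules reference a confidence score but events lack one")

  pos <- position_index(poses)
  females <- female_ids_of(mice)
  rej <- new.env()
  bump <- function(key) assign(key, (if (exists(key, rej)) get(key, rej) else 0L) + 1L, rej)

  keep <- logical(nrow(events))
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    r <- rules[[ev$label]]
    rows <- seg_rows(ev$start_frame, ev$end_frame)
    ok <- TRUE
    fail <- function(rule) { bump(paste(ev$label, rule, sep = ":")); FALSE }
    dur <- ev$end_frame - ev$start_frame
    if (!is.null(r$min_duration_frames) && !(dur > r$min_duration_frames))
      ok <- fail("min_duration_frames")
    if (ok && !is.null(r$min_confidence) && !(ev$confidence > r$min_confidence))
      ok <- fail("min_confidence")
    if (ok && ev$label == "chase") {
      d <- pair_distance(pos, ev$aggressor_id, ev$aggressed_id, rows)
      if (!(mean(d) < r$max_male_distance_cm)) ok <- fail("max_male_distance_cm")
      if (ok && length(females)) {
        df <- sapply(females, function(f)
          pair_distance(pos, ev$aggressed_id, f, rows))
        dmin <- if (is.matrix(df)) apply(df, 1, min) else min(df)
        if (!(mean(dmin) > r$min_chased_female_distance_cm))
          ok <- fail("min_chased_female_distance_cm")
      }
      if (ok) {
        chaser <- pos[[ev$aggressor_id]][rows, , drop = FALSE]
        chased <- pos[[ev$aggressed_id]][rows, , drop = FALSE]
        near <- vapply(seq_along(rows), function(k) {
          min(sqrt((chased[, 1] - chaser[k, 1])^2 +
                   (chased[, 2] - chaser[k, 2])^2)) <= r$overlap_radius_cm
        }, TRUE)
        if (!(mean(near) >= r$min_traj_overlap)) ok <- fail("min_traj_overlap")
      }
    }
    if (ok && ev$label == "flee") {
      others <- setdiff(names(pos), ev$actor_id)
      dmat <- sapply(others, function(o) pair_distance(pos, ev$actor_id, o, rows))
      dmin <- if (is.matrix(dmat)) apply(dmat, 1, min) else dmat
      if (!(mean(dmin) < r$max_closest_animal_cm))
        ok <- fail("max_closest_animal_cm")
    }
    if (ok && ev$label == "investigate") {
      d <- pair_distance(pos, ev$actor_id, ev$recipient_id, rows)
      if (!(mean(d) > r$min_male_distance_cm)) ok <- fail("min_male_distance_cm")
      if (ok) {
        sp <- (speed_in_rows(pos[[ev$actor_id]], rows, fps) +
               speed_in_rows(pos[[ev$recipient_id]], rows, fps)) / 2
        if (!(mean(sp) < r$max_speed && mean(sp) > r$min_speed))
          ok <- fail("speed_band")
      }
    }
    if (ok && ev$label == "fight") {
      ids <- c(ev$actor_id, ev$recipient_id)
      if (length(females)) {
        d0 <- sapply(females, function(f)
          pair_distance(pos, ids[1], f, rows[1]))
        d0 <- c(d0, sapply(females, function(f)
          pair_distance(pos, ids[2], f, rows[1])))
        if (!(min(d0) > r$min_female_distance_at_start_cm))
          ok <- fail("min_female_distance_at_start_cm")
      }
      if (ok) {
        sp <- (speed_in_rows(pos[[ids[1]]], rows, fps) +
               speed_in_rows(pos[[ids[2]]], rows, fps)) / 2
        if (!(mean(sp) > r$min_avg_speed)) ok <- fail("min_avg_speed")
      }
    }
    keep[i] <- ok
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  counts <- unlist(as.list(rej))
  attr(out, "rejections") <- if (is.null(counts)) integer(0) else counts
  out
}

speed_in_rows <- function(mat, rows, fps) {
  r0 <- pmax(rows - 1L, 1L)
  sqrt((mat[rows, 1] - mat[r0, 1])^2 + (mat[rows, 2] - mat[r0, 2])^2) * fps
}
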
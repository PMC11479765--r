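# Initiator assignment and zone-latency controls.

front_half_polygon <- function(e, n = 33) {
  # half of the social ellipse on the nose side of the minor axis
  t <- seq(-pi / 2, pi / 2, length.out = n)
  ct <- cos(e$theta); st <- sin(e$theta)
  px <- e$a * cos(t); py <- e$b * sin(t)
  cbind(e$center[1] + ct * px - st * py,
        e$center[2] + st * px + ct * py)
}

pose_ellipse_at <- function(d, row, extension_cm) {
  list(center = c(d$x_cm[row], d$y_cm[row]), theta = d$theta_rad[row],
       a = d$a_cm[row] + extension_cm, b = d$b_cm[row])
}

first_front_overlap <- function(da, db, rows, extension_cm) {
  for (r in rows) {
    ea <- pose_ellipse_at(da, r, extension_cm)
    eb <- pose_ellipse_at(db, r, extension_cm)
    if (convex_polys_overlap(front_half_polygon(ea), ellipse_polygon(eb)))
      return(r)
  }
  Inf
}

#' Assign the initiator of a social interaction
#'
#' Rules, applied in order at the bout's first frame:
#' 1. If exactly one partner is stationary (instantaneous speed below
#'    `speed_threshold`), the moving partner initiated.
#' 2. Otherwise the animal whose front half-ellipse (the nose side of the
#'    minor axis) overlaps the partner's social ellipse first initiated;
#'    if the two front overlaps begin within `mutual_window` frames of each
#'    other and both animals are heading toward each other (heading-to-target
#'    angle below pi/2), the initiation is mutual.
#' 3. Anything else (both stationary, or no front overlap found) is
#'    undetermined.
#'
#' @param si One interaction row (`male_id`, `female_id`, `start_frame`).
#' @param poses Pose table covering the bout start.
#' @param fps Frames per second.
#' @param speed_threshold Stationarity threshold (cm/s).
#' @param mutual_window Frame tolerance for mutual initiation.
#' @param extension_cm Social-ellipse extension.
#' @param lookahead Frames after bout start searched for front overlap.
#' @return One of "male", "female", "mutual", "undetermined".
#' @export
determine_initiator <- function(si, poses, fps = 30, speed_threshold = 0.023,
                                mutual_window = 6, extension_cm = 3,
                                lookahead = 15) {
  sp <- split(poses, poses$mouse_id)
  dm <- sp[[si$male_id]]; df <- sp[[si$female_id]]
  if (is.null(dm) || is.null(df)) stop("missing trajectory for a partner")
  dm <- dm[order(dm$frame), ]; df <- df[order(df$frame), ]
  f0 <- dm$frame[1]
  row0 <- si$start_frame - f0 + 1L
  if (row0 < 1L || row0 > nrow(dm)) stop("bout start outside the pose range")
  rprev <- max(row0 - 1L, 1L)
  speed_at <- function(d) {
    sqrt((d$x_cm[row0] - d$x_cm[rprev])^2 +
         (d$y_cm[row0] - d$y_cm[rprev])^2) * fps
  }
  vm <- speed_at(dm); vf <- speed_at(df)
  m_still <- vm < speed_threshold; f_still <- vf < speed_threshold
  if (m_still && f_still) return("undetermined")
  if (f_still && !m_still) return("male")
  if (m_still && !f_still) return("female")

  rows <- row0:min(row0 + lookahead, nrow(dm))
  fm <- first_front_overlap(dm, df, rows, extension_cm)
  ff <- first_front_overlap(df, dm, rows, extension_cm)
  if (is.infinite(fm) && is.infinite(ff)) return("undetermined")
  if (abs(fm - ff) <= mutual_window) {
    am <- heading_to_target_angle(dm[row0, ], df[row0, ])
    af <- heading_to_target_angle(df[row0, ], dm[row0, ])
    if (am < pi / 2 && af < pi / 2) return("mutual")
  }
  if (fm < ff) return("male")
  if (ff < fm) return("female")
  "undetermined"
}

#' Fill the initiator column of an interaction table
#' @param interactions Output of [detect_interactions()].
#' @param bundle The matching `recording_bundle`.
#' @param ... Passed to [determine_initiator()].
#' @export
fill_initiators <- function(interactions, bundle, ...) {
  if (nrow(interactions) == 0) return(interactions)
  interactions$initiator <- vapply(seq_len(nrow(interactions)), function(i)
    determine_initiator(interactions[i, ], bundle$poses,
                        fps = bundle$arena$fps, ...), character(1))
  interactions
}

#' Default arena zones
#'
#' Five circular zones of 6 cm radius: the arena center (zone 5) and four
#' "central" zones at the midpoints between the center and the north, east,
#' south and west wall midpoints (zones 1-4).
#'
#' @param arena An [arena_spec()].
#' @param radius_cm Zone radius.
#' @return data.frame with `zone_id`, `x_cm`, `y_cm`, `radius_cm`.
#' @export
default_zones <- function(arena, radius_cm = 6) {
  W <- arena$width_cm; H <- arena$height_cm
  data.frame(zone_id = 1:5,
             x_cm = c(W / 2, 3 * W / 4, W / 2, W / 4, W / 2),
             y_cm = c(3 * H / 4, H / 2, H / 4, H / 2, H / 2),
             radius_cm = radius_cm)
}

#' Latency for males to reach arena zones after aggressive behavior
#'
#' For every aggressive trigger and zone, measures the time from trigger end
#' until each male's centroid first enters the zone disk (0 when already
#' inside). Latencies are summarised per male, zone and role as medians;
#' events in which a zone is never reached before the recording ends are
#' excluded from the median and counted.
#'
#' @param bundle A `recording_bundle` with poses.
#' @param triggers Role-labeled aggressive events.
#' @param zones data.frame from [default_zones()].
#' @return list with `latencies` (per event x zone x role) and `summary`
#'   (per male x zone medians, with `n_unreached`).
#' @export
zone_latencies <- function(bundle, triggers, zones = default_zones(bundle$arena)) {
  fps <- bundle$arena$fps
  pos <- position_index(bundle$poses)
  n <- nrow(pos[[1]])
  rows_list <- list()
  for (i in seq_len(nrow(triggers))) {
    tr <- triggers[i, ]
    if (is.na(tr$aggressor_id)) next
    for (role in c("aggressor", "aggressed")) {
      id <- if (role == "aggressor") tr$aggressor_id else tr$aggressed_id
      start_row <- min(tr$end_frame + 1L, n)
      px <- pos[[id]][start_row:n, 1]; py <- pos[[id]][start_row:n, 2]
      for (z in seq_len(nrow(zones))) {
        inside <- (px - zones$x_cm[z])^2 + (py - zones$y_cm[z])^2 <=
          zones$radius_cm[z]^2
        hit <- which(inside)[1]
        rows_list[[length(rows_list) + 1]] <- data.frame(
          event = i, role = role, mouse_id = id, zone_id = zones$zone_id[z],
          latency_s = if (is.na(hit)) NA_real_ else (hit - 1) / fps,
          stringsAsFactors = FALSE)
      }
    }
  }
  lat <- do.call(rbind, rows_list)
  agg <- stats::aggregate(latency_s ~ mouse_id + zone_id + role, data = lat,
                          FUN = stats::median, na.action = stats::na.omit)
  unreached <- stats::aggregate(is.na(lat$latency_s),
                                by = list(mouse_id = lat$mouse_id,
                                          zone_id = lat$zone_id,
                                          role = lat$role), FUN = sum)
  names(unreached)[4] <- "n_unreached"
  list(latencies = lat, summary = merge(agg, unreached))
}
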
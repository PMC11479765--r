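#' Instantaneous speed of a trajectory
#'
#' Speed at frame t is the Euclidean centroid displacement from frame t-1 to
#' t multiplied by the frame rate. The first frame is backfilled with the
#' speed at the second frame so downstream stationarity tests are total.
#'
#' @param trajectory Pose rows for a single mouse, frame-sorted (columns
#'   `x_cm`, `y_cm`), or a two-column matrix of centroids.
#' @param fps Frames per second.
#' @return Numeric vector of speeds (cm/s), one per frame.
#' @export
compute_speed <- function(trajectory, fps) {
  if (is.data.frame(trajectory)) {
    x <- trajectory$x_cm; y <- trajectory$y_cm
  } else {
    x <- trajectory[, 1]; y <- trajectory[, 2]
  }
  n <- length(x)
  if (n < 2) stop("speed needs at least two frames")
  sp <- sqrt(diff(x)^2 + diff(y)^2) * fps
  c(sp[1], sp)
}

#' Fraction of the arena explored
#'
#' Tiles the arena bounding box with square bins of side `sqrt(bin_area_cm2)`
#' and reports the percentage of bins that contain at least one centroid.
#' For a rectangular arena, partial edge bins count in the denominator; for a
#' circular arena, a bin counts if its center lies inside the circle.
#'
#' @param trajectory Pose rows for one mouse (columns `x_cm`, `y_cm`).
#' @param arena An [arena_spec()].
#' @param bin_area_cm2 Bin area; the standard grid sizes are 9, 36, 81 cm^2.
#' @return Percentage of bins visited (0-100).
#' @export
exploration_fraction <- function(trajectory, arena, bin_area_cm2) {
  side <- sqrt(bin_area_cm2)
  W <- arena$width_cm; H <- arena$height_cm
  if (side > W || side > H) stop("bin side exceeds the arena dimensions")
  nx <- ceiling(W / side); ny <- ceiling(H / side)
  x <- if (is.data.frame(trajectory)) trajectory$x_cm else trajectory[, 1]
  y <- if (is.data.frame(trajectory)) trajectory$y_cm else trajectory[, 2]
  ix <- pmin(pmax(floor(x / side), 0), nx - 1)
  iy <- pmin(pmax(floor(y / side), 0), ny - 1)
  if (arena$shape == "circle") {
    r <- arena$diameter_cm / 2
    cx <- (rep(seq_len(nx), ny) - 0.5) * side
    cy <- (rep(seq_len(ny), each = nx) - 0.5) * side
    inside <- sqrt((cx - r)^2 + (cy - r)^2) <= r
    denom <- sum(inside)
    keep <- inside[ix + nx * iy + 1]
    visited <- length(unique((ix + nx * iy)[keep]))
  } else {
    denom <- nx * ny
    visited <- length(unique(ix + nx * iy))
  }
  100 * visited / denom
}

#' Aggression summary for a pair of co-recorded males
#'
#' Counts the aggressive events (chases and flights) in which each male acted
#' as the aggressor, and summarises their asymmetry with an aggression score
#' -- the difference between the second and the first male's counts divided
#' by their total -- together with a 1-df chi-square goodness-of-fit test
#' against equal expression of aggression.
#'
#' @param events Event table with derived roles (see [derive_roles()]).
#' @param male_ids Character vector of the two male ids; the score sign
#'   follows this ordering.
#' @return list with `counts`, `aggression_score` (in `[-1, 1]`, positive
#'   when the second male is more aggressive), `more_aggressive_id`,
#'   `chi_square_p`, and `defined` (FALSE when no aggressive events exist).
#' @export
aggression_summary <- function(events, male_ids) {
  stopifnot(length(male_ids) == 2)
  agg <- events[events$label %in% c("chase", "flee"), , drop = FALSE]
  counts <- c(sum(agg$aggressor_id == male_ids[1], na.rm = TRUE),
              sum(agg$aggressor_id == male_ids[2], na.rm = TRUE))
  names(counts) <- male_ids
  total <- sum(counts)
  if (total == 0) {
    return(list(counts = counts, aggression_score = NA_real_,
                more_aggressive_id = NA_character_, chi_square_p = NA_real_,
                defined = FALSE))
  }
  score <- (counts[2] - counts[1]) / total
  more <- if (counts[1] == counts[2]) NA_character_ else male_ids[which.max(counts)]
  p <- suppressWarnings(stats::chisq.test(counts, p = c(0.5, 0.5))$p.value)
  list(counts = counts, aggression_score = unname(score),
       more_aggressive_id = more, chi_square_p = p, defined = TRUE)
}
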
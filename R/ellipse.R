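#' Social ellipse of a pose
#'
#' The social ellipse is the fitted body ellipse lengthened 3 cm along the
#' major axis in front of and behind the animal: the center, orientation and
#' semi-minor axis are unchanged and the semi-major axis grows by the
#' extension.
#'
#' @param pose A single pose row (`x_cm`, `y_cm`, `theta_rad`, `a_cm`,
#'   `b_cm`) or a list with `center`, `theta`, `a`, `b`.
#' @param extension_cm Extension at each end of the major axis (cm).
#' @return list with `center`, `theta`, `a`, `b` describing the ellipse.
#' @export
social_ellipse <- function(pose, extension_cm = 3) {
  if (extension_cm < 0) stop("extension_cm must be non-negative")
  e <- as_ellipse(pose)
  e$a <- e$a + extension_cm
  e
}

as_ellipse <- function(pose) {
  if (!is.null(pose$center))
    return(list(center = pose$center, theta = pose$theta, a = pose$a, b = pose$b))
  list(center = c(pose$x_cm, pose$y_cm), theta = pose$theta_rad,
       a = pose$a_cm, b = pose$b_cm)
}

#' Polygonal approximation of an ellipse boundary
#'
#' @param e Ellipse (list with `center`, `theta`, `a`, `b`).
#' @param n Number of boundary vertices.
#' @return n x 2 matrix of vertices, counter-clockwise.
#' @export
ellipse_polygon <- function(e, n = 64) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  ct <- cos(e$theta); st <- sin(e$theta)
  px <- e$a * cos(t); py <- e$b * sin(t)
  cbind(e$center[1] + ct * px - st * py,
        e$center[2] + st * px + ct * py)
}

# Separating-axis test for two convex polygons. Touching boundaries count as
# overlap (closed regions): separation requires a strict gap on some axis.
convex_polys_overlap <- function(P, Q) {
  for (poly in list(P, Q)) {
    m <- nrow(poly)
    edges <- poly[c(2:m, 1), ] - poly
    ax <- cbind(-edges[, 2], edges[, 1])
    pp <- ax %*% t(P)
    pq <- ax %*% t(Q)
    pmin1 <- apply(pp, 1, min); pmax1 <- apply(pp, 1, max)
    qmin <- apply(pq, 1, min); qmax <- apply(pq, 1, max)
    if (any(pmax1 < qmin | qmax < pmin1)) return(FALSE)
  }
  TRUE
}

#' Do two ellipses overlap?
#'
#' True when the closed elliptical regions intersect (boundary contact
#' counts). Implemented by polygonal approximation with `n_vertices`
#' boundary points per ellipse and a convex separating-axis test, which also
#' covers containment. Cheap center-distance bounds bypass the polygon test
#' for clearly separated or clearly touching pairs.
#'
#' @param e1,e2 Ellipses (lists with `center`, `theta`, `a`, `b`).
#' @param n_vertices Boundary vertices per ellipse.
#' @return logical.
#' @export
ellipses_overlap <- function(e1, e2, n_vertices = 64) {
  if (e1$a <= 0 || e1$b <= 0 || e2$a <= 0 || e2$b <= 0)
    stop("degenerate (zero-area) ellipse")
  d <- sqrt(sum((e1$center - e2$center)^2))
  if (d > e1$a + e2$a) return(FALSE)
  if (d <= e1$b + e2$b) return(TRUE)
  convex_polys_overlap(ellipse_polygon(e1, n_vertices),
                       ellipse_polygon(e2, n_vertices))
}

# Vectorised overlap over aligned pose frames for one (male, female) pair.
# p1, p2: data.frames/lists with x, y, theta, a, b vectors (social axes).
overlap_frames <- function(x1, y1, t1, a1, b1, x2, y2, t2, a2, b2,
                           n_vertices = 64) {
  d <- sqrt((x1 - x2)^2 + (y1 - y2)^2)
  res <- d <= (b1 + b2)                    # certain overlap
  maybe <- which(d <= (a1 + a2) & !res)    # ambiguous band
  for (i in maybe) {
    e1 <- list(center = c(x1[i], y1[i]), theta = t1[i], a = a1[i], b = b1[i])
    e2 <- list(center = c(x2[i], y2[i]), theta = t2[i], a = a2[i], b = b2[i])
    res[i] <- convex_polys_overlap(ellipse_polygon(e1, n_vertices),
                                   ellipse_polygon(e2, n_vertices))
  }
  res
}

runs_from_logical <- function(flag, min_frames) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_frames
  cbind(start = starts[keep], end = ends[keep])  # inclusive row indices
}

#' Detect social interaction bouts from poses
#'
#' For every eligible mouse pair, finds maximal runs of consecutive frames in
#' which the two social ellipses overlap; runs shorter than `min_frames`
#' (6 frames, i.e. 0.2 s at 30 fps) are discarded and no gap-merging is
#' applied. By default only opposite-sex pairs are scanned. A simpler
#' centroid-distance detector (separation below one body length, 6 cm) is
#' available for sensitivity analyses.
#'
#' @param bundle A `recording_bundle` with dense trajectories.
#' @param pair_filter "opposite_sex", "same_sex" or "all".
#' @param min_frames Minimum bout length in frames.
#' @param extension_cm Social-ellipse extension.
#' @param method "ellipse" (overlap of social ellipses) or "centroid"
#'   (centroid separation below `centroid_threshold_cm`).
#' @param centroid_threshold_cm Threshold for the centroid method.
#' @return data.frame of bouts: `recording_id`, `male_id`, `female_id` (for
#'   same-sex pairs these columns hold the two ids in sorted order),
#'   `start_frame`, `end_frame` (half-open), `duration_s`, `initiator`
#'   (`NA`, fill with [fill_initiators()]).
#' @export
detect_interactions <- function(bundle, pair_filter = "opposite_sex",
                                min_frames = 6, extension_cm = 3,
                                method = c("ellipse", "centroid"),
                                centroid_threshold_cm = 6) {
  method <- match.arg(method)
  if (is.null(bundle$poses) || nrow(bundle$poses) == 0)
    stop("detect_interactions needs a bundle with poses")
  listed <- bundle$mice$mouse_id
  have <- unique(bundle$poses$mouse_id)
  if (length(setdiff(listed, have)))
    stop("missing trajectory for mouse: ",
         paste(setdiff(listed, have), collapse = ", "))
  fps <- bundle$arena$fps
  sp <- split(bundle$poses, bundle$poses$mouse_id)
  sp <- lapply(sp, function(d) d[order(d$frame), ])
  sexes <- stats::setNames(bundle$mice$sex, bundle$mice$mouse_id)

  pairs <- utils::combn(listed, 2, simplify = FALSE)
  pairs <- Filter(function(p) {
    opp <- sexes[p[1]] != sexes[p[2]]
    switch(pair_filter, opposite_sex = opp, same_sex = !opp, all = TRUE)
  }, pairs)

  out <- list()
  for (p in pairs) {
    # order as (male, female) when opposite-sex, else lexicographic
    if (sexes[p[1]] != sexes[p[2]]) {
      m <- if (sexes[p[1]] == "M") p[1] else p[2]
      f <- setdiff(p, m)
    } else { m <- min(p); f <- max(p) }
    d1 <- sp[[m]]; d2 <- sp[[f]]
    if (method == "centroid") {
      flag <- sqrt((d1$x_cm - d2$x_cm)^2 + (d1$y_cm - d2$y_cm)^2) <=
        centroid_threshold_cm
    } else {
      flag <- overlap_frames(d1$x_cm, d1$y_cm, d1$theta_rad,
                             d1$a_cm + extension_cm, d1$b_cm,
                             d2$x_cm, d2$y_cm, d2$theta_rad,
                             d2$a_cm + extension_cm, d2$b_cm)
    }
    runs <- runs_from_logical(flag, min_frames)
    if (nrow(runs)) {
      f0 <- d1$frame[1]
      out[[length(out) + 1]] <- data.frame(
        recording_id = bundle$recording_id,
        male_id = m, female_id = f,
        start_frame = f0 + runs[, "start"] - 1L,
        end_frame = f0 + runs[, "end"],          # half-open
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(recording_id = character(0), male_id = character(0),
                      female_id = character(0), start_frame = integer(0),
                      end_frame = integer(0), duration_s = numeric(0),
                      initiator = character(0), stringsAsFactors = FALSE))
  }
  si <- do.call(rbind, out)
  si <- si[order(si$start_frame, si$male_id), , drop = FALSE]
  si$duration_s <- (si$end_frame - si$start_frame) / fps
  si$initiator <- NA_character_
  rownames(si) <- NULL
  si
}
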
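# Fixtures built in code: small pose/event tables and ellipse helpers used
# across the test files.

make_pose_df <- function(mouse_id, xy, theta = NULL, a = 2, b = 1.2,
                         recording_id = "recT", frame0 = 0) {
  n <- nrow(xy)
  if (is.null(theta)) theta <- rep(0, n)
  data.frame(recording_id = recording_id, mouse_id = mouse_id,
             frame = frame0 + seq_len(n) - 1L,
             x_cm = xy[, 1], y_cm = xy[, 2], theta_rad = theta,
             a_cm = a, b_cm = b,
             nose_x_cm = xy[, 1] + a * cos(theta),
             nose_y_cm = xy[, 2] + a * sin(theta),
             stringsAsFactors = FALSE)
}

make_event <- function(label, actor, recipient, start, end, confidence = 1) {
  derive_roles(data.frame(label = label, actor_id = actor,
                          recipient_id = recipient, start_frame = start,
                          end_frame = end, confidence = confidence,
                          stringsAsFactors = FALSE))
}

make_si <- function(male, female, start, end, fps = 30,
                    recording_id = "recT") {
  data.frame(recording_id = recording_id, male_id = male, female_id = female,
             start_frame = start, end_frame = end,
             duration_s = (end - start) / fps, initiator = NA_character_,
             stringsAsFactors = FALSE)
}

rand_ellipse <- function() {
  a <- stats::runif(1, 2, 8)
  list(center = stats::runif(2, 0, 20), theta = stats::runif(1, -pi, pi),
       a = a, b = stats::runif(1, 1, a))
}

# Brute-force membership oracle for ellipse overlap: dense boundary
# sampling plus center containment.
point_in_ellipse <- function(pts, e, tol = 1e-12) {
  d <- cbind(pts[, 1] - e$center[1], pts[, 2] - e$center[2])
  ct <- cos(e$theta); st <- sin(e$theta)
  xr <- ct * d[, 1] + st * d[, 2]
  yr <- -st * d[, 1] + ct * d[, 2]
  (xr / e$a)^2 + (yr / e$b)^2 <= 1 + tol
}

boundary_points <- function(e, n = 1e4) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  ct <- cos(e$theta); st <- sin(e$theta)
  px <- e$a * cos(t); py <- e$b * sin(t)
  cbind(e$center[1] + ct * px - st * py, e$center[2] + st * px + ct * py)
}

overlap_oracle <- function(e1, e2, n = 1e4) {
  any(point_in_ellipse(boundary_points(e1, n), e2)) ||
    any(point_in_ellipse(boundary_points(e2, n), e1)) ||
    point_in_ellipse(matrix(e1$center, 1), e2) ||
    point_in_ellipse(matrix(e2$center, 1), e1)
}

inflate_ellipse <- function(e, d) { e$a <- e$a + d; e$b <- e$b + d; e }

# Pool triggered sequences over a cohort generated at the schedule level.
pool_cohort_sequences <- function(cohort, fps = 30) {
  do.call(rbind, lapply(cohort, function(rec) {
    b <- rec$bundle
    trig <- b$events[b$events$label %in% c("chase", "flee"), , drop = FALSE]
    extract_triggered_sequences(trig, episodes_to_interactions(rec), fps,
                                recording_id = b$recording_id)
  }))
}
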
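#' Wrap angles to (-pi, pi]
#' @param x Angles in radians.
#' @export
wrap_angle <- function(x) {
  w <- x %% (2 * pi)
  w[w > pi] <- w[w > pi] - 2 * pi
  w
}

#' Angle between a male's heading and the direction to a female
#'
#' The heading vector `v1` runs from the male's body center to his nose; the
#' target vector `v2` runs from the male's center to the female's center.
#' The unsigned angle between them is the two-argument arctangent of the
#' cross-product magnitude and the dot product, giving a value in `[0, pi]`.
#'
#' @param male_pose,female_pose Single pose rows.
#' @return Angle in radians, in `[0, pi]`.
#' @export
heading_to_target_angle <- function(male_pose, female_pose) {
  v1 <- c(male_pose$nose_x_cm - male_pose$x_cm,
          male_pose$nose_y_cm - male_pose$y_cm)
  v2 <- c(female_pose$x_cm - male_pose$x_cm,
          female_pose$y_cm - male_pose$y_cm)
  angle_between(v1, v2)
}

angle_between <- function(v1, v2) {
  if (all(v1 == 0) || all(v2 == 0))
    stop("zero-length vector in angle computation")
  atan2(abs(v1[1] * v2[2] - v1[2] * v2[1]), sum(v1 * v2))
}

#' Signed difference between two ellipse orientations
#'
#' @param pose1,pose2 Pose rows (or numbers interpreted as angles).
#' @return theta1 - theta2 wrapped to (-pi, pi].
#' @export
orientation_difference <- function(pose1, pose2) {
  t1 <- if (is.numeric(pose1)) pose1 else pose1$theta_rad
  t2 <- if (is.numeric(pose2)) pose2 else pose2$theta_rad
  wrap_angle(t1 - t2)
}

circ_arc_dist <- function(a, m) {
  d <- abs(a - m) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Circular median and variance of an angle sample
#'
#' The circular median is the sample angle minimizing the mean arc-length
#' distance to all angles (ties broken by the smallest angle in `[0, 2*pi)`);
#' the circular variance is one minus the mean resultant length, 0 for a
#' perfectly concentrated sample and 1 for a balanced one.
#'
#' @param values Angles in radians.
#' @return list with `circular_median` and `circular_variance`.
#' @export
circular_summary <- function(values) {
  if (length(values) == 0) stop("empty angle sample")
  a <- values %% (2 * pi)
  R <- Mod(mean(exp(1i * a)))
  cand <- sort(unique(a))
  cost <- vapply(cand, function(m) mean(circ_arc_dist(a, m)), numeric(1))
  med <- cand[which(cost <= min(cost) + 1e-12)][1]
  list(circular_median = med, circular_variance = 1 - R)
}

# Two-sample Watson U^2 on the pooled circular ranks, with tie weighting.
watson_u2_stat <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  a <- c(x, y) %% (2 * pi)
  g <- c(rep(1L, n1), rep(2L, n2))
  o <- order(a)
  a <- a[o]; g <- g[o]
  e1 <- cumsum(g == 1L) / n1
  e2 <- cumsum(g == 2L) / n2
  last <- !duplicated(a, fromLast = TRUE)
  d <- (e1 - e2)[last]
  tk <- diff(c(0L, which(last)))
  (n1 * n2 / N^2) * (sum(tk * d^2) - sum(tk * d)^2 / N)
}

#' Watson's two-sample U2 test for circular data
#'
#' Compares two circular distributions with Watson's U2 statistic computed
#' from the empirical distribution functions on the pooled sample; the
#' statistic is invariant under a common rotation of both samples.
#' Significance is assessed by random permutation of the pooled labels:
#' `p = (1 + #permuted U2 >= observed) / (1 + n_permutations)`.
#'
#' @param sample1,sample2 Angles in radians (each of length >= 5).
#' @param n_permutations Number of label permutations.
#' @param seed Optional RNG seed for the permutations.
#' @return list with `u2_statistic`, `p_value`, `n1`, `n2`, `n_permutations`.
#' @export
watson_u2 <- function(sample1, sample2, n_permutations = 999, seed = NULL) {
  n1 <- length(sample1); n2 <- length(sample2)
  if (n1 < 5 || n2 < 5) stop("watson_u2 needs at least 5 angles per sample")
  if (!is.null(seed)) set.seed(seed)
  obs <- watson_u2_stat(sample1, sample2)
  pooled <- c(sample1, sample2)
  N <- n1 + n2
  count <- 0L
  for (b in seq_len(n_permutations)) {
    idx <- sample.int(N, n1)
    stat <- watson_u2_stat(pooled[idx], pooled[-idx])
    if (stat >= obs - 1e-12) count <- count + 1L
  }
  list(u2_statistic = obs,
       p_value = (1 + count) / (1 + n_permutations),
       n1 = n1, n2 = n2, n_permutations = n_permutations)
}
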
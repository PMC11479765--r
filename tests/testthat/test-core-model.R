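test_that("pose tables round-trip through CSV and validate invariants", {
  arena <- arena_spec()
  set.seed(1)
  mice <- default_mice()
  poses <- do.call(rbind, lapply(mice$mouse_id, function(id)
    make_pose_df(id, cbind(runif(100, 5, 70), runif(100, 5, 70)),
                 theta = runif(100, -pi, pi))))
  b <- recording_bundle(arena, mice, poses = poses, recording_id = "recT")
  path <- tempfile(fileext = ".csv")
  write_pose_table(b, path)
  b2 <- read_pose_table(path, arena)
  expect_equal(nrow(b2$poses), 400)
  expect_equal(length(unique(b2$poses$mouse_id)), 4)
  p1 <- b$poses[order(b$poses$mouse_id, b$poses$frame), ]
  rownames(p1) <- NULL
  expect_equal(b2$poses[, pose_cols <- names(p1)], p1, tolerance = 1e-12)
})

test_that("a trajectory gap is reported with the missing frames", {
  arena <- arena_spec()
  xy <- cbind(runif(21, 5, 70), runif(21, 5, 70))
  poses <- make_pose_df("M1", xy)
  poses <- poses[poses$frame != 10, ]
  path <- tempfile(fileext = ".csv")
  write.csv(poses, path, row.names = FALSE)
  expect_error(read_pose_table(path, arena), "10")
})

test_that("an empty pose file with a header yields an empty bundle", {
  arena <- arena_spec()
  path <- tempfile(fileext = ".csv")
  b0 <- recording_bundle(arena, default_mice(),
                         poses = make_pose_df("M1", cbind(1, 1))[0, ],
                         validate = FALSE)
  write_pose_table(b0, path)
  b <- read_pose_table(path, arena)
  expect_equal(nrow(b$poses), 0)
})

test_that("event roles derive from chase and flee semantics", {
  ev <- make_event(c("chase", "flee", "walk"),
                   c("M1", "M2", "M1"), c("M2", "M1", NA),
                   c(10, 50, 5), c(40, 80, 30), c(1.2, 0.9, 2.0))
  expect_equal(ev$aggressor_id, c("M1", "M1", NA))
  expect_equal(ev$aggressed_id, c("M2", "M2", NA))
  path <- tempfile(fileext = ".csv")
  write_event_table(ev, path)
  ev2 <- read_event_table(path)        # rows come back start-sorted
  ev_sorted <- ev[order(ev$start_frame), ]
  expect_equal(ev2$label, ev_sorted$label)
  expect_equal(ev2$aggressor_id, ev_sorted$aggressor_id)
  expect_error(read_event_table({
    p <- tempfile(fileext = ".csv")
    write.csv(data.frame(label = "hop", actor_id = "M1", recipient_id = "M2",
                         start_frame = 0, end_frame = 10, confidence = 1),
              p, row.names = FALSE); p
  }), "unknown")
})

test_that("speed is displacement times fps, translation-invariant, fps-linear", {
  xy <- rbind(c(0, 0), c(1, 0), c(4, 4))
  sp <- compute_speed(xy, 30)
  expect_equal(sp, c(30, 30, 150))   # 1 cm and 3-4-5 steps at 30 fps
  expect_equal(compute_speed(xy + 100, 30), sp)
  expect_equal(compute_speed(xy, 60), 2 * sp)
  expect_equal(compute_speed(rbind(c(2, 3), c(2, 3), c(2, 3)), 30),
               c(0, 0, 0))
  expect_error(compute_speed(xy[1, , drop = FALSE], 30), "two frames")
})

test_that("exploration fraction counts visited grid bins", {
  arena <- arena_spec()
  still <- cbind(rep(10, 50), rep(10, 50))
  # 81 cm^2 bins tile the 76.2 cm square into 9 x 9 = 81 bins
  expect_equal(exploration_fraction(still, arena, 81), 100 / 81)
  # visiting every bin center gives 100 %
  centers <- expand.grid(x = (1:9 - 0.5) * 9, y = (1:9 - 0.5) * 9)
  expect_equal(exploration_fraction(as.matrix(centers), arena, 81), 100)
  expect_error(exploration_fraction(still, arena, 80^2), "exceeds")
})

test_that("exploration fraction is non-decreasing in bin area", {
  arena <- arena_spec()
  set.seed(7)
  for (rep in 1:5) {
    xy <- cbind(runif(200, 0, 76), runif(200, 0, 76))
    fr <- sapply(c(9, 36, 81), function(a) exploration_fraction(xy, arena, a))
    expect_true(all(diff(fr) >= -1e-9))
  }
})

test_that("aggression score follows the published formula and is antisymmetric", {
  ev <- make_event(rep("chase", 40), rep(c("M1", "M2"), c(30, 10)),
                   rep(c("M2", "M1"), c(30, 10)),
                   seq(0, 390, 10), seq(5, 395, 10))
  s <- aggression_summary(ev, c("M1", "M2"))
  # (count_male2 - count_male1) / total
  expect_equal(s$aggression_score, (10 - 30) / 40)
  expect_equal(s$more_aggressive_id, "M1")
  s2 <- aggression_summary(ev, c("M2", "M1"))
  expect_equal(s2$aggression_score, -s$aggression_score)
  # equal counts: score 0, chi-square p = 1
  ev_eq <- make_event(rep("chase", 20), rep(c("M1", "M2"), 10),
                      rep(c("M2", "M1"), 10), seq(0, 190, 10), seq(5, 195, 10))
  s3 <- aggression_summary(ev_eq, c("M1", "M2"))
  expect_equal(s3$aggression_score, 0)
  expect_equal(s3$chi_square_p, 1)
  # one-sided extreme: |score| = 1 and tiny p
  ev1 <- make_event(rep("chase", 216), "M1", "M2",
                    seq(0, 2150, 10), seq(5, 2155, 10))
  s4 <- aggression_summary(ev1, c("M1", "M2"))
  expect_equal(abs(s4$aggression_score), 1)
  expect_lt(s4$chi_square_p, 0.001)
  # no aggressive events: flagged undefined
  walk <- make_event("walk", "M1", NA, 0, 30)
  expect_false(aggression_summary(walk, c("M1", "M2"))$defined)
})

test_that("refinement filters enforce the per-label thresholds", {
  arena <- arena_spec()
  n <- 200
  # males side by side 5 cm apart, far from females
  pos_m1 <- cbind(seq(5, 30, length.out = n), rep(10, n))
  poses <- rbind(make_pose_df("M1", pos_m1),
                 make_pose_df("M2", cbind(pos_m1[, 1], rep(11, n))),
                 make_pose_df("F1", cbind(rep(60, n), rep(60, n))),
                 make_pose_df("F2", cbind(rep(60, n), rep(20, n))))
  mice <- default_mice()
  ev <- rbind(
    make_event("chase", "M1", "M2", 0, 6, 1.0),    # 6 frames: not > 6
    make_event("chase", "M1", "M2", 0, 40, 1.0),   # passes
    make_event("flee", "M2", "M1", 50, 80, 0.6),   # confidence not > 0.7
    make_event("flee", "M2", "M1", 50, 80, 0.9),   # passes
    make_event("walk", "M1", NA, 100, 125, 1.5),   # 25 frames, score 1.5: keep
    make_event("walk", "M1", NA, 100, 115, 1.5))   # 15 frames: drop
  out <- refine_events(ev, poses, mice, fps = 30)
  expect_equal(nrow(out), 3)
  expect_setequal(out$start_frame, c(0, 50, 100))
  rej <- attr(out, "rejections")
  expect_equal(unname(rej["chase:min_duration_frames"]), 1L)
  expect_equal(unname(rej["flee:min_confidence"]), 1L)
})

test_that("refinement output is a subset and idempotent", {
  arena <- arena_spec()
  set.seed(3)
  n <- 400
  poses <- do.call(rbind, lapply(default_mice()$mouse_id, function(id)
    make_pose_df(id, cbind(runif(n, 2, 74), runif(n, 2, 74)))))
  ev <- rbind(
    make_event(rep("chase", 5), "M1", "M2", seq(0, 200, 50), seq(0, 200, 50) + c(4, 10, 30, 60, 90),
               runif(5, 0.3, 1.5)),
    make_event(rep("walk", 4), "M2", NA, seq(250, 310, 20), seq(250, 310, 20) + c(10, 25, 30, 15),
               runif(4, 0.5, 2)))
  once <- refine_events(ev, poses, default_mice(), fps = 30)
  expect_true(all(once$start_frame %in% ev$start_frame))
  twice <- refine_events(once, poses, default_mice(), fps = 30)
  expect_equal(nrow(twice), nrow(once))
  expect_equal(twice$start_frame, once$start_frame)
})

test_that("rules that need a confidence score error when it is absent", {
  poses <- make_pose_df("M1", cbind(1:50, rep(10, 50)))
  ev <- make_event("walk", "M1", NA, 0, 30)
  ev$confidence <- NA_real_
  expect_error(refine_events(ev, poses, default_mice(), fps = 30),
               "confidence")
})
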
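trigger_fixture <- function() {
  make_event(c("chase", "flee"), c("M1", "M2"), c("M2", "M1"),
             c(100, 1000), c(200, 1100))
}

test_that("latency and duration follow the half-open frame arithmetic", {
  trig <- trigger_fixture()
  si <- rbind(make_si("M2", "F1", 235, 280),
              make_si("M1", "F2", 1180, 1220))
  sq <- extract_triggered_sequences(trig, si, fps = 30)
  expect_equal(nrow(sq), 2)
  expect_equal(sq$latency_s[1], 35 / 30)
  expect_equal(sq$duration_s[1], 1.5)
  expect_equal(sq$partner_state, c("aggressed", "aggressor"))
  # an interaction starting during the trigger keeps a negative latency
  si2 <- make_si("M2", "F1", 180, 220)
  sq2 <- extract_triggered_sequences(trig[1, ], si2, fps = 30)
  expect_equal(sq2$latency_s, -20 / 30)
})

test_that("each interaction is attributed to at most one trigger", {
  trig <- make_event(rep("chase", 3), "M1", "M2",
                     c(0, 300, 600), c(50, 350, 650))
  si <- rbind(make_si("M2", "F1", 80, 120),
              make_si("M1", "F1", 400, 430))
  sq <- extract_triggered_sequences(trig, si, fps = 30)
  expect_equal(nrow(sq), 2)
  expect_equal(anyDuplicated(sq$si_index), 0)
  expect_lte(nrow(sq), nrow(trig))
  expect_equal(attr(sq, "n_unmatched"), 1L)
  # invariance under a global frame offset
  trig2 <- trig; trig2$start_frame <- trig$start_frame + 900
  trig2$end_frame <- trig$end_frame + 900
  si_2 <- si; si_2$start_frame <- si$start_frame + 900
  si_2$end_frame <- si$end_frame + 900
  sq2 <- extract_triggered_sequences(trig2, si_2, fps = 30)
  expect_equal(sq2$latency_s, sq$latency_s)
  expect_equal(sq2$duration_s, sq$duration_s)
})

test_that("recovered pairings equal the planted pairings on a cohort", {
  cfg <- synthetic_config(duration_s = 1800, rate_aggressive_per_h = 50)
  rec <- generate_recording(cfg, seed = 2)
  b <- rec$bundle
  si <- detect_interactions(b)
  trig <- b$events[b$events$label %in% c("chase", "flee"), ]
  sq <- extract_triggered_sequences(trig, si, fps = 30)
  gt <- rec$truth$sequences
  expect_equal(nrow(sq), nrow(gt))
  mg <- merge(sq, gt, by = "trigger_index")
  expect_true(all(mg$si_start == mg$si1_start))
  expect_true(all(mg$partner_male_id == mg$si1_male))
  expect_true(all(mg$partner_state == mg$si1_state))
})

test_that("summaries report per-animal counts and medians", {
  trig <- trigger_fixture()
  si <- rbind(make_si("M2", "F1", 235, 280),
              make_si("M1", "F2", 1180, 1220))
  sq <- extract_triggered_sequences(trig, si, fps = 30)
  s <- summarize_sequences(sq)
  expect_equal(sum(s$n_sequences), 2)
  expect_equal(s$n_sequences[s$partner_state == "aggressed"], 1)
  one <- summarize_sequences(sq[1, ])
  expect_equal(one$n_sequences, 1)
})

test_that("control triggers are size-matched, reproducible, capped at supply", {
  ev <- make_event(rep("walk", 100), "M1", NA,
                   seq(0, 9900, 100), seq(30, 9930, 100))
  w1 <- control_triggers(ev, "walk", n_match = 40, seed = 5)
  w2 <- control_triggers(ev, "walk", n_match = 40, seed = 5)
  expect_equal(nrow(w1), 40)
  expect_identical(w1$start_frame, w2$start_frame)
  inv <- make_event(rep("investigate", 30), "M1", "M2",
                    seq(0, 2900, 100), seq(30, 2930, 100))
  expect_equal(nrow(control_triggers(inv, "investigate", n_match = 40)), 30)
  expect_warning(control_triggers(inv[0, ], "investigate", n_match = 5),
                 "no investigate")
})

test_that("walk-triggered sequences carry walker states and no planted bias", {
  cfg <- synthetic_config(duration_s = 7200, rate_aggressive_per_h = 40,
                          rate_walk_per_h = 80,
                          p_approach_aggressed = 0.9,
                          p_approach_aggressor = 0.1)
  cohort <- generate_cohort(cfg, 3, seed = 6, poses = FALSE)
  counts <- c(walker = 0, non_walker = 0)
  for (rec in cohort) {
    ev <- rec$bundle$events
    walks <- control_triggers(ev, "walk", n_match = 40, seed = 1)
    sq <- extract_triggered_sequences(walks, episodes_to_interactions(rec),
                                      fps = 30, kind = "walk")
    counts <- counts + table(factor(sq$partner_state,
                                    levels = c("walker", "non_walker")))
  }
  n <- sum(counts)
  expect_gt(n, 30)
  # the planted effect is aggression-specific: walker share ~ 1/2
  expect_lt(abs(counts[["walker"]] / n - 0.5), 3.5 * sqrt(0.25 / n))
})

test_that("hourly binning normalizes within hours and flags stragglers", {
  trig <- make_event(rep("chase", 4), "M1", "M2",
                     c(0, 5000, 110000, 120000), c(50, 5050, 110050, 120050))
  si <- rbind(make_si("M2", "F1", 100, 150),
              make_si("M1", "F1", 5100, 5160),
              make_si("M2", "F2", 110100, 110150),
              make_si("M2", "F1", 120100, 120150))
  sq <- extract_triggered_sequences(trig, si, fps = 30)
  hp <- hour_binned_state_proportions(sq, n_bins = 5)
  sums <- tapply(hp$proportion, hp$hour, sum)
  expect_true(all(abs(sums[!is.na(sums)] - 1) < 1e-9))
  expect_true(all(is.na(hp$proportion[hp$hour %in% c(3, 4, 5)])))
  # a sequence past the final bin lands in the last bin with a warning
  sq2 <- sq; sq2$si_start[4] <- 5 * 3600 * 30 + 10
  expect_warning(hp2 <- hour_binned_state_proportions(sq2, n_bins = 5),
                 "final bin")
  expect_equal(sum(hp2$n[hp2$hour == 5]), 1)
})

test_that("three-step typing reproduces the four type definitions", {
  trig <- make_event("chase", "M1", "M2", 100, 200)  # aggressor M1
  combos <- list(
    list(si1 = c("M2", "F1"), si2 = c("M1", "F1"), type = 1L),
    list(si1 = c("M1", "F1"), si2 = c("M2", "F1"), type = 2L),
    list(si1 = c("M2", "F1"), si2 = c("M1", "F2"), type = 3L),
    list(si1 = c("M1", "F1"), si2 = c("M2", "F2"), type = 4L))
  for (cb in combos) {
    si <- rbind(make_si(cb$si1[1], cb$si1[2], 250, 300),
                make_si(cb$si2[1], cb$si2[2], 350, 400))
    sq <- extract_triggered_sequences(trig, si, fps = 30)
    ts <- classify_three_step(sq, si, trig)
    expect_equal(ts$sequence_type, cb$type)
    expect_equal(ts$same_female, cb$si1[2] == cb$si2[2])
  }
})

test_that("the four types partition the typed sequences", {
  cfg <- synthetic_config(duration_s = 7200, rate_aggressive_per_h = 55)
  cohort <- generate_cohort(cfg, 2, seed = 14, poses = FALSE)
  total_typed <- 0L
  for (rec in cohort) {
    b <- rec$bundle
    trig <- b$events[b$events$label %in% c("chase", "flee"), ]
    si <- episodes_to_interactions(rec)
    sq <- extract_triggered_sequences(trig, si, fps = 30)
    ts <- classify_three_step(sq, si, trig)
    expect_true(all(ts$sequence_type %in% 1:4))
    expect_equal(sum(table(factor(ts$sequence_type, levels = 1:4))), nrow(ts))
    gt <- rec$truth$sequences
    mg <- merge(ts, gt[!is.na(gt$planted_type), ], by = "trigger_index")
    expect_equal(mg$sequence_type, mg$planted_type)
    total_typed <- total_typed + nrow(ts)
  }
  expect_gt(total_typed, 50)
})

test_that("phase profiles are flat for constant separation and keep endpoints", {
  arena <- arena_spec()
  n <- 800
  poses <- rbind(make_pose_df("M1", cbind(rep(10, n), rep(10, n))),
                 make_pose_df("M2", cbind(rep(10, n), rep(20, n))),
                 make_pose_df("F1", cbind(rep(20, n), rep(10, n))),
                 make_pose_df("F2", cbind(rep(60, n), rep(60, n))))
  b <- recording_bundle(arena, default_mice(), poses = poses, validate = FALSE)
  trig <- make_event("chase", "M1", "M2", 100, 160)
  si <- rbind(make_si("M2", "F1", 190, 250), make_si("M1", "F1", 300, 360))
  sq <- extract_triggered_sequences(trig, si, fps = 30)
  ts <- classify_three_step(sq, si, trig)
  pp <- phase_profiles(ts, b, trig)
  # aggressed (M2) sits 10 cm from F1's x-offset: constant sqrt(200) profile
  prof <- pp$profiles[["aggressed_female.si"]]
  expect_true(all(abs(prof$instances - sqrt(10^2 + 10^2)) < 1e-9))
  # interpolation preserves the first and last values of each instance
  agg <- pp$profiles[["aggressor_female.agg"]]
  expect_equal(unname(agg$instances[1, 1]), 10)   # M1 to F1 at trigger start
  expect_equal(unname(agg$instances[1, ncol(agg$instances)]), 10)
  expect_true(all(pp$points$distance_cm >= 0))
  expect_equal(sort(unique(pp$points$timepoint)),
               sort(c("si_start_plus_1", "end_plus_1", "end_plus_2",
                      "end_plus_3")))
  # type 1 sequences also track the male-male dyad
  expect_true("male_male.si" %in% names(pp$profiles))
})

test_that("fight attribution separates type 1 from the pooled other types", {
  trig <- make_event(c("chase", "chase"), "M1", "M2",
                     c(100, 2000), c(200, 2100))
  si <- rbind(make_si("M2", "F1", 250, 300), make_si("M1", "F1", 350, 400),
              make_si("M1", "F2", 2150, 2200), make_si("M2", "F1", 2250, 2300))
  sq <- extract_triggered_sequences(trig, si, fps = 30)
  ts <- classify_three_step(sq, si, trig)
  expect_equal(sort(ts$sequence_type), c(1L, 4L))
  fights <- make_event("fight", "M1", "M2", 2400, 2500)
  ff <- fights_following(ts, fights, trig)
  expect_equal(ff$counts$pct_with_fight[ff$counts$group == "type1"], 0)
  expect_equal(ff$counts$pct_with_fight[ff$counts$group == "other"], 100)
  # no fights at all: both proportions zero
  ff0 <- fights_following(ts, fights[0, ], trig)
  expect_true(all(ff0$counts$pct_with_fight == 0))
})

test_that("planted fight probabilities separate type 1 from other sequences", {
  cfg <- synthetic_config(duration_s = 10800, rate_aggressive_per_h = 55,
                          p_fight_after_type1 = 0.05,
                          p_fight_after_other = 0.5,
                          p_follow_same_female = 0.5,
                          p_follow_same_female_alt = 0.5)
  cohort <- generate_cohort(cfg, 3, seed = 8, poses = FALSE)
  pct <- sapply(cohort, function(rec) {
    b <- rec$bundle
    trig <- b$events[b$events$label %in% c("chase", "flee"), ]
    si <- episodes_to_interactions(rec)
    sq <- extract_triggered_sequences(trig, si, fps = 30)
    ts <- classify_three_step(sq, si, trig)
    ff <- fights_following(ts, b$events[b$events$label == "fight", ], trig)
    c(ff$counts$pct_with_fight[ff$counts$group == "type1"],
      ff$counts$pct_with_fight[ff$counts$group == "other"])
  })
  expect_true(all(pct[1, ] < pct[2, ]))
})
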
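fake_sequences <- function(n_aggr, n_aggd, recording_id = "r1") {
  data.frame(recording_id = rep(recording_id, n_aggr + n_aggd),
             partner_state = rep(c("aggressor", "aggressed"),
                                 c(n_aggr, n_aggd)),
             latency_s = runif(n_aggr + n_aggd, 0, 5),
             duration_s = runif(n_aggr + n_aggd, 0.2, 4),
             stringsAsFactors = FALSE)
}

test_that("difference index follows its formula and sign convention", {
  expect_equal(difference_index(fake_sequences(30, 70)), -0.4)
  expect_equal(difference_index(fake_sequences(25, 25)), 0)
  expect_equal(difference_index(fake_sequences(0, 40)), -1)
  expect_error(difference_index(fake_sequences(0, 0)), "no sequences")
})

test_that("subsampled index distributions are reproducible and calibrated", {
  set.seed(1)
  sq <- rbind(fake_sequences(20, 60, "r1"), fake_sequences(25, 55, "r2"))
  d1 <- subsample_index_distribution(sq, k = 50, n_iter = 200, seed = 9)
  d2 <- subsample_index_distribution(sq, k = 50, n_iter = 200, seed = 9)
  expect_identical(d1$distribution, d2$distribution)
  expect_equal(d1$frac_negative, 1)      # strongly aggressed-biased cohort
  expect_lt(d1$z, 0)
  expect_error(subsample_index_distribution(sq, k = 100), "fewer than")
  # balanced cohort: distribution centered at zero
  bal <- rbind(fake_sequences(40, 40, "r1"), fake_sequences(40, 40, "r2"))
  db <- subsample_index_distribution(bal, k = 50, n_iter = 400, seed = 2)
  expect_lt(abs(mean(db$distribution)), 3 * sd(db$distribution))
})

test_that("identity shuffling centers the null at zero and flags real effects", {
  set.seed(3)
  sym <- fake_sequences(50, 50)
  s0 <- identity_shuffle_null(sym, n_iter = 400, seed = 4)
  expect_gt(s0$p, 0.05)
  expect_lt(abs(mean(s0$null_distribution)),
            3 * sd(s0$null_distribution) / sqrt(400) * 20 + 0.05)
  eff <- fake_sequences(25, 175)
  s1 <- identity_shuffle_null(eff, n_iter = 500, seed = 4)
  expect_lt(s1$p, 0.001)
  expect_true(all(s1$observed_index < s1$null_distribution))
  # the null mean is ~0 regardless of the effect in the data
  expect_lt(abs(mean(s1$null_distribution)), 0.05)
  # recording-level variant runs and stays centered
  eff$recording_id <- rep(c("r1", "r2"), 100)
  s2 <- identity_shuffle_null(eff, n_iter = 300, seed = 1, mode = "recording")
  expect_lt(abs(mean(s2$null_distribution)), 0.2)
})

test_that("time randomization preserves durations and is reproducible", {
  ev <- make_event(rep("chase", 30), "M1", "M2",
                   seq(0, 29000, 1000), seq(0, 29000, 1000) + 60)
  r1 <- randomize_event_times(ev, 40000, seed = 6)
  r2 <- randomize_event_times(ev, 40000, seed = 6)
  expect_identical(r1$start_frame, r2$start_frame)
  expect_equal(sort(r1$end_frame - r1$start_frame),
               sort(ev$end_frame - ev$start_frame))
  expect_true(all(r1$start_frame >= 0 & r1$end_frame <= 40000))
  expect_error(randomize_event_times(make_event("chase", "M1", "M2", 0, 500),
                                     100), "exceeds")
})

test_that("state decoding finds separable structure and not random labels", {
  set.seed(8)
  # perfectly separable planted features
  sep <- data.frame(
    recording_id = "r1",
    partner_state = rep(c("aggressed", "aggressor"), each = 60),
    latency_s = c(runif(60, 0.1, 0.9), runif(60, 3, 6)),
    duration_s = c(runif(60, 0.2, 1), runif(60, 2, 4)),
    stringsAsFactors = FALSE)
  d_sep <- decode_state(sep, n_iter = 150, seed = 1)
  expect_gt(d_sep$mean, 95)
  expect_lt(d_sep$p, 0.001)
  # random labels: within 2 sd of chance
  rnd <- sep
  rnd$partner_state <- sample(rnd$partner_state)
  d_rnd <- decode_state(rnd, n_iter = 150, seed = 2)
  expect_lt(abs(d_rnd$mean - 50), 2 * d_rnd$sd)
  # size-matched on balanced data behaves like observed
  d_sm <- decode_state(sep, n_iter = 150, condition = "size_matched", seed = 3)
  expect_gt(d_sm$mean, 95)
  expect_error(decode_state(sep[c(1:8, 61:68), ]), "at least 20")
  one <- sep; one$partner_state <- "aggressed"
  expect_error(decode_state(one), "two classes")
})

test_that("state decoding keeps its type-I error on null-mode cohorts", {
  cfg <- synthetic_config(duration_s = 2400, rate_aggressive_per_h = 55,
                          null_mode = TRUE)
  rej <- 0L
  n_rep <- 200
  for (r in seq_len(n_rep)) {
    rec <- generate_recording(cfg, seed = 3000 + r, poses = FALSE)
    b <- rec$bundle
    trig <- b$events[b$events$label %in% c("chase", "flee"), ]
    sq <- extract_triggered_sequences(trig, episodes_to_interactions(rec),
                                      fps = 30)
    if (nrow(sq) < 20 || length(unique(sq$partner_state)) < 2) next
    d <- decode_state(sq, n_iter = 200, seed = r)
    if (d$p < 0.05) rej <- rej + 1L
  }
  expect_lte(rej / n_rep, 0.08)
})

test_that("multiclass decoding separates structured classes, not shuffled ones", {
  set.seed(4)
  n <- 40
  d <- data.frame(type = factor(rep(1:4, each = n)),
                  f1 = c(rnorm(n, 0), rnorm(n, 6), rnorm(n, 0), rnorm(n, 6)),
                  f2 = c(rnorm(n, 0), rnorm(n, 0), rnorm(n, 6), rnorm(n, 6)))
  run <- decode_multiclass(d, c("f1", "f2"), "type", n_iter = 60, seed = 1)
  expect_gt(run$mean, 80)
  expect_equal(run$chance, 25)
  shuf <- decode_multiclass(d, c("f1", "f2"), "type", n_iter = 60,
                            shuffle_labels = TRUE, seed = 2)
  expect_lt(abs(shuf$mean - 25), 3 * shuf$sd)
  small <- d[c(1:2, 41:80, 81:160), ]
  expect_error(decode_multiclass(small, c("f1", "f2"), "type",
                                 size_matched = TRUE), "at least 4")
})

test_that("group stats wrap the standard tests with documented edge cases", {
  x <- c(1, 2, 3, 4, 5)
  same <- group_stats(x, x, test = "wilcoxon_signed_rank")
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  w <- group_stats(x, x + 2, test = "wilcoxon_signed_rank")
  expect_lt(w$p, 0.1)
  expect_error(group_stats(x, x[1:3], test = "wilcoxon_signed_rank"),
               "equal length")
  # three groups, one shifted: significant omnibus, correct pair flagged
  set.seed(12)
  v <- c(rnorm(15), rnorm(15), rnorm(15, 3))
  g <- rep(c("a", "b", "c"), each = 15)
  kw <- group_stats(v, groups = g, test = "kruskal_wallis_dunn_sidak")
  expect_lt(kw$p, 0.01)
  ph <- kw$post_hoc
  sig <- ph[ph$p_adj < 0.05, ]
  expect_true(all(sig$group1 == "c" | sig$group2 == "c"))
  expect_false(any(sig$group1 == "a" & sig$group2 == "b"))
  # extreme chi-square
  cs <- group_stats(c(216, 0), test = "chi_square")
  expect_lt(cs$p, 0.001)
  # z wrappers
  z1 <- group_stats(rnorm(1000, 60, 5), y = 50, test = "one_sided_z")
  expect_lt(z1$p, 0.05)
  expect_equal(bonferroni_alpha(0.05, 5), 0.01)
})

test_that("the pipeline runs end to end and is reproducible", {
  cfg <- synthetic_config(duration_s = 3600, rate_aggressive_per_h = 55)
  cohort <- generate_cohort(cfg, 2, seed = 30, poses = FALSE)
  pc <- pipeline_config(out_dir = NULL, n_iter = 100, n_decoder_iter = 50,
                        seed = 7)
  r1 <- run_pipeline(cohort, pc, use_planted_interactions = TRUE)
  r2 <- run_pipeline(cohort, pc, use_planted_interactions = TRUE)
  expect_identical(r1$subsample_index$distribution,
                   r2$subsample_index$distribution)
  expect_identical(r1$decoder_observed$accuracies,
                   r2$decoder_observed$accuracies)
  expect_gt(nrow(r1$sequences), 20)
  expect_equal(sum(r1$type_counts), nrow(r1$three_step))
  out <- file.path(tempdir(), "ppl_out")
  pc2 <- pipeline_config(out_dir = out, n_iter = 50, n_decoder_iter = 30)
  run_pipeline(cohort, pc2, use_planted_interactions = TRUE)
  expect_true(file.exists(file.path(out, "sequences.csv")))
  expect_true(file.exists(file.path(out, "run_log.json")))
})
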
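# Triggered-sequence extraction, controls, three-step typing, phase
# profiles and fight association.

partner_state_labels <- function(kind) {
  switch(kind,
         aggressive = c("aggressor", "aggressed"),
         walk = c("walker", "non_walker"),
         investigate = c("investigator", "investigated"))
}

#' Extract triggered behavioral sequences
#'
#' Pairs each trigger event with the earliest male-female social interaction
#' whose start lies at or after the trigger's start and before the next
#' trigger's start, so every interaction is attributed to at most one
#' trigger (its nearest preceding one). The latency is measured from the
#' trigger's end to the interaction's start and may be negative when
#' socialization begins while the trigger is still running.
#'
#' @param triggers Trigger events, sorted by start. For aggressive triggers
#'   (chase/flee) role columns must be present; for walk triggers the walker
#'   is `actor_id`; for investigations the investigator is `actor_id`.
#' @param interactions Male-female interaction table.
#' @param fps Frames per second.
#' @param kind "aggressive", "walk" or "investigate"; controls the
#'   partner-state labels.
#' @param recording_id Recording id recorded with each sequence.
#' @return data.frame with one row per trigger that yielded a sequence:
#'   trigger and interaction frames, `latency_s`, `duration_s`,
#'   `partner_male_id`, `female_id`, `partner_state`, `hour_bin`. The count
#'   of triggers without a following interaction is in attribute
#'   `"n_unmatched"`.
#' @export
extract_triggered_sequences <- function(triggers, interactions, fps = 30,
                                        kind = "aggressive",
                                        recording_id = NULL) {
  states <- partner_state_labels(kind)
  tr <- triggers[order(triggers$start_frame), , drop = FALSE]
  si <- interactions[order(interactions$start_frame), , drop = FALSE]
  n_tr <- nrow(tr)
  empty <- data.frame(recording_id = character(0), trigger_index = integer(0),
                      trigger_label = character(0), trigger_start = integer(0),
                      trigger_end = integer(0), si_index = integer(0),
                      si_start = integer(0), si_end = integer(0),
                      latency_s = numeric(0), duration_s = numeric(0),
                      partner_male_id = character(0), female_id = character(0),
                      partner_state = character(0), hour_bin = integer(0),
                      stringsAsFactors = FALSE)
  if (n_tr == 0 || nrow(si) == 0) {
    attr(empty, "n_unmatched") <- n_tr
    return(empty)
  }
  next_start <- c(tr$start_frame[-1], Inf)
  rows <- vector("list", n_tr)
  unmatched <- 0L
  for (i in seq_len(n_tr)) {
    j <- which(si$start_frame >= tr$start_frame[i] &
               si$start_frame < next_start[i])[1]
    if (is.na(j)) { unmatched <- unmatched + 1L; next }
    partner <- si$male_id[j]
    state <- if (kind == "aggressive") {
      if (partner == tr$aggressed_id[i]) "aggressed" else "aggressor"
    } else {
      if (partner == tr$actor_id[i]) states[1] else states[2]
    }
    rows[[i]] <- data.frame(
      recording_id = if (is.null(recording_id)) {
        if (!is.null(si$recording_id)) si$recording_id[j] else "rec"
      } else recording_id,
      trigger_index = i, trigger_label = tr$label[i],
      trigger_start = tr$start_frame[i], trigger_end = tr$end_frame[i],
      si_index = j, si_start = si$start_frame[j], si_end = si$end_frame[j],
      latency_s = (si$start_frame[j] - tr$end_frame[i]) / fps,
      duration_s = (si$end_frame[j] - si$start_frame[j]) / fps,
      partner_male_id = partner, female_id = si$female_id[j],
      partner_state = state,
      hour_bin = as.integer(floor(si$start_frame[j] / fps / 3600)) + 1L,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  attr(out, "n_unmatched") <- unmatched
  out
}

#' Per-animal sequence summaries
#'
#' @param sequences Output of [extract_triggered_sequences()] (possibly
#'   pooled over recordings).
#' @return data.frame per recording x partner male: sequence count, median
#'   latency and median duration, with the partner state.
#' @export
summarize_sequences <- function(sequences) {
  if (nrow(sequences) == 0) stop("no sequences to summarise")
  key <- interaction(sequences$recording_id, sequences$partner_male_id,
                     sequences$partner_state, drop = TRUE)
  parts <- split(sequences, key)
  out <- do.call(rbind, lapply(parts, function(d) data.frame(
    recording_id = d$recording_id[1],
    partner_male_id = d$partner_male_id[1],
    partner_state = d$partner_state[1],
    n_sequences = nrow(d),
    median_latency_s = stats::median(d$latency_s),
    median_duration_s = stats::median(d$duration_s),
    stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$recording_id, out$partner_state), ]
}

#' Sample-size-matched control triggers
#'
#' Draws a random subset of nonaggressive events (walks or investigations)
#' to match the aggressive sample size. When fewer control events than
#' `n_match` exist, all are used.
#'
#' @param events Event table.
#' @param kind "walk" or "investigate".
#' @param n_match Target number of triggers.
#' @param seed RNG seed.
#' @return The selected trigger events, start-sorted.
#' @export
control_triggers <- function(events, kind = c("walk", "investigate"),
                             n_match, seed = NULL) {
  kind <- match.arg(kind)
  cand <- events[events$label == kind, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no ", kind, " events to sample from")
    return(cand)
  }
  if (!is.null(seed)) set.seed(seed)
  if (nrow(cand) > n_match)
    cand <- cand[sort(sample.int(nrow(cand), n_match)), , drop = FALSE]
  cand <- cand[order(cand$start_frame), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

#' Hourly proportions of sequences by partner state
#'
#' Bins sequences into one-hour bins by interaction start time and reports,
#' per bin, the fraction of sequences in each partner state. Sequences
#' beyond the final bin are assigned to it with a warning.
#'
#' @param sequences Sequence table.
#' @param n_bins Number of one-hour bins (5 for a five-hour recording).
#' @param fps Frames per second.
#' @return data.frame per hour x state with `n` and `proportion` (within
#'   hour; empty hours are flagged with `NA` proportion).
#' @export
hour_binned_state_proportions <- function(sequences, n_bins = 5, fps = 30) {
  bin <- as.integer(floor(sequences$si_start / fps / 3600)) + 1L
  if (any(bin > n_bins)) {
    warning(sum(bin > n_bins), " sequence(s) beyond the final bin; assigned to it")
    bin[bin > n_bins] <- n_bins
  }
  states <- sort(unique(sequences$partner_state))
  out <- expand.grid(hour = seq_len(n_bins), partner_state = states,
                     stringsAsFactors = FALSE)
  out$n <- mapply(function(h, s) sum(bin == h & sequences$partner_state == s),
                  out$hour, out$partner_state)
  tot <- stats::ave(out$n, out$hour, FUN = sum)
  out$proportion <- ifelse(tot > 0, out$n / tot, NA_real_)
  out[order(out$hour, out$partner_state), ]
}

#' Classify three-step behavioral sequences
#'
#' Extends each aggression-triggered sequence with the next male-female
#' interaction (by either male) that starts after the first one and before
#' the next aggressive trigger. Sequences whose two interactions involve
#' different males are typed 1-4 by the first interaction's partner state
#' and whether the second involves the same female:
#' type 1 = aggressed then aggressor with the same female (bait-and-switch),
#' type 2 = aggressor then aggressed, same female,
#' type 3 = aggressed then aggressor, other female,
#' type 4 = aggressor then aggressed, other female.
#' Sequences with no second interaction, or a repeat by the same male, are
#' excluded and counted.
#'
#' @param sequences Aggression-triggered sequences.
#' @param interactions Full male-female interaction table.
#' @param triggers The aggressive trigger events (start-sorted), used to
#'   bound the search window.
#' @return data.frame of typed sequences with `si2_*` columns,
#'   `sequence_type`, `same_female`; excluded counts in attribute
#'   `"n_excluded"` (no second interaction / same male).
#' @export
classify_three_step <- function(sequences, interactions, triggers) {
  si <- interactions[order(interactions$start_frame), , drop = FALSE]
  tr_starts <- sort(triggers$start_frame)
  rows <- vector("list", nrow(sequences))
  n_no_si2 <- 0L; n_same_male <- 0L
  for (i in seq_len(nrow(sequences))) {
    s <- sequences[i, ]
    nxt <- tr_starts[tr_starts > s$trigger_start][1]
    if (is.na(nxt)) nxt <- Inf
    cand <- which(si$start_frame > s$si_start & si$start_frame < nxt &
                  !(si$start_frame == s$si_start & si$male_id == s$partner_male_id))
    cand <- cand[cand != s$si_index]
    if (!length(cand)) { n_no_si2 <- n_no_si2 + 1L; next }
    j <- cand[1]
    if (si$male_id[j] == s$partner_male_id) { n_same_male <- n_same_male + 1L; next }
    same_f <- si$female_id[j] == s$female_id
    type <- if (s$partner_state == "aggressed") {
      if (same_f) 1L else 3L
    } else {
      if (same_f) 2L else 4L
    }
    s$si2_index <- j
    s$si2_start <- si$start_frame[j]
    s$si2_end <- si$end_frame[j]
    s$si2_male_id <- si$male_id[j]
    s$si2_female_id <- si$female_id[j]
    s$same_female <- same_f
    s$sequence_type <- type
    rows[[i]] <- s
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- sequences[0, ]
    out$si2_index <- integer(0); out$si2_start <- integer(0)
    out$si2_end <- integer(0); out$si2_male_id <- character(0)
    out$si2_female_id <- character(0); out$same_female <- logical(0)
    out$sequence_type <- integer(0)
  }
  rownames(out) <- NULL
  attr(out, "n_excluded") <- c(no_second_si = n_no_si2, same_male = n_same_male)
  out
}

interp_to_grid <- function(y, L) {
  n <- length(y)
  if (n == 0) return(rep(NA_real_, L))
  if (n == 1) return(rep(y, L))
  if (L == 1) return(y[1])
  stats::approx(seq(0, 1, length.out = n), y, xout = seq(0, 1, length.out = L))$y
}

#' Phase-normalized dyad distance profiles
#'
#' For each typed sequence, computes per-frame centroid distances for the
#' aggressor-female and aggressed-female dyads (and the male-male dyad for
#' type 1 sequences) across four phases: the aggressive encounter (AGG), the
#' gap between its end and the first interaction's start, the first
#' interaction (SI), and a fixed post-interaction window. Each phase's
#' series is linearly interpolated onto a common grid whose length equals
#' the longest instance of that phase, preserving endpoints; zero-length
#' phases (non-positive latency) are skipped in aggregation.
#'
#' In addition, raw (non-normalized) distances are extracted at SI start
#' + 1 s and at post-interaction times 1, 2 and 3 s after SI end.
#'
#' @param three_step Typed sequences ([classify_three_step()]).
#' @param bundle Recording bundle with poses.
#' @param triggers Aggressive triggers (for role lookup by trigger index).
#' @param post_window_s Post-interaction window (s).
#' @return list with `profiles` (per dyad, per phase: instances x grid
#'   matrix plus `median`/`iqr` rows), `points` (long data.frame of the
#'   extracted time points), `grid_lengths`.
#' @export
phase_profiles <- function(three_step, bundle, triggers, post_window_s = 5) {
  fps <- bundle$arena$fps
  pos <- position_index(bundle$poses)
  n <- nrow(pos[[1]])
  post_f <- round(post_window_s * fps)
  phases <- c("agg", "gap", "si", "post")

  dist_series <- function(id1, id2, from, to) {   # frames, half-open
    if (to <= from) return(numeric(0))
    rows <- (from + 1L):min(to, n)
    pair_distance(pos, id1, id2, rows)
  }
  dist_at <- function(id1, id2, frame) {
    r <- min(frame + 1L, n)
    pair_distance(pos, id1, id2, r)
  }

  series <- list(); points <- list()
  for (i in seq_len(nrow(three_step))) {
    s <- three_step[i, ]
    tr <- triggers[s$trigger_index, ]
    aggr <- tr$aggressor_id; aggd <- tr$aggressed_id
    fem <- s$female_id
    dyads <- list(aggressor_female = c(aggr, fem),
                  aggressed_female = c(aggd, fem))
    if (!is.null(s$sequence_type) && s$sequence_type == 1L)
      dyads$male_male <- c(aggr, aggd)
    bounds <- list(agg = c(s$trigger_start, s$trigger_end),
                   gap = c(s$trigger_end, max(s$trigger_end, s$si_start)),
                   si = c(s$si_start, s$si_end),
                   post = c(s$si_end, s$si_end + post_f))
    for (dn in names(dyads)) {
      ids <- dyads[[dn]]
      for (ph in phases) {
        key <- paste(dn, ph, sep = ".")
        series[[key]] <- c(series[[key]],
                           list(dist_series(ids[1], ids[2],
                                            bounds[[ph]][1], bounds[[ph]][2])))
      }
      tp <- c(si_start_plus_1 = s$si_start + fps,
              end_plus_1 = s$si_end + fps,
              end_plus_2 = s$si_end + 2L * fps,
              end_plus_3 = s$si_end + 3L * fps)
      points[[length(points) + 1]] <- data.frame(
        sequence = i, dyad = dn, timepoint = names(tp),
        distance_cm = vapply(tp, function(f) dist_at(ids[1], ids[2], f),
                             numeric(1)),
        sequence_type = s$sequence_type, stringsAsFactors = FALSE)
    }
  }

  grid_lengths <- sapply(phases, function(ph) {
    keys <- grep(paste0("\\.", ph, "$"), names(series), value = TRUE)
    max(c(1L, unlist(lapply(series[keys], function(lst) lengths(lst)))))
  })
  profiles <- list()
  for (key in names(series)) {
    ph <- sub("^.*\\.", "", key)
    L <- grid_lengths[[ph]]
    inst <- series[[key]]
    nonzero <- lengths(inst) > 0
    mat <- do.call(rbind, lapply(inst[nonzero], interp_to_grid, L = L))
    if (is.null(mat)) mat <- matrix(numeric(0), 0, L)
    profiles[[key]] <- list(
      instances = mat,
      median = if (nrow(mat)) apply(mat, 2, stats::median) else rep(NA_real_, L),
      iqr = if (nrow(mat)) apply(mat, 2, stats::IQR) else rep(NA_real_, L))
  }
  list(profiles = profiles,
       points = do.call(rbind, points),
       grid_lengths = grid_lengths)
}

#' Fights following three-step sequences
#'
#' Attributes a fight to a three-step sequence when the fight starts after
#' the second interaction ends and before the next aggressive trigger.
#' Reports counts and the percentage of sequences followed by at least one
#' fight, for type 1 against the pooled other types.
#'
#' @param three_step Typed sequences.
#' @param fight_events Fight events.
#' @param triggers Aggressive trigger events.
#' @param horizon_s Optional fixed attribution horizon (s) instead of the
#'   next trigger; `NULL` uses the next-trigger window.
#' @param fps Frames per second.
#' @return list with per-group `counts` data.frame (group, n_sequences,
#'   n_with_fight, pct_with_fight) and the per-sequence logical
#'   `fight_followed`.
#' @export
fights_following <- function(three_step, fight_events, triggers,
                             horizon_s = NULL, fps = 30) {
  tr_starts <- sort(triggers$start_frame)
  fs <- fight_events$start_frame
  followed <- logical(nrow(three_step))
  for (i in seq_len(nrow(three_step))) {
    s <- three_step[i, ]
    lim <- if (is.null(horizon_s)) {
      nxt <- tr_starts[tr_starts > s$trigger_start][1]
      if (is.na(nxt)) Inf else nxt
    } else s$si2_end + horizon_s * fps
    followed[i] <- any(fs >= s$si2_end & fs < lim)
  }
  grp <- ifelse(three_step$sequence_type == 1L, "type1", "other")
  counts <- do.call(rbind, lapply(c("type1", "other"), function(g) {
    idx <- grp == g
    data.frame(group = g, n_sequences = sum(idx),
               n_with_fight = sum(followed[idx]),
               pct_with_fight = if (sum(idx)) 100 * mean(followed[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, fight_followed = followed)
}
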
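# Difference-index permutation suite and randomization controls.

#' Difference index of partner states
#'
#' `(n_aggressor_partner - n_aggressed_partner) / (n_aggressor_partner +
#' n_aggressed_partner)`: an index below 0 means post-aggression
#' interactions more often involved the aggressed male.
#'
#' @param sequences Sequence table with `partner_state`, or a logical/char
#'   vector of states.
#' @return Signed index in `[-1, 1]`.
#' @export
difference_index <- function(sequences) {
  st <- if (is.data.frame(sequences)) sequences$partner_state else sequences
  n_aggr <- sum(st == "aggressor")
  n_aggd <- sum(st == "aggressed")
  tot <- n_aggr + n_aggd
  if (tot == 0) stop("difference index undefined: no sequences")
  (n_aggr - n_aggd) / tot
}

#' Subsampled difference-index distribution
#'
#' Repeatedly draws `k` sequences without replacement from every recording,
#' pools them, and computes the difference index, yielding a distribution
#' whose location is tested against zero with a two-sided z-test
#' (`z = mean / sd` over the iterations).
#'
#' @param sequences Pooled sequence table with `recording_id`.
#' @param k Sequences drawn per recording.
#' @param n_iter Iterations.
#' @param seed RNG seed.
#' @return list with `distribution`, `z`, `p`, `frac_negative`.
#' @export
subsample_index_distribution <- function(sequences, k = 50, n_iter = 1000,
                                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  by_rec <- split(sequences$partner_state, sequences$recording_id)
  short <- names(by_rec)[lengths(by_rec) < k]
  if (length(short))
    stop("recording(s) with fewer than k = ", k, " sequences: ",
         paste(short, collapse = ", "))
  dist <- vapply(seq_len(n_iter), function(it) {
    pooled <- unlist(lapply(by_rec, function(st) st[sample.int(length(st), k)]),
                     use.names = FALSE)
    difference_index(pooled)
  }, numeric(1))
  s <- stats::sd(dist)
  z <- if (s > 0) mean(dist) / s else sign(mean(dist)) * Inf
  list(distribution = dist, z = z,
       p = 2 * stats::pnorm(-abs(z)),
       frac_negative = mean(dist < 0))
}

#' Identity-shuffle null for the difference index
#'
#' Destroys the state linkage by randomly flipping each trigger's
#' aggressor/aggressed assignment (probability 1/2) while keeping behavior
#' order and durations; partner states are recomputed and the index
#' re-evaluated per iteration. The observed index is compared to the null
#' with a two-sided z-test. A recording-level variant flips all triggers of
#' a recording together.
#'
#' @param sequences Sequence table with `partner_state` (one row per
#'   trigger) and `recording_id`.
#' @param n_iter Iterations.
#' @param seed RNG seed.
#' @param mode "event" (independent per-trigger flips, the default) or
#'   "recording".
#' @return list with `observed_index`, `null_distribution`, `z`, `p`.
#' @export
identity_shuffle_null <- function(sequences, n_iter = 1000, seed = NULL,
                                  mode = c("event", "recording")) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  st <- sequences$partner_state
  obs <- difference_index(st)
  flip_states <- function(st, flip) ifelse(flip,
                                           ifelse(st == "aggressor", "aggressed", "aggressor"),
                                           st)
  null <- vapply(seq_len(n_iter), function(it) {
    flip <- if (mode == "event") {
      stats::runif(length(st)) < 0.5
    } else {
      rec_flip <- stats::runif(length(unique(sequences$recording_id))) < 0.5
      rec_flip[match(sequences$recording_id, unique(sequences$recording_id))]
    }
    difference_index(flip_states(st, flip))
  }, numeric(1))
  s <- stats::sd(null)
  z <- if (s > 0) (obs - mean(null)) / s else sign(obs - mean(null)) * Inf
  list(observed_index = obs, null_distribution = null, z = z,
       p = 2 * stats::pnorm(-abs(z)), n_iterations = n_iter)
}

#' Randomize event start times
#'
#' Redraws each event's start uniformly in `[0, recording_length -
#' duration)` while preserving its duration, label and roles. Used to build
#' the time-randomized decoder control.
#'
#' @param events Event table.
#' @param recording_length Recording length in frames.
#' @param seed RNG seed.
#' @return The events with new starts, re-sorted.
#' @export
randomize_event_times <- function(events, recording_length, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- events$end_frame - events$start_frame
  if (any(dur > recording_length))
    stop("event duration exceeds the recording length")
  new_start <- floor(stats::runif(nrow(events)) * (recording_length - dur))
  events$start_frame <- as.integer(new_start)
  events$end_frame <- as.integer(new_start + dur)
  events <- events[order(events$start_frame), , drop = FALSE]
  rownames(events) <- NULL
  events
}
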
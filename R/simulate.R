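# Multi-agent arena simulator with planted ground truth.
#
# Baseline locomotion is an Ornstein-Uhlenbeck speed process with wrapped
# heading diffusion and specular reflection at boundaries. Scripted kernels
# override the baseline for labeled behaviors (chase, flee, walk,
# investigate, fight) and for post-aggression approach episodes, which are
# the planted male-female social interactions. A state-dependent tendency
# for the aggressed male to approach a female quickly after aggression --
# and for the aggressor to then engage the same female (sequence type 1) --
# is tunable, with a null mode in which the two states share all
# parameters.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

fold <- function(p, lo, hi) {
  L <- hi - lo
  q <- (p - lo) %% (2 * L)
  lo + ifelse(q > L, 2 * L - q, q)
}

#' Configuration for the synthetic arena simulator
#'
#' Defaults emulate the study conditions: four mice (2M/2F) in a 76.2 cm
#' square arena at 30 fps, aggressive male-male bouts at ~40/h, and a
#' state-dependent approach effect calibrated to the printed medians
#' (aggressed-male latency median ~1.2 s and shorter interactions; a
#' bait-and-switch follow-up making type 1 the majority three-step type).
#'
#' @param arena [arena_spec()].
#' @param duration_s Recording length in seconds (default 5 h).
#' @param mice Group composition ([default_mice()]).
#' @param mean_speed_cm_s,speed_sd_cm_s,speed_tau_s Baseline
#'   Ornstein-Uhlenbeck speed: stationary mean and sd (cm/s) and relaxation
#'   time (s).
#' @param heading_diffusion_rad2_s Baseline heading diffusion (rad^2/s).
#' @param a_cm,b_cm Body ellipse semi-axes (cm).
#' @param rate_aggressive_per_h Aggressive (chase/flee) bouts per hour;
#'   bouts are laid out on a renewal grid whose pitch also bounds the rate
#'   so that a full triggered sequence always fits between bouts.
#' @param p_chase Probability an aggressive bout is a chase (vs flee).
#' @param p_male1_aggressor Probability the first male is the aggressor.
#' @param rate_walk_per_h,rate_investigate_per_h,rate_background_fight_per_h
#'   Rates of nonaggressive events placed between aggressive blocks.
#' @param p_approach_aggressed,p_approach_aggressor Probability that the
#'   male in each state approaches a female after an aggressive bout.
#' @param latency_median_s,latency_sdlog Log-normal post-aggression approach
#'   latency per state (named `aggressed`, `aggressor`).
#' @param si_duration_median_s,si_duration_sdlog Log-normal interaction
#'   duration per state.
#' @param p_followup Probability the other male engages a female after the
#'   first interaction when he did not approach independently.
#' @param p_follow_same_female Probability the follow-up targets the same
#'   female when the first interaction involved the aggressed male.
#' @param p_follow_same_female_alt Same, when it involved the aggressor.
#' @param p_fight_after_type1,p_fight_after_other Probability a fight
#'   follows a completed three-step sequence, by type.
#' @param noise_free Confine baseline movement to sex-specific regions and
#'   freeze the target female during approaches, so the planted episodes
#'   are the only male-female contacts; required for exact planted-event
#'   recovery.
#' @param null_mode Equalize all state-dependent parameters (approach
#'   probabilities, latency and duration distributions, fight
#'   probabilities) to their means.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(arena = arena_spec(), duration_s = 18000,
                             mice = default_mice(),
                             mean_speed_cm_s = 6, speed_sd_cm_s = 2,
                             speed_tau_s = 1, heading_diffusion_rad2_s = 1.5,
                             a_cm = 2, b_cm = 1.2,
                             rate_aggressive_per_h = 40, p_chase = 0.75,
                             p_male1_aggressor = 0.7,
                             rate_walk_per_h = 60, rate_investigate_per_h = 20,
                             rate_background_fight_per_h = 2,
                             p_approach_aggressed = 0.47,
                             p_approach_aggressor = 0.45,
                             latency_median_s = c(aggressed = 1.2, aggressor = 4),
                             latency_sdlog = 0.8,
                             si_duration_median_s = c(aggressed = 1.5, aggressor = 3),
                             si_duration_sdlog = 0.5,
                             p_followup = 0.9,
                             p_follow_same_female = 0.85,
                             p_follow_same_female_alt = 0.55,
                             p_fight_after_type1 = 0.05,
                             p_fight_after_other = 0.30,
                             noise_free = TRUE, null_mode = FALSE) {
  cfg <- as.list(environment())
  probs <- c(p_chase, p_male1_aggressor, p_approach_aggressed,
             p_approach_aggressor, p_followup, p_follow_same_female,
             p_follow_same_female_alt, p_fight_after_type1, p_fight_after_other)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  rates <- c(rate_aggressive_per_h, rate_walk_per_h, rate_investigate_per_h,
             rate_background_fight_per_h)
  if (any(rates < 0)) stop("rates must be non-negative")
  if (duration_s <= 0) stop("duration must be positive")
  if (null_mode) {
    pm <- mean(c(p_approach_aggressed, p_approach_aggressor))
    cfg$p_approach_aggressed <- cfg$p_approach_aggressor <- pm
    lm <- exp(mean(log(latency_median_s)))
    cfg$latency_median_s <- c(aggressed = lm, aggressor = lm)
    dm <- exp(mean(log(si_duration_median_s)))
    cfg$si_duration_median_s <- c(aggressed = dm, aggressor = dm)
    pf <- mean(c(p_fight_after_type1, p_fight_after_other))
    cfg$p_fight_after_type1 <- cfg$p_fight_after_other <- pf
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# ---------------------------------------------------------------------------
# Event schedule.
#
# Aggressive blocks sit on a renewal grid whose pitch is bounded below by
# the worst-case span of a full block (bout + latency + two interactions +
# fight + buffer), so blocks never overlap and the trigger schedule depends
# only on the rate and one jitter draw per block -- not on the
# state-dependent parameters. Each block consumes a fixed number of random
# draws so that effect-mode and null-mode runs with the same seed share the
# same aggressive-event schedule.

BLOCK_SPAN_S <- 62

draw_block <- function(cfg, ts_f, fps) {
  u <- stats::runif(9); z <- stats::rnorm(6)
  males <- male_ids_of(cfg$mice); females <- female_ids_of(cfg$mice)
  label <- if (u[1] < cfg$p_chase) "chase" else "flee"
  aggressor <- if (u[2] < cfg$p_male1_aggressor) males[1] else males[2]
  aggressed <- setdiff(males, aggressor)
  dur_f <- round(clamp(exp(log(2) + 0.4 * z[1]), 0.4, 8) * fps)
  te_f <- ts_f + dur_f
  lat <- clamp(exp(log(cfg$latency_median_s) +
                   cfg$latency_sdlog * z[2:3]), 0.3, 12)    # aggressed, aggressor
  sdur <- clamp(exp(log(cfg$si_duration_median_s) +
                    cfg$si_duration_sdlog * z[4:5]), 0.3, 10)
  fire <- c(aggressed = u[3] < cfg$p_approach_aggressed,
            aggressor = u[4] < cfg$p_approach_aggressor)
  b <- list(label = label, aggressor = aggressor, aggressed = aggressed,
            ts = ts_f, te = te_f, si1 = NULL, si2 = NULL, fight = NULL,
            type = NA_integer_)
  if (!any(fire)) { b$end <- te_f + round(6 * fps); return(b) }
  state1 <- if (fire["aggressed"] && (!fire["aggressor"] ||
                                      lat["aggressed"] <= lat["aggressor"]))
    "aggressed" else "aggressor"
  m1 <- if (state1 == "aggressed") aggressed else aggressor
  f1 <- females[1 + (u[5] < 0.5)]
  s1 <- te_f + round(lat[state1] * fps)
  e1 <- s1 + round(sdur[state1] * fps)
  b$si1 <- list(male = m1, female = f1, state = state1, s = s1, e = e1)
  has2 <- all(fire) || u[6] < cfg$p_followup
  last_end <- e1
  if (has2) {
    state2 <- setdiff(c("aggressed", "aggressor"), state1)
    m2 <- setdiff(c(aggressed, aggressor), m1)
    p_same <- if (state1 == "aggressed") cfg$p_follow_same_female
              else cfg$p_follow_same_female_alt
    f2 <- if (u[7] < p_same) f1 else setdiff(females, f1)
    gap2 <- clamp(exp(log(1) + 0.4 * z[6]), 0.3, 4)
    s2 <- e1 + round(gap2 * fps)
    e2 <- s2 + round(sdur[state2] * fps)
    b$si2 <- list(male = m2, female = f2, state = state2, s = s2, e = e2)
    b$type <- if (state1 == "aggressed") { if (f2 == f1) 1L else 3L
              } else { if (f2 == f1) 2L else 4L }
    p_fight <- if (b$type == 1L) cfg$p_fight_after_type1 else cfg$p_fight_after_other
    if (u[8] < p_fight) {
      fs <- e2 + round((4.5 + u[9]) * fps)
      fdur <- round(clamp(exp(log(2) + 0.3 * z[6]), 1.2, 5) * fps)
      b$fight <- list(s = fs, e = fs + fdur)
      last_end <- fs + fdur
    } else last_end <- e2
  }
  b$end <- last_end + round(6 * fps)
  b
}

build_schedule <- function(cfg) {
  fps <- cfg$arena$fps
  N <- round(cfg$duration_s * fps)
  warm <- round(15 * fps)
  blocks <- list()
  if (cfg$rate_aggressive_per_h > 0) {
    pitch_s <- max(3600 / cfg$rate_aggressive_per_h, BLOCK_SPAN_S + 4)
    closing <- round(3 * fps)
    t0 <- warm + closing
    i <- 0L
    repeat {
      jit <- stats::runif(1) * min(8, pitch_s - BLOCK_SPAN_S - 2)
      ts <- t0 + round((i * pitch_s + jit) * fps)
      if (ts + round(BLOCK_SPAN_S * fps) > N - round(5 * fps)) break
      blocks[[length(blocks) + 1]] <- draw_block(cfg, ts, fps)
      i <- i + 1L
    }
  }
  # free intervals between blocks host walks, investigations, rare fights
  gap_events <- list()
  total_rate <- cfg$rate_walk_per_h + cfg$rate_investigate_per_h +
    cfg$rate_background_fight_per_h
  if (total_rate > 0) {
    males <- male_ids_of(cfg$mice)
    bounds <- c(warm, unlist(lapply(blocks, function(b) c(b$ts - round(3 * fps), b$end))),
                N - round(3 * fps))
    starts <- bounds[seq(1, length(bounds), 2)]
    ends <- bounds[seq(2, length(bounds), 2)]
    rate_f <- total_rate / 3600 / fps
    pr <- c(cfg$rate_walk_per_h, cfg$rate_investigate_per_h,
            cfg$rate_background_fight_per_h) / total_rate
    for (k in seq_along(starts)) {
      pos <- starts[k]
      repeat {
        pos <- pos + round(stats::rexp(1, rate_f)) + round(2.5 * fps)
        kind <- sample(c("walk", "investigate", "fight"), 1, prob = pr)
        dur <- round(clamp(stats::rlnorm(1, log(switch(kind, walk = 1.5,
                                                       investigate = 2,
                                                       fight = 2)), 0.45),
                           if (kind == "fight") 1.2 else 0.8, 6) * fps)
        if (pos + dur > ends[k] - fps) break
        actor <- sample(males, 1)
        gap_events[[length(gap_events) + 1]] <- list(
          kind = kind, actor = actor,
          recipient = if (kind == "walk") NA_character_ else setdiff(males, actor),
          s = pos, e = pos + dur)
        pos <- pos + dur + round(0.5 * fps)
      }
    }
  }
  list(blocks = blocks, gap_events = gap_events, n_frames = N)
}

# ---------------------------------------------------------------------------
# Pose synthesis.

sim_regions <- function(cfg) {
  W <- cfg$arena$width_cm; H <- cfg$arena$height_cm
  if (cfg$arena$shape == "circle") {
    # use the inscribed square as the folding box
    r <- cfg$arena$diameter_cm / 2
    s <- r / sqrt(2)
    base <- list(x = c(r - s + 0.5, r + s - 0.5), y = c(r - s + 0.5, r + s - 0.5))
    W <- base$x[2] - base$x[1] + 1; H <- base$y[2] - base$y[1] + 1
  } else {
    base <- list(x = c(1, W - 1), y = c(1, H - 1))
  }
  mice <- cfg$mice
  regions <- stats::setNames(rep(list(base), nrow(mice)), mice$mouse_id)
  if (cfg$noise_free) {
    males <- male_ids_of(mice); females <- female_ids_of(mice)
    xm <- base$x; ym <- base$y
    mid_x <- (xm[1] + xm[2]) / 2; mid_y <- (ym[1] + ym[2]) / 2
    male_box <- list(x = c(xm[1], mid_x - 4), y = ym)
    f_upper <- list(x = c(mid_x + 10, xm[2]), y = c(mid_y + 8, ym[2]))
    f_lower <- list(x = c(mid_x + 10, xm[2]), y = c(ym[1], mid_y - 8))
    for (m in males) regions[[m]] <- male_box
    regions[[females[1]]] <- f_upper
    if (length(females) > 1) regions[[females[2]]] <- f_lower
  }
  regions
}

region_center <- function(b) c(mean(b$x), mean(b$y))

leg_path <- function(p0, waypts, n) {
  pts <- rbind(p0, waypts)
  seg <- diff(pts)
  L <- sqrt(rowSums(seg^2))
  tot <- sum(L)
  if (tot < 1e-9 || n < 1)
    return(matrix(rep(p0, each = max(n, 1)), ncol = 2))
  s_t <- tot * seq_len(n) / n
  cum <- c(0, cumsum(L))
  idx <- pmin(findInterval(s_t, cum, rightmost.closed = TRUE), length(L))
  frac <- (s_t - cum[idx]) / L[idx]
  pts[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
}

unit_vec <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(1, 0) else v / n
}

new_sim_state <- function(cfg, regions) {
  ids <- cfg$mice$mouse_id
  N <- round(cfg$duration_s * cfg$arena$fps)
  P <- lapply(ids, function(id) matrix(NA_real_, N, 2))
  names(P) <- ids
  st <- lapply(ids, function(id) {
    b <- regions[[id]]
    list(pos = c(stats::runif(1, b$x[1], b$x[2]),
                 stats::runif(1, b$y[1], b$y[2])),
         vdev = 0, hraw = stats::runif(1, -pi, pi))
  })
  names(st) <- ids
  env <- new.env()
  env$P <- P; env$st <- st
  env$filled <- stats::setNames(rep(0L, length(ids)), ids)
  env$N <- N; env$cfg <- cfg; env$regions <- regions
  env$fps <- cfg$arena$fps
  env
}

put_rows <- function(env, id, xy) {
  n <- nrow(xy)
  if (n == 0) return(invisible())
  r0 <- env$filled[id]
  if (r0 + n > env$N) {                       # never write past the recording
    n <- env$N - r0
    if (n <= 0) return(invisible())
    xy <- xy[seq_len(n), , drop = FALSE]
  }
  env$P[[id]][(r0 + 1):(r0 + n), ] <- xy
  env$filled[id] <- r0 + n
  env$st[[id]]$pos <- xy[n, ]
  if (n >= 2) {
    d <- xy[n, ] - xy[n - 1, ]
    if (sum(d^2) > 1e-12) env$st[[id]]$hraw <- atan2(d[2], d[1])
  }
  invisible()
}

baseline_piece <- function(env, id, n, speed = NULL, hdiff = NULL, h0 = NULL) {
  cfg <- env$cfg; fps <- env$fps
  s <- env$st[[id]]; b <- env$regions[[id]]
  if (is.null(speed)) {
    phi <- exp(-1 / (cfg$speed_tau_s * fps))
    sig <- cfg$speed_sd_cm_s * sqrt(1 - phi^2)
    dev <- as.numeric(stats::filter(stats::rnorm(n, 0, sig), phi,
                                    "recursive", init = s$vdev))
    v <- pmax(0, cfg$mean_speed_cm_s + dev)
    env$st[[id]]$vdev <- dev[n]
  } else {
    v <- rep(speed, n)
  }
  hd <- if (is.null(hdiff)) cfg$heading_diffusion_rad2_s else hdiff
  h <- (if (is.null(h0)) s$hraw else h0) +
    cumsum(stats::rnorm(n, 0, sqrt(hd / fps)))
  env$st[[id]]$hraw <- h[n]
  x <- fold(s$pos[1] + cumsum(v / fps * cos(h)), b$x[1], b$x[2])
  y <- fold(s$pos[2] + cumsum(v / fps * sin(h)), b$y[1], b$y[2])
  cbind(x, y)
}

adv <- function(env, id, to_row) {
  n <- to_row - env$filled[id]
  if (n > 0) put_rows(env, id, baseline_piece(env, id, n))
  invisible()
}

scripted_leg <- function(env, id, to_row, waypts) {
  n <- to_row - env$filled[id]
  if (n > 0)
    put_rows(env, id, leg_path(env$st[[id]]$pos, waypts, n))
  invisible()
}

scripted_hold <- function(env, id, to_row, point) {
  n <- to_row - env$filled[id]
  if (n > 0)
    put_rows(env, id, matrix(rep(point, each = n), ncol = 2))
  invisible()
}

clamp_box <- function(xy, b) {
  cbind(clamp(xy[, 1], b$x[1], b$x[2]), clamp(xy[, 2], b$y[1], b$y[2]))
}

clamp_point <- function(p, b) {
  c(clamp(p[1], b$x[1], b$x[2]), clamp(p[2], b$y[1], b$y[2]))
}

script_bout <- function(env, b) {
  fps <- env$fps; a <- env$cfg$a_cm
  aggr <- b$aggressor; aggd <- b$aggressed
  box_d <- env$regions[[aggd]]; box_r <- env$regions[[aggr]]
  if (b$label == "chase") {
    adv(env, aggd, b$ts)
    run <- baseline_piece(env, aggd, b$te - b$ts, speed = 20, hdiff = 0.3)
    gap <- stats::runif(1, 0.35, 0.8) * 4 * a
    start_row <- env$filled[aggd]             # row of the pre-run position
    u0 <- unit_vec(run[1, ] - env$P[[aggd]][start_row, ])
    c0 <- max(env$filled[aggr], b$ts - round(2.5 * fps))
    adv(env, aggr, c0)
    scripted_leg(env, aggr, b$ts,
                 matrix(clamp_point(env$P[[aggd]][start_row, ] - gap * u0,
                                    box_r), ncol = 2))
    put_rows(env, aggd, run)
    steps <- rbind(u0, apply(diff(run), 1, unit_vec) |> t())
    follow <- clamp_box(run - gap * steps, box_r)
    put_rows(env, aggr, follow)
  } else {
    adv(env, aggr, b$ts)
    p_r <- env$st[[aggr]]$pos
    c0 <- max(env$filled[aggd], b$ts - round(2.5 * fps))
    adv(env, aggd, c0)
    appr <- clamp_point(p_r + 6 * unit_vec(env$st[[aggd]]$pos - p_r), box_d)
    scripted_leg(env, aggd, b$ts, matrix(appr, ncol = 2))
    h0 <- atan2(env$st[[aggd]]$pos[2] - p_r[2], env$st[[aggd]]$pos[1] - p_r[1])
    scripted_hold(env, aggr, b$te, p_r)
    put_rows(env, aggd,
             baseline_piece(env, aggd, b$te - b$ts, speed = 22, hdiff = 0.2,
                            h0 = h0))
  }
}

# Approach + contact + return for one planted interaction. Returns realized
# frame anchors.
script_si <- function(env, si) {
  fps <- env$fps; cfg <- env$cfg
  m <- si$male; f <- si$female
  v_app <- 18; v_max <- 25
  mbox <- env$regions[[m]]; fbox <- env$regions[[f]]
  dur <- si$e - si$s
  dec <- max(env$filled[m], env$filled[f], si$s - round(6 * fps))
  adv(env, m, dec); adv(env, f, dec)
  use_corridor <- cfg$noise_free
  route <- function(pm, pf) {
    if (use_corridor) {
      wp <- c((mbox$x[2] + fbox$x[1]) / 2,
              clamp(region_center(fbox)[2], mbox$y[1], mbox$y[2]))
      contact <- pf + 2 * unit_vec(wp - pf)
      list(waypts = rbind(wp, contact), contact = contact,
           len = sqrt(sum((wp - pm)^2)) + sqrt(sum((contact - wp)^2)))
    } else {
      contact <- pf + 2 * unit_vec(pm - pf)
      list(waypts = matrix(contact, ncol = 2), contact = contact,
           len = sqrt(sum((contact - pm)^2)))
    }
  }
  r0 <- route(env$st[[m]]$pos, env$st[[f]]$pos)
  fa <- max(dec, si$s - max(1L, ceiling(r0$len / v_app * fps)))
  adv(env, m, fa); adv(env, f, fa)
  pm <- env$st[[m]]$pos; pf <- env$st[[f]]$pos
  r <- route(pm, pf)
  arrive <- max(si$s, fa + max(1L, ceiling(r$len / v_max * fps)))
  e_real <- arrive + dur
  # the female pauses for the episode and until the male has retreated out
  # of social-ellipse reach, so the bout ends in a single crossing
  scripted_hold(env, f, e_real + round(0.8 * fps), pf)
  scripted_leg(env, m, arrive, r$waypts)
  scripted_hold(env, m, e_real, r$contact)
  # return to the male's home range: first retreat straight backward along
  # the contact bearing so the overlap ends in a single crossing (a turning
  # departure lets the ellipse overlap flicker back on), then route home
  retreat <- clamp_point(pf + 13 * unit_vec(r$contact - pf),
                         list(x = c(min(mbox$x[1], fbox$x[1]),
                                    max(mbox$x[2], fbox$x[2])),
                              y = c(min(mbox$y[1], fbox$y[1]),
                                    max(mbox$y[2], fbox$y[2]))))
  back <- if (use_corridor) {
    rbind(retreat,
          c((mbox$x[2] + fbox$x[1]) / 2,
            clamp(pf[2], mbox$y[1], mbox$y[2])),
          c(mbox$x[2] - 4, clamp(pf[2], mbox$y[1] + 4, mbox$y[2] - 4)))
  } else {
    rbind(retreat,
          clamp_point(r$contact + 15 * unit_vec(pm - pf), mbox))
  }
  ret_len <- sum(sqrt(rowSums(diff(rbind(r$contact, back))^2)))
  ret_end <- e_real + max(1L, ceiling(ret_len / v_app * fps))
  scripted_leg(env, m, ret_end, back)
  list(male = m, female = f, state = si$state, fa = fa, s = arrive,
       e = e_real, ret_end = ret_end)
}

script_fight <- function(env, mA, mB, fs_sched, dur) {
  fps <- env$fps
  fs <- max(fs_sched, env$filled[mA] + 1L, env$filled[mB] + round(0.3 * fps))
  adv(env, mA, fs)
  pA <- env$st[[mA]]$pos
  c0 <- max(env$filled[mB], fs - round(2.5 * fps))
  adv(env, mB, c0)
  scripted_leg(env, mB, fs,
               matrix(clamp_point(pA + 2 * unit_vec(env$st[[mB]]$pos - pA),
                                  env$regions[[mB]]), ncol = 2))
  n <- dur
  box <- env$regions[[mA]]
  small <- list(x = clamp(c(pA[1] - 8, pA[1] + 8), box$x[1], box$x[2]),
                y = clamp(c(pA[2] - 8, pA[2] + 8), box$y[1], box$y[2]))
  h <- stats::runif(1, -pi, pi) + cumsum(stats::rnorm(n, 0, sqrt(2 / fps)))
  wx <- fold(pA[1] + cumsum(12 / fps * cos(h)), small$x[1], small$x[2])
  wy <- fold(pA[2] + cumsum(12 / fps * sin(h)), small$y[1], small$y[2])
  ang <- 2 * pi * seq_len(n) / max(n, 1)
  off <- cbind(1.2 * cos(ang), 1.2 * sin(ang))
  put_rows(env, mA, clamp_box(cbind(wx, wy) + off, box))
  put_rows(env, mB, clamp_box(cbind(wx, wy) - off, box))
  c(fs, fs + n)
}

script_investigate <- function(env, actor, recipient, s_sched, dur) {
  fps <- env$fps
  s <- max(s_sched, env$filled[recipient] + 1L,
           env$filled[actor] + round(0.3 * fps))
  adv(env, recipient, s)
  pA <- env$st[[recipient]]$pos
  c0 <- max(env$filled[actor], s - round(2.5 * fps))
  adv(env, actor, c0)
  contact <- clamp_point(pA + 2.2 * unit_vec(env$st[[actor]]$pos - pA),
                         env$regions[[actor]])
  scripted_leg(env, actor, s, matrix(contact, ncol = 2))
  scripted_hold(env, recipient, s + dur, pA)
  scripted_hold(env, actor, s + dur, contact)
  c(s, s + dur)
}

synthesize_poses <- function(cfg, sch) {
  regions <- sim_regions(cfg)
  env <- new_sim_state(cfg, regions)
  fps <- env$fps
  items <- c(lapply(seq_along(sch$blocks), function(i)
               list(kind = "block", at = sch$blocks[[i]]$ts, idx = i)),
             lapply(seq_along(sch$gap_events), function(i)
               list(kind = "gap", at = sch$gap_events[[i]]$s, idx = i)))
  items <- items[order(vapply(items, `[[`, numeric(1), "at"))]
  episodes <- list(); fights <- list(); invest <- list()
  for (it in items) {
    if (it$kind == "block") {
      b <- sch$blocks[[it$idx]]
      script_bout(env, b)
      if (!is.null(b$si1)) {
        ep <- script_si(env, b$si1)
        ep$trigger <- it$idx; ep$rank <- 1L
        episodes[[length(episodes) + 1]] <- ep
        if (!is.null(b$si2)) {
          si2 <- b$si2
          # keep the scheduled gap after the realized end of the first episode
          shift <- ep$e - b$si1$e
          si2$s <- si2$s + shift; si2$e <- si2$e + shift
          ep2 <- script_si(env, si2)
          ep2$trigger <- it$idx; ep2$rank <- 2L
          episodes[[length(episodes) + 1]] <- ep2
          if (!is.null(b$fight)) {
            fr <- script_fight(env, b$aggressor, b$aggressed,
                               b$fight$s + (ep2$e - si2$e) + (si2$s - b$si2$s),
                               b$fight$e - b$fight$s)
            fights[[length(fights) + 1]] <- list(s = fr[1], e = fr[2],
                                                 trigger = it$idx)
          }
        }
      }
    } else {
      g <- sch$gap_events[[it$idx]]
      if (g$kind == "investigate") {
        r <- script_investigate(env, g$actor, g$recipient, g$s, g$e - g$s)
        invest[[length(invest) + 1]] <- list(actor = g$actor,
                                             recipient = g$recipient,
                                             s = r[1], e = r[2])
      } else if (g$kind == "fight") {
        r <- script_fight(env, g$actor, g$recipient, g$s, g$e - g$s)
        fights[[length(fights) + 1]] <- list(s = r[1], e = r[2], trigger = NA)
      }
      # walks ride on the baseline; the label needs no kinematic override
    }
  }
  for (id in names(env$P)) adv(env, id, env$N)
  list(env = env, episodes = episodes, fights = fights, invest = invest)
}

# Headings point along the direction of travel; frames without measurable
# displacement carry the previous heading forward (mice move head-first).
heading_from_displacement <- function(xy) {
  n <- nrow(xy)
  d <- diff(xy)
  moved <- rowSums(d^2) > 1e-12
  th <- atan2(d[, 2], d[, 1])
  # theta[i] (i >= 2) = angle of the last moving step at or before i-1
  last_idx <- cummax(ifelse(moved, seq_len(n - 1), 0L))
  theta <- numeric(n)
  theta[1] <- 0
  has <- last_idx > 0L
  theta[-1][has] <- th[last_idx[has]]
  if (any(!has) || !moved[1]) {
    first_mov <- which(moved)[1]
    seed <- if (is.na(first_mov)) 0 else th[first_mov]
    theta[c(TRUE, !has)] <- seed
  } else theta[1] <- th[1]
  theta
}

poses_from_env <- function(env, recording_id) {
  cfg <- env$cfg
  out <- lapply(names(env$P), function(id) {
    xy <- env$P[[id]]
    theta <- heading_from_displacement(xy)
    data.frame(recording_id = recording_id, mouse_id = id,
               frame = 0:(nrow(xy) - 1), x_cm = xy[, 1], y_cm = xy[, 2],
               theta_rad = theta, a_cm = cfg$a_cm, b_cm = cfg$b_cm,
               nose_x_cm = xy[, 1] + cfg$a_cm * cos(theta),
               nose_y_cm = xy[, 2] + cfg$a_cm * sin(theta),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Refine a planted episode to the frames where the social ellipses actually
# overlap -- evaluated on the emitted pose table itself, so the planted
# interval is exactly what the detector sees.
realize_episode <- function(pose_mats, cfg, N, ep, extension_cm = 3,
                            min_frames = 6) {
  w0 <- max(ep$fa, 1L)
  w1 <- min(ep$ret_end + 15L, N)
  rows <- w0:w1
  pm <- pose_mats[[ep$male]]
  pf <- pose_mats[[ep$female]]
  A <- cfg$a_cm + extension_cm
  nr <- length(rows)
  flag <- overlap_frames(pm[rows, 1], pm[rows, 2], pm[rows, 3],
                         rep(A, nr), rep(cfg$b_cm, nr),
                         pf[rows, 1], pf[rows, 2], pf[rows, 3],
                         rep(A, nr), rep(cfg$b_cm, nr))
  runs <- runs_from_logical(flag, min_frames)
  if (nrow(runs) == 0) return(c(ep$s, ep$e))  # fallback to the scripted window
  # choose the run containing (or nearest to) the scripted contact frame
  mid <- ep$s - w0 + 1L
  sel <- which(runs[, "start"] <= mid & runs[, "end"] >= mid)
  if (!length(sel)) sel <- which.min(abs(runs[, "start"] - mid))
  r <- runs[sel[1], ]
  c(w0 + r["start"] - 2L, w0 + r["end"] - 1L)   # 0-based half-open frames
}

conf_draw <- function(label) {
  switch(label,
         chase = stats::runif(1, 0.8, 2.5),
         flee = stats::runif(1, 0.9, 2.5),
         walk = stats::runif(1, 1.2, 3),
         investigate = stats::runif(1, 0.2, 1),
         fight = stats::runif(1, 1.8, 4))
}

#' Generate a synthetic arena recording with planted ground truth
#'
#' Builds the event schedule, optionally synthesizes the pose trajectories,
#' and returns both the recording bundle (as a perfect classifier would
#' label it) and the planted ground truth: the approach episodes with their
#' realized interaction frames, the planted initiator (the approaching
#' male), and the planted three-step sequence types.
#'
#' @param config [synthetic_config()].
#' @param seed RNG seed (determinism: identical seeds give identical
#'   recordings).
#' @param recording_id Identifier stored in the tables.
#' @param poses Synthesize trajectories (`TRUE`) or stop at the schedule
#'   level (`FALSE`; bundle has `poses = NULL` and episodes carry their
#'   scheduled frames), which is considerably faster for statistical
#'   replicate studies.
#' @return list with `bundle` (a `recording_bundle`, plus `n_frames`) and
#'   `truth` (list: `episodes`, `sequences`, `fights` data.frames).
#' @export
generate_recording <- function(config, seed = 1, recording_id = "rec1",
                               poses = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(seed)
  fps <- config$arena$fps
  sch <- build_schedule(config)
  syn <- if (poses) synthesize_poses(config, sch) else NULL
  pose_df <- if (poses) poses_from_env(syn$env, recording_id) else NULL

  # planted episodes ---------------------------------------------------
  if (poses) {
    pose_mats <- lapply(split(pose_df[, c("x_cm", "y_cm", "theta_rad")],
                              pose_df$mouse_id), as.matrix)
    ep_rows <- lapply(syn$episodes, function(ep) {
      fr <- realize_episode(pose_mats, config, sch$n_frames, ep)
      data.frame(trigger_index = ep$trigger, rank = ep$rank,
                 male_id = ep$male, female_id = ep$female,
                 partner_state = ep$state, start_frame = fr[1],
                 end_frame = fr[2], initiator = "male",
                 stringsAsFactors = FALSE)
    })
  } else {
    ep_rows <- list()
    for (i in seq_along(sch$blocks)) {
      b <- sch$blocks[[i]]
      for (rk in 1:2) {
        si <- if (rk == 1) b$si1 else b$si2
        if (is.null(si)) next
        ep_rows[[length(ep_rows) + 1]] <- data.frame(
          trigger_index = i, rank = rk, male_id = si$male,
          female_id = si$female, partner_state = si$state,
          start_frame = si$s, end_frame = si$e, initiator = "male",
          stringsAsFactors = FALSE)
      }
    }
  }
  episodes <- if (length(ep_rows)) do.call(rbind, ep_rows) else
    data.frame(trigger_index = integer(0), rank = integer(0),
               male_id = character(0), female_id = character(0),
               partner_state = character(0), start_frame = integer(0),
               end_frame = integer(0), initiator = character(0))

  # events table --------------------------------------------------------
  ev_rows <- list()
  for (i in seq_along(sch$blocks)) {
    b <- sch$blocks[[i]]
    if (b$label == "chase") {
      actor <- b$aggressor; recip <- b$aggressed
    } else { actor <- b$aggressed; recip <- b$aggressor }
    ev_rows[[length(ev_rows) + 1]] <- data.frame(
      label = b$label, actor_id = actor, recipient_id = recip,
      start_frame = b$ts, end_frame = b$te, confidence = conf_draw(b$label),
      stringsAsFactors = FALSE)
  }
  if (poses) {
    for (fx in syn$fights)
      ev_rows[[length(ev_rows) + 1]] <- data.frame(
        label = "fight", actor_id = male_ids_of(config$mice)[1],
        recipient_id = male_ids_of(config$mice)[2],
        start_frame = fx$s, end_frame = fx$e, confidence = conf_draw("fight"),
        stringsAsFactors = FALSE)
    for (iv in syn$invest)
      ev_rows[[length(ev_rows) + 1]] <- data.frame(
        label = "investigate", actor_id = iv$actor, recipient_id = iv$recipient,
        start_frame = iv$s, end_frame = iv$e,
        confidence = conf_draw("investigate"), stringsAsFactors = FALSE)
    for (g in sch$gap_events)
      if (g$kind == "walk")
        ev_rows[[length(ev_rows) + 1]] <- data.frame(
          label = "walk", actor_id = g$actor, recipient_id = NA_character_,
          start_frame = g$s, end_frame = g$e, confidence = conf_draw("walk"),
          stringsAsFactors = FALSE)
  } else {
    for (i in seq_along(sch$blocks)) {
      b <- sch$blocks[[i]]
      if (!is.null(b$fight))
        ev_rows[[length(ev_rows) + 1]] <- data.frame(
          label = "fight", actor_id = b$aggressor, recipient_id = b$aggressed,
          start_frame = b$fight$s, end_frame = b$fight$e,
          confidence = conf_draw("fight"), stringsAsFactors = FALSE)
    }
    for (g in sch$gap_events)
      ev_rows[[length(ev_rows) + 1]] <- data.frame(
        label = g$kind, actor_id = g$actor,
        recipient_id = if (g$kind == "walk") NA_character_ else g$recipient,
        start_frame = g$s, end_frame = g$e, confidence = conf_draw(g$kind),
        stringsAsFactors = FALSE)
  }
  events <- if (length(ev_rows)) do.call(rbind, ev_rows) else
    data.frame(label = character(0), actor_id = character(0),
               recipient_id = character(0), start_frame = integer(0),
               end_frame = integer(0), confidence = numeric(0),
               stringsAsFactors = FALSE)
  events <- derive_roles(events)
  events <- events[order(events$start_frame), , drop = FALSE]
  rownames(events) <- NULL

  # planted sequences ----------------------------------------------------
  seq_rows <- list()
  for (i in seq_along(sch$blocks)) {
    b <- sch$blocks[[i]]
    if (is.null(b$si1)) next
    e1 <- episodes[episodes$trigger_index == i & episodes$rank == 1L, ]
    e2 <- episodes[episodes$trigger_index == i & episodes$rank == 2L, ]
    seq_rows[[length(seq_rows) + 1]] <- data.frame(
      trigger_index = i, trigger_start = b$ts, trigger_end = b$te,
      si1_male = b$si1$male, si1_female = b$si1$female,
      si1_state = b$si1$state,
      si1_start = e1$start_frame, si1_end = e1$end_frame,
      si2_male = if (nrow(e2)) e2$male_id else NA_character_,
      si2_female = if (nrow(e2)) e2$female_id else NA_character_,
      si2_start = if (nrow(e2)) e2$start_frame else NA_integer_,
      si2_end = if (nrow(e2)) e2$end_frame else NA_integer_,
      planted_type = b$type,
      fight_planted = !is.null(b$fight),
      stringsAsFactors = FALSE)
  }
  sequences <- if (length(seq_rows)) do.call(rbind, seq_rows) else NULL

  bundle <- recording_bundle(config$arena, config$mice,
                             poses = pose_df,
                             events = events, recording_id = recording_id,
                             validate = FALSE)
  bundle$n_frames <- sch$n_frames
  if (poses) validate_bundle(bundle)
  list(bundle = bundle,
       truth = list(episodes = episodes, sequences = sequences,
                    fights = if (poses) syn$fights else NULL))
}

#' Generate a cohort of synthetic recordings
#'
#' @param config [synthetic_config()].
#' @param n_recordings Number of recordings (the study used 11).
#' @param seed Master seed; per-recording seeds are derived from it
#'   reproducibly.
#' @param poses Synthesize trajectories per recording.
#' @return list of `generate_recording()` results, named `rec01`, ...
#' @export
generate_cohort <- function(config, n_recordings = 11, seed = 1,
                            poses = TRUE) {
  stopifnot(n_recordings >= 1)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, n_recordings)
  out <- lapply(seq_len(n_recordings), function(i)
    generate_recording(config, seed = seeds[i],
                       recording_id = sprintf("rec%02d", i), poses = poses))
  names(out) <- vapply(out, function(r) r$bundle$recording_id, character(1))
  out
}

#' Planted episodes as an interaction table
#'
#' Converts the ground-truth approach episodes of a generated recording to
#' the same shape [detect_interactions()] emits, so downstream sequence
#' stages can run on planted interactions directly (e.g., at the schedule
#' level, without pose synthesis).
#'
#' @param rec A `generate_recording()` result.
#' @return Interaction data.frame.
#' @export
episodes_to_interactions <- function(rec) {
  ep <- rec$truth$episodes
  fps <- rec$bundle$arena$fps
  data.frame(recording_id = rec$bundle$recording_id,
             male_id = ep$male_id, female_id = ep$female_id,
             start_frame = ep$start_frame, end_frame = ep$end_frame,
             duration_s = (ep$end_frame - ep$start_frame) / fps,
             initiator = ep$initiator, stringsAsFactors = FALSE)[
               order(ep$start_frame), ]
}
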
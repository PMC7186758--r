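# Synthetic colony and spike-train generator with planted, recoverable
# effects: stop/go locomotion, scripted approach events that plant passive
# and active social contacts, and a behavior-coupled inhomogeneous-Poisson
# firing rate. Ground truth (event times, true rate, true parameters) is
# returned alongside the tracks so downstream stages can be tested by
# parameter recovery.

# --- locomotion primitives ---------------------------------------------------

# Per-frame stop/go flags of a 2-state Markov chain (geometric bout lengths),
# started from the stationary distribution.
sim_go_flags <- function(n, p_stop_to_go, p_go_to_stop) {
  p_stop_stat <- p_go_to_stop / (p_stop_to_go + p_go_to_stop)
  start_go <- stats::runif(1) >= p_stop_stat
  K <- ceiling(n * max(p_stop_to_go, p_go_to_stop)) + 50
  repeat {
    a <- stats::rgeom(K, p_stop_to_go) + 1
    b <- stats::rgeom(K, p_go_to_stop) + 1
    lens <- if (start_go) as.vector(rbind(b, a)) else as.vector(rbind(a, b))
    vals <- rep(c(start_go, !start_go), K)
    if (sum(lens) >= n) return(rep(vals, lens)[seq_len(n)])
    K <- K * 2
  }
}

# Reflect coordinates into [lo, hi] (triangle fold): a random walk folded
# this way bounces off the walls without leaving the region.
fold_reflect <- function(z, lo, hi) {
  L <- hi - lo
  y <- (z - lo) %% (2 * L)
  lo + ifelse(y <= L, y, 2 * L - y)
}

# Free correlated random walk: steps with per-frame log-normal speed during
# go bouts and wrapped-normal heading persistence, folded into a rectangle.
sim_free_steps <- function(n, cfg) {
  go <- sim_go_flags(n, cfg$p_stop_to_go, cfg$p_go_to_stop)
  sdlog <- cfg$speed_sdlog
  meanlog <- log(max(cfg$speed_mean_cm_s, 1e-12)) - sdlog^2 / 2
  sp <- stats::rlnorm(n, meanlog, sdlog)          # cm/s while walking
  step <- sp / cfg$frame_rate_hz * go             # cm per frame
  th0 <- stats::runif(1, 0, 360)
  th <- th0 + cumsum(stats::rnorm(n, 0, cfg$heading_sd_deg) * go)
  list(go = go, speed_cm_s = sp * go, step = step,
       dx = step * cos(th * pi / 180), dy = step * sin(th * pi / 180))
}

clip_to_box <- function(p, lo, hi) pmin(pmax(p, lo), hi)

# --- event placement ---------------------------------------------------------

# Place planted approach events: Poisson counts per type, sync times drawn
# uniformly (snapped to the frame grid) with a minimum separation; an event
# that cannot be placed after `tries` draws is dropped.
plan_events <- function(cfg, rules, tries = 200) {
  rate <- cfg$frame_rate_hz
  edge <- 9  # s: keeps the whole scripted episode inside the recording
  n_p <- stats::rpois(1, cfg$approach_rate_passive_per_min * cfg$duration_s / 60)
  n_a <- stats::rpois(1, cfg$approach_rate_active_per_min * cfg$duration_s / 60)
  if (cfg$n_other_bees == 0) n_p <- n_a <- 0L
  types <- sample(c(rep("passive_contact", n_p), rep("active_contact", n_a)))
  placed_t <- numeric(0); placed_type <- character(0); dropped <- 0L
  if (cfg$duration_s <= 2 * edge) types <- character(0)
  for (ty in types) {
    ok <- FALSE
    for (k in seq_len(tries)) {
      u <- round(stats::runif(1, edge, cfg$duration_s - edge) * rate) / rate
      if (all(abs(u - placed_t) >= cfg$min_event_gap_s)) { ok <- TRUE; break }
    }
    if (ok) { placed_t <- c(placed_t, u); placed_type <- c(placed_type, ty) }
    else dropped <- dropped + 1L
  }
  o <- order(placed_t)
  list(t_sync = placed_t[o], type = placed_type[o], n_dropped = dropped)
}

# Direction of the scripted approach: within +/-60 degrees of the radial
# direction toward the partner's latent position (so the partner's transit
# keeps a wide berth of the focal bee), preferring small deviations, subject
# to the whole scripted excursion staying inside the arena.
choose_event_dir <- function(pos_a, w_ang_deg, extent_cm, W, H) {
  offs <- c(0, as.vector(rbind(seq(5, 60, by = 5), -seq(5, 60, by = 5))))
  best <- NULL; best_margin <- -Inf
  for (off in offs) {
    ang <- (w_ang_deg + off) * pi / 180
    u <- c(cos(ang), sin(ang))
    p <- pos_a + extent_cm * u
    margin <- min(p[1], W - p[1], p[2], H - p[2])
    if (margin >= 0.5) return(u)
    if (margin > best_margin) { best_margin <- margin; best <- u }
  }
  best
}

# --- the generator -----------------------------------------------------------

#' Simulate a colony of tracked bees with planted social events
#'
#' Generates frame-aligned trajectories for one focal bee and
#' `n_other_bees` companions inside the arena, together with complete ground
#' truth. Each bee performs a correlated random walk with stop/go Markov
#' bouts, reflected at the walls of its home range. The focal bee and the
#' other bees keep separate home ranges at least `avoid_radius_cm` apart, so
#' that every close encounter is a scripted approach event and ground truth
#' for social contacts is complete. Scripted events plant "passive contact"
#' episodes (a partner approaches while the focal bee stays still) and
#' "active contact" episodes (the focal bee starts walking toward the
#' partner `active_onset_lead_s` seconds before the contact moment). Ground
#' truth for walking onsets is derived from the latent locomotion program,
#' and ground truth for "alone" windows from the generator's own event
#' schedule, by the same rules the detectors apply to the realized tracks.
#'
#' @param cfg a [sim_config()].
#' @param rules the [analysis_config()] whose thresholds the planted events
#'   are guaranteed to satisfy.
#' @return list with `tracks` (a [track_table()]) and `truth` (class
#'   `ground_truth`): `$events` (state, window start, sync time, partner),
#'   `$params` (true rate-model parameters), `$multipliers` (per-window
#'   segment rate multipliers), `$focal_moving` (latent per-frame locomotion),
#'   `$n_dropped_placement`.
#' @export
simulate_colony <- function(cfg = sim_config(), rules = analysis_config()) {
  validate_sim_config(cfg)
  rate <- cfg$frame_rate_hz
  n <- round(cfg$duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  W <- cfg$arena_width_cm; H <- cfg$arena_height_cm
  with_seed(cfg$seed, {
    # home ranges: focal on the left, others on the right, with a buffer wide
    # enough that even a scripted focal excursion stays > alone_radius away
    # from non-partner bees
    max_excursion <- cfg$focal_walk_speed_cm_s *
      (cfg$active_onset_lead_s + 2.6)  # forward walk length, cm
    if (cfg$n_other_bees > 0) {
      gap <- max(cfg$avoid_radius_cm,
                 max_excursion + rules$alone_radius_cm + 1)
      f_hi <- (W - gap) / 2
      if (f_hi < 4) {
        stopf("arena too narrow for separated home ranges (need width > %g cm)",
              gap + 8, class = "beesocial_config_error")
      }
      f_box <- c(0.5, f_hi)
      o_box <- c(f_hi + gap, W - 0.5)
    } else {
      f_box <- c(0.5, W - 0.5)
      o_box <- NULL
    }
    y_box <- c(0.5, H - 0.5)

    plan <- plan_events(cfg, rules)
    n_ev <- length(plan$t_sync)
    other_ids <- if (cfg$n_other_bees > 0) {
      sprintf("bee%02d", seq_len(cfg$n_other_bees))
    } else character(0)
    partner <- if (n_ev > 0) sample(other_ids, n_ev, replace = TRUE) else character(0)
    i_sync <- round(plan$t_sync * rate) + 1L
    onset_frames <- round(cfg$active_onset_lead_s * rate)

    # ---- focal trajectory ----
    fw <- sim_free_steps(n, cfg)
    eff_go <- fw$go
    eff_speed <- fw$speed_cm_s
    fx <- numeric(n); fy <- numeric(n)
    cur <- c(stats::runif(1, f_box[1] + 1, f_box[2] - 1),
             stats::runif(1, y_box[1] + 1, y_box[2] - 1))
    ptr <- 1L
    ev_u <- matrix(NA_real_, n_ev, 2)
    ev_anchor <- matrix(NA_real_, n_ev, 2)
    walk_info <- vector("list", n_ev)
    step_cm <- cfg$focal_walk_speed_cm_s / rate
    free_chunk <- function(from, to) {
      if (to < from) return(invisible(NULL))
      idx <- from:to
      fx[idx] <<- fold_reflect(cur[1] + cumsum(fw$dx[idx]), f_box[1], f_box[2])
      fy[idx] <<- fold_reflect(cur[2] + cumsum(fw$dy[idx]), y_box[1], y_box[2])
      cur <<- c(fx[to], fy[to])
      invisible(NULL)
    }
    for (e in seq_len(n_ev)) {
      i_s <- i_sync[e]
      i0 <- i_s - 55L
      free_chunk(ptr, i0 - 1L)
      ev_anchor[e, ] <- cur
      if (plan$type[e] == "active_contact") {
        # still until the onset, walk toward the partner past the contact
        # moment, then walk back to the anchor; the walk direction is fixed
        # in the partner pass below once the partner's latent entry point is
        # known, so only the frame bookkeeping happens here (the walk ends
        # back at the anchor, so `cur` is already correct)
        i_on <- i_s - onset_frames
        still_idx <- i0:(i_on - 1L)
        fx[still_idx] <- cur[1]; fy[still_idx] <- cur[2]
        nb <- (i_s + 25L) - i_on + 1L            # forward-walk frames
        walk_idx <- i_on:(i_s + 25L)
        back_idx <- (i_s + 26L):(i_s + 25L + nb) # walk back to the anchor
        walk_info[[e]] <- list(walk_idx = walk_idx, back_idx = back_idx,
                               nb = nb)
        eff_go[still_idx] <- FALSE
        eff_speed[still_idx] <- 0
        eff_go[c(walk_idx, back_idx)] <- TRUE
        eff_speed[c(walk_idx, back_idx)] <- cfg$focal_walk_speed_cm_s
        ptr <- i_s + 26L + nb
      } else {
        still_idx <- i0:(i_s + 55L)
        fx[still_idx] <- cur[1]; fy[still_idx] <- cur[2]
        eff_go[still_idx] <- FALSE
        eff_speed[still_idx] <- 0
        ptr <- i_s + 56L
      }
    }
    free_chunk(ptr, n)

    # ---- other bees: latent walks in their home range ----
    ox <- vector("list", cfg$n_other_bees)
    oy <- vector("list", cfg$n_other_bees)
    if (cfg$n_other_bees > 0) {
      for (b in seq_len(cfg$n_other_bees)) {
        ow <- sim_free_steps(n, cfg)
        start <- c(stats::runif(1, o_box[1] + 1, o_box[2] - 1),
                   stats::runif(1, y_box[1] + 1, y_box[2] - 1))
        ox[[b]] <- fold_reflect(start[1] + cumsum(ow$dx), o_box[1], o_box[2])
        oy[[b]] <- fold_reflect(start[2] + cumsum(ow$dy), y_box[1], y_box[2])
      }
    }

    # ---- scripted approach episodes ----
    sched_not_alone <- rep(FALSE, n)  # frames with the partner <= alone radius
    for (e in seq_len(n_ev)) {
      i_s <- i_sync[e]
      b <- match(partner[e], other_ids)
      pos_a <- ev_anchor[e, ]
      L_in <- c(ox[[b]][i_s - 55L], oy[[b]][i_s - 55L])
      w_ang <- atan2(L_in[2] - pos_a[2], L_in[1] - pos_a[1]) * 180 / pi
      extent <- if (plan$type[e] == "active_contact") 16 + max_excursion + 1 else 17
      u <- choose_event_dir(pos_a, w_ang, extent, W, H)
      ev_u[e, ] <- u
      # focal scripted walk for active contacts, along u and back
      if (plan$type[e] == "active_contact") {
        wi <- walk_info[[e]]
        prog_f <- step_cm * seq_len(wi$nb)
        fx[wi$walk_idx] <- pos_a[1] + prog_f * u[1]
        fy[wi$walk_idx] <- pos_a[2] + prog_f * u[2]
        prog_b <- step_cm * (wi$nb - seq_len(wi$nb))
        fx[wi$back_idx] <- pos_a[1] + prog_b * u[1]
        fy[wi$back_idx] <- pos_a[2] + prog_b * u[2]
      }
      # partner distance schedule (cm from the focal bee)
      d_app <- seq(16, 0.8, length.out = 31)
      # approach + hold + retreat: position = focal position + d * u
      rel_frames <- (i_s - 30L):(i_s + 35L)
      d_rel <- c(d_app, rep(0.8, 5), 0.8 + (16 - 0.8) * (1:30) / 30)
      px <- fx[rel_frames] + d_rel * u[1]
      py <- fy[rel_frames] + d_rel * u[2]
      ox[[b]][rel_frames] <- px
      oy[[b]][rel_frames] <- py
      # transit in: polar interpolation around the (still) focal anchor
      in_idx <- (i_s - 55L):(i_s - 31L)
      r0 <- sqrt(sum((L_in - pos_a)^2)); a0 <- atan2(L_in[2] - pos_a[2], L_in[1] - pos_a[1])
      a1 <- atan2(u[2], u[1])
      dal <- ((a1 - a0 + pi) %% (2 * pi)) - pi
      alpha <- seq(0, 1, length.out = length(in_idx))
      rr <- r0 + (16 - r0) * alpha
      aa <- a0 + dal * alpha
      ox[[b]][in_idx] <- pos_a[1] + rr * cos(aa)
      oy[[b]][in_idx] <- pos_a[2] + rr * sin(aa)
      # transit out: polar interpolation around the focal position at the
      # retreat end toward the latent exit point
      out_idx <- (i_s + 36L):(i_s + 55L)
      ref <- c(fx[i_s + 35L], fy[i_s + 35L])
      L_out <- c(ox[[b]][i_s + 55L], oy[[b]][i_s + 55L])
      r1 <- sqrt(sum((L_out - ref)^2)); a2 <- atan2(L_out[2] - ref[2], L_out[1] - ref[1])
      dal2 <- ((a2 - a1 + pi) %% (2 * pi)) - pi
      alpha2 <- seq_len(length(out_idx)) / length(out_idx)
      rr2 <- 16 + (r1 - 16) * alpha2
      aa2 <- a1 + dal2 * alpha2
      ox[[b]][out_idx] <- ref[1] + rr2 * cos(aa2)
      oy[[b]][out_idx] <- ref[2] + rr2 * sin(aa2)
      # containment and minimum-separation safeguards over the whole episode
      ep <- (i_s - 55L):(i_s + 55L)
      ox[[b]][ep] <- clip_to_box(ox[[b]][ep], 0.05, W - 0.05)
      oy[[b]][ep] <- clip_to_box(oy[[b]][ep], 0.05, H - 0.05)
      dd <- sqrt((ox[[b]][ep] - fx[ep])^2 + (oy[[b]][ep] - fy[ep])^2)
      close_bad <- which(dd < 1.5 & !(ep %in% ((i_s - 30L):(i_s + 35L))))
      for (j in close_bad) {
        i <- ep[j]
        ang <- seq(0, 2 * pi, length.out = 73)[-73]
        cx <- fx[i] + 1.6 * cos(ang); cy <- fy[i] + 1.6 * sin(ang)
        okang <- cx > 0.05 & cx < W - 0.05 & cy > 0.05 & cy < H - 0.05
        k <- which.min((cx - ox[[b]][i])^2 + (cy - oy[[b]][i])^2 + ifelse(okang, 0, 1e9))
        ox[[b]][i] <- cx[k]; oy[[b]][i] <- cy[k]
      }
      dd <- sqrt((ox[[b]][ep] - fx[ep])^2 + (oy[[b]][ep] - fy[ep])^2)
      sched_not_alone[ep] <- sched_not_alone[ep] | dd <= rules$alone_radius_cm
    }

    # ---- ground-truth events ----
    pre_s <- rules$sync_mark_s
    contacts <- new_events(plan$type,
                           t_start_s = t[i_sync] - pre_s,
                           t_sync_s = t[i_sync],
                           partner_id = partner)
    # walking onsets from the latent locomotion program (scripted overrides
    # included), by the same rule the detector applies to realized speeds
    cand <- onset_frames_from_movement(eff_go, eff_speed / rate, rules, rate)
    t_on <- resolve_candidates(t[cand], rules$window_s)
    onsets <- new_events("walking_onset",
                         t_start_s = t_on - pre_s, t_sync_s = t_on)
    t_end <- cfg$duration_s
    keep_on <- onsets$t_start_s >= 0 & onsets$t_start_s + rules$window_s <= t_end
    onsets <- onsets[keep_on, , drop = FALSE]
    alone <- tile_alone_runs(!sched_not_alone, t, rules, rate)
    n_passive <- sum(plan$type == "passive_contact")
    rnd_start <- if (n_passive > 0) {
      (floor(stats::runif(n_passive, 0, t_end - rules$window_s) * rate)) / rate
    } else numeric(0)
    randoms <- new_events("random", t_start_s = rnd_start,
                          t_sync_s = rnd_start + pre_s)
    events <- rbind(alone, randoms, onsets, contacts)
    events <- events[order(events$t_start_s, events$state), , drop = FALSE]
    rownames(events) <- NULL

    # ---- per-window rate multipliers ----
    w_frames <- round(rules$window_s * rate)
    seg_frames <- round(cfg$mult_segment_s * rate)
    n_seg <- w_frames %/% seg_frames
    mult <- do.call(rbind, lapply(seq_len(nrow(events)), function(k) {
      st <- events$state[k]
      sg <- cfg$sigma_state[[st]]
      # median-preserving log-normal: multipliers symmetric about 1 on the
      # log scale, so larger sigma raises within-window rate dispersion
      m <- if (sg > 0) stats::rlnorm(n_seg, 0, sg) else rep(1, n_seg)
      i0 <- round(events$t_start_s[k] * rate) + 1L
      data.frame(event = k, state = st,
                 frame0 = i0 + (seq_len(n_seg) - 1L) * seg_frames,
                 n_frames = seg_frames, m = m)
    }))
    if (is.null(mult)) {
      mult <- data.frame(event = integer(0), state = character(0),
                         frame0 = integer(0), n_frames = integer(0),
                         m = numeric(0))
    }

    # ---- body-axis angles from realized motion ----
    # body axis equals the realized direction of motion; a stationary bee
    # keeps its last heading (the first frame gets a random axis)
    theta_from_path <- function(x, y) {
      m <- length(x)
      ddx <- c(NA, diff(x)); ddy <- c(NA, diff(y))
      mv <- !is.na(ddx) & sqrt(ddx^2 + ddy^2) > 1e-9
      th <- rep(NA_real_, m)
      th[mv] <- wrap_deg(atan2(ddy[mv], ddx[mv]) * 180 / pi)
      if (is.na(th[1])) th[1] <- stats::runif(1, 0, 360)
      idx <- which(!is.na(th))
      th[idx][findInterval(seq_len(m), idx)]
    }
    th_f <- theta_from_path(fx, fy)
    rnd6 <- function(z) round(z, 6)
    frames0 <- seq_len(n) - 1L
    nbee <- 1L + cfg$n_other_bees
    all_x <- c(fx, unlist(ox)); all_y <- c(fy, unlist(oy))
    all_th <- c(wrap_deg(th_f),
                unlist(lapply(seq_along(other_ids), function(b) {
                  wrap_deg(theta_from_path(ox[[b]], oy[[b]]))
                })))
    tracks <- track_table(rep(frames0, nbee), rep(t, nbee),
                          rep(c("focal", other_ids), each = n),
                          rnd6(all_x), rnd6(all_y), rnd6(all_th),
                          frame_rate_hz = rate, arena_cm = c(W, H))
    truth <- structure(list(
      events = events,
      params = list(baseline_hz = cfg$baseline_hz,
                    beta_dist_hz = cfg$beta_dist_hz,
                    dist_kernel_d0_cm = cfg$dist_kernel_d0_cm,
                    alpha_hz = cfg$alpha_hz, lead_s = cfg$lead_s,
                    bump_width_s = cfg$bump_width_s,
                    sigma_state = as.list(cfg$sigma_state)),
      multipliers = mult,
      focal_moving = eff_go,
      focal_speed_cm_s = eff_speed,
      n_frames = n, frame_rate_hz = rate, duration_s = cfg$duration_s,
      n_dropped_placement = plan$n_dropped
    ), class = "ground_truth")
    list(tracks = tracks, truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(x$events$state)
  cat(sprintf("<ground_truth> %d frames at %g fps; planted events: %s\n",
              x$n_frames, x$frame_rate_hz,
              paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                    collapse = ", ")))
  invisible(x)
}

#' True firing-rate series of the simulated focal unit
#'
#' Assembles the ground-truth rate \eqn{\lambda(t)} on the frame grid:
#' baseline plus the distance component `beta_dist * exp(-d/d0)` (d =
#' realized nearest-bee distance, vanishing when no other bee is present),
#' plus a raised-cosine bump of amplitude `alpha_hz` and full width
#' `bump_width_s` peaking `lead_s` seconds before each planted active
#' contact (truncated at the contact moment), all multiplied by the
#' per-window segment multipliers and clipped at zero.
#'
#' @param tracks,truth a simulation from [simulate_colony()].
#' @param cfg the [sim_config()] used for that simulation.
#' @return a `rate_series` data.frame (`t`, `count` = NA, `rate` = lambda in
#'   Hz) on the frame grid.
#' @export
compute_rate <- function(tracks, truth, cfg) {
  rate <- truth$frame_rate_hz
  n <- truth$n_frames
  t <- (seq_len(n) - 1) / rate
  nn <- nearest_bee(tracks)
  d <- nn$nn_dist_cm[match(seq_len(n) - 1L, nn$frame)]
  kern <- ifelse(is.na(d), 0, exp(-d / cfg$dist_kernel_d0_cm))
  bump <- rep(0, n)
  act <- truth$events[truth$events$state == "active_contact", , drop = FALSE]
  if (nrow(act) > 0 && cfg$alpha_hz > 0 && cfg$bump_width_s > 0) {
    for (ts in act$t_sync_s) {
      u <- t - ts                     # lag relative to the contact moment
      z <- u + cfg$lead_s             # 0 at the bump peak
      sel <- abs(z) <= cfg$bump_width_s / 2 & u <= 0
      bump[sel] <- bump[sel] +
        0.5 * (1 + cos(2 * pi * z[sel] / cfg$bump_width_s))
    }
  }
  m <- rep(1, n)
  if (nrow(truth$multipliers) > 0) {
    order_states <- c("alone", "random", "walking_onset",
                      "passive_contact", "active_contact")
    for (st in order_states) {
      rows <- truth$multipliers[truth$multipliers$state == st, , drop = FALSE]
      for (k in seq_len(nrow(rows))) {
        i0 <- rows$frame0[k]
        idx <- i0:(i0 + rows$n_frames[k] - 1L)
        idx <- idx[idx >= 1 & idx <= n]
        m[idx] <- rows$m[k]
      }
    }
  }
  lam <- pmax(0, (cfg$baseline_hz + cfg$beta_dist_hz * kern +
                    cfg$alpha_hz * bump) * m)
  out <- data.frame(t = t, count = NA_real_, rate = lam)
  attr(out, "bin_w") <- 1 / rate
  attr(out, "t0") <- 0
  class(out) <- c("rate_series", "data.frame")
  out
}

#' Simulate a spike train from a rate series by thinning
#'
#' Inhomogeneous-Poisson sampling: candidate spikes are drawn from a
#' homogeneous Poisson process at `max(lambda)` and accepted with
#' probability `lambda(t)/max(lambda)` (lambda piecewise constant on the
#' frame bins). Reproducible under the seed.
#'
#' @param lambda_series a `rate_series` with the true rate in Hz.
#' @param seed integer seed.
#' @return a [spike_train()] (possibly empty).
#' @export
simulate_spikes <- function(lambda_series, seed = 1L) {
  lam <- lambda_series$rate
  if (length(lam) == 0) return(spike_train(numeric(0)))
  if (any(lam < 0)) stopf("lambda must be nonnegative")
  bin_w <- attr(lambda_series, "bin_w") %||% 0.1
  t0 <- attr(lambda_series, "t0") %||% lambda_series$t[1]
  t_end <- t0 + length(lam) * bin_w
  lam_max <- max(lam)
  if (lam_max == 0) return(spike_train(numeric(0), t_span = c(t0, t_end)))
  with_seed(seed, {
    n_cand <- stats::rpois(1, lam_max * (t_end - t0))
    cand <- sort(stats::runif(n_cand, t0, t_end))
    idx <- pmin(floor((cand - t0) / bin_w) + 1, length(lam))
    keep <- stats::runif(n_cand) < lam[idx] / lam_max
    spike_train(round(cand[keep], 6), t_span = c(t0, t_end))
  })
}

#' Simulate a full recording: tracks, true rate and spikes
#'
#' Convenience wrapper running [simulate_colony()], [compute_rate()] and
#' [simulate_spikes()] (spike seed derived from `cfg$seed`).
#'
#' @inheritParams simulate_colony
#' @return list with `tracks`, `truth` (with `$lambda` attached), `spikes`.
#' @export
simulate_recording <- function(cfg = sim_config(), rules = analysis_config()) {
  sim <- simulate_colony(cfg, rules)
  lam <- compute_rate(sim$tracks, sim$truth, cfg)
  spikes <- simulate_spikes(lam, seed = cfg$seed + 1000003L)
  sim$truth$lambda <- lam
  list(tracks = sim$tracks, truth = sim$truth, spikes = spikes)
}

#' Write a simulated fixture to disk
#'
#' Writes `tracks.csv`, `spikes.txt` and `truth.json` into `out_dir`. The
#' tracks and spikes round-trip losslessly through [read_tracks()] and
#' [read_spikes()]; re-running with the same configuration produces
#' byte-identical files.
#'
#' @inheritParams simulate_colony
#' @param out_dir output directory (created if missing).
#' @return named character vector of the three paths, invisibly.
#' @export
make_fixture <- function(cfg = sim_config(), out_dir,
                         rules = analysis_config()) {
  if (missing(out_dir)) stopf("out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stopf("cannot create output directory: %s", out_dir,
          class = "beesocial_io_error")
  }
  rec <- simulate_recording(cfg, rules)
  paths <- c(tracks = file.path(out_dir, "tracks.csv"),
             spikes = file.path(out_dir, "spikes.txt"),
             truth = file.path(out_dir, "truth.json"))
  tryCatch({
    write_tracks(rec$tracks, paths[["tracks"]])
    write_spikes(rec$spikes, paths[["spikes"]])
    truth_out <- list(events = rec$truth$events,
                      params = rec$truth$params,
                      multipliers = rec$truth$multipliers,
                      n_frames = rec$truth$n_frames,
                      frame_rate_hz = rec$truth$frame_rate_hz,
                      duration_s = rec$truth$duration_s)
    jsonlite::write_json(truth_out, paths[["truth"]], auto_unbox = TRUE,
                         digits = 10)
  }, error = function(e) {
    stopf("failed writing fixture under %s: %s", out_dir, conditionMessage(e),
          class = "beesocial_io_error")
  })
  invisible(paths)
}
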
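# Social-state classification: 4 s windows labeled alone / random /
# walking onset / passive contact / active contact from distance and
# movement rules.

new_events <- function(state = character(0), t_start_s = numeric(0),
                       t_sync_s = numeric(0), partner_id = NA_character_) {
  n <- length(t_sync_s)
  data.frame(state = rep_len(state, n), t_start_s = t_start_s,
             t_sync_s = t_sync_s,
             partner_id = rep_len(partner_id, n),
             stringsAsFactors = FALSE)
}

#' Frame-level movement flags and stillness predicate
#'
#' A frame is *moving* when its walking speed is at or above the
#' `moving_speed_threshold_cm_s`. A span of `still_span_s` seconds starting
#' at frame i is *still* when the total path length inside it is below
#' `still_displacement_mm`. A span is *continuously moving* when at least a
#' fraction `moving_fraction` of its frames are moving.
#'
#' @param speed_cm_s frame-wise walking speed, cm/s (`NA` treated as not
#'   moving and as zero displacement).
#' @param cfg an [analysis_config()].
#' @param frame_rate_hz frames per second.
#' @return a list with logical vector `moving`, numeric `disp_cm` (per-frame
#'   displacement), logical `still_from` (span starting at frame i is still)
#'   and numeric `moving_frac_from` (moving fraction of the span starting at
#'   frame i); the trailing span positions are `NA`.
#' @export
movement_flags <- function(speed_cm_s, cfg = analysis_config(),
                           frame_rate_hz = 10) {
  disp <- speed_cm_s / frame_rate_hz
  disp[is.na(disp)] <- 0
  moving <- !is.na(speed_cm_s) & speed_cm_s >= cfg$moving_speed_threshold_cm_s
  k <- round(cfg$still_span_s * frame_rate_hz)
  path <- roll_sum_forward(disp, k)
  still_from <- path < cfg$still_displacement_mm / 10  # mm -> cm
  moving_frac_from <- roll_sum_forward(as.numeric(moving), k) / k
  list(moving = moving, disp_cm = disp, still_from = still_from,
       moving_frac_from = moving_frac_from, span_frames = k)
}

# Shared walking-onset rule: onset frames where a still span ends and a
# continuous-move span begins. Used both by the detector (on realized
# kinematics) and by the generator's ground truth (on the latent locomotion
# program), so both routes apply the identical rule to their own inputs.
onset_frames_from_movement <- function(moving, disp_cm, cfg, frame_rate_hz) {
  k <- round(cfg$still_span_s * frame_rate_hz)
  n <- length(moving)
  if (n < 2 * k) return(integer(0))
  path <- roll_sum_forward(disp_cm, k)
  frac <- roll_sum_forward(as.numeric(moving), k) / k
  i <- (k + 1):(n - k + 1)
  cand <- i[moving[i] &
              path[i - k] < cfg$still_displacement_mm / 10 &
              frac[i] >= cfg$moving_fraction]
  cand
}

#' Detect "alone" windows
#'
#' Maximal runs of frames in which no other bee is within
#' `alone_radius_cm` (strictly greater distance, or no other bee tracked)
#' are tiled greedily from the run start into non-overlapping windows of
#' `window_s` seconds, each synchronized at its `sync_mark_s` mark.
#'
#' @param bhv a [behavior_series()].
#' @param cfg an [analysis_config()].
#' @return event data.frame (`state`, `t_start_s`, `t_sync_s`, `partner_id`).
#' @export
detect_alone <- function(bhv, cfg = analysis_config()) {
  rate <- attr(bhv, "frame_rate_hz") %||% 10
  alone <- is.na(bhv$nn_dist_cm) | bhv$nn_dist_cm > cfg$alone_radius_cm
  tile_alone_runs(alone, bhv$time_s, cfg, rate)
}

# Tile maximal TRUE runs of `flags` into non-overlapping whole windows,
# greedily from each run start. Shared by the detector (flags from realized
# nearest-bee distances) and the generator's ground truth (flags from its
# own event schedule), so both apply the identical tiling rule.
tile_alone_runs <- function(flags, time_s, cfg, frame_rate_hz) {
  w <- round(cfg$window_s * frame_rate_hz)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  out <- list()
  for (j in which(r$values & r$lengths >= w)) {
    n_win <- r$lengths[j] %/% w
    s_idx <- starts[j] + (seq_len(n_win) - 1) * w
    out[[length(out) + 1]] <- new_events(
      "alone",
      t_start_s = time_s[s_idx],
      t_sync_s = time_s[s_idx] + cfg$sync_mark_s
    )
  }
  if (length(out) == 0) return(new_events())
  do.call(rbind, out)
}

#' Detect walking-onset events
#'
#' An onset is a frame at which a `still_span_s` stillness span (total path
#' under `still_displacement_mm`) ends and a continuous-move span of the
#' same length begins; the event window is synchronized to the onset frame.
#' Overlapping candidates are resolved by keeping the earliest and skipping
#' `window_s` seconds. Events whose full window does not fit inside the
#' recording are dropped.
#'
#' @inheritParams detect_alone
#' @return event data.frame.
#' @export
detect_walking_onset <- function(bhv, cfg = analysis_config()) {
  rate <- attr(bhv, "frame_rate_hz") %||% 10
  mf <- movement_flags(bhv$speed_cm_s, cfg, rate)
  cand <- onset_frames_from_movement(mf$moving, mf$disp_cm, cfg, rate)
  if (length(cand) == 0) return(new_events())
  t_cand <- bhv$time_s[cand]
  t_keep <- resolve_candidates(t_cand, cfg$window_s)
  ev <- new_events("walking_onset",
                   t_start_s = t_keep - cfg$sync_mark_s,
                   t_sync_s = t_keep)
  clip_events_to_recording(ev, bhv, cfg)
}

clip_events_to_recording <- function(ev, bhv, cfg) {
  t0 <- bhv$time_s[1]
  t1 <- bhv$time_s[nrow(bhv)] + 1 / (attr(bhv, "frame_rate_hz") %||% 10)
  keep <- ev$t_start_s >= t0 - 1e-9 &
    (ev$t_start_s + cfg$window_s) <= t1 + 1e-9
  dropped <- sum(!keep)
  out <- ev[keep, , drop = FALSE]
  attr(out, "n_dropped_boundary") <- dropped
  out
}

#' Detect passive and active social contacts
#'
#' A contact moment is the first frame at which some other bee comes closer
#' than `contact_radius_cm`. The window of `window_s` seconds is
#' synchronized so that this moment falls at the `sync_mark_s` mark. A
#' candidate is kept only if the focal bee was alone at the window start (no
#' other bee within `alone_radius_cm`) and exactly one bee is within the
#' contact radius at the sync frame. The contact is *active* when the focal
#' bee was still in the early window and started walking within
#' `active_onset_window_s` seconds before the contact moment (and keeps
#' walking); it is *passive* when the focal bee either did not move for the
#' entire window or moved for the entire window. Contacts matching neither
#' template are dropped and counted in the `n_unclassified` attribute.
#'
#' @inheritParams detect_alone
#' @return event data.frame with `partner_id` filled; attributes
#'   `n_unclassified`, `n_rejected_crowded` (more than one bee at sync),
#'   `n_rejected_not_alone` (not alone at window start).
#' @export
detect_contacts <- function(bhv, cfg = analysis_config()) {
  rate <- attr(bhv, "frame_rate_hz") %||% 10
  n <- nrow(bhv)
  w <- round(cfg$window_s * rate)
  pre <- round(cfg$sync_mark_s * rate)
  post <- w - pre
  mf <- movement_flags(bhv$speed_cm_s, cfg, rate)
  d <- bhv$nn_dist_cm
  in_contact <- !is.na(d) & d < cfg$contact_radius_cm
  edges <- which(in_contact & !c(FALSE, in_contact[-n]))
  out <- list()
  n_uncl <- 0L; n_crowd <- 0L; n_not_alone <- 0L; n_bound <- 0L
  onset_lo <- round(cfg$active_onset_window_s[2] * rate)
  onset_hi <- round(cfg$active_onset_window_s[1] * rate)
  for (i in edges) {
    w0 <- i - pre; w1 <- i + post - 1
    if (w0 < 1 || w1 > n) { n_bound <- n_bound + 1L; next }
    if (!is.na(d[w0]) && d[w0] < cfg$alone_radius_cm) {
      n_not_alone <- n_not_alone + 1L; next
    }
    if (!is.na(bhv$nn2_dist_cm[i]) && bhv$nn2_dist_cm[i] < cfg$contact_radius_cm) {
      n_crowd <- n_crowd + 1L; next
    }
    mv <- mf$moving[w0:w1]
    frac_all <- mean(mv)
    start_frames <- mf$moving[w0:(i - onset_lo - 1)]
    frac_start <- mean(start_frames)
    onset_range <- (i - onset_lo):(i - onset_hi)
    onset_rel <- which(mf$moving[onset_range])
    state <- NA_character_
    if (frac_start <= 1 - cfg$moving_fraction && length(onset_rel) > 0) {
      # j is the first moving frame inside the onset interval, so the focal
      # bee is still between the window start span and j by construction
      j <- onset_range[onset_rel[1]]
      if (mean(mf$moving[j:w1]) >= cfg$moving_fraction) {
        state <- "active_contact"
      }
    }
    if (is.na(state)) {
      if (frac_all <= 1 - cfg$moving_fraction || frac_all >= cfg$moving_fraction) {
        state <- "passive_contact"
      }
    }
    if (is.na(state)) { n_uncl <- n_uncl + 1L; next }
    out[[length(out) + 1]] <- new_events(
      state,
      t_start_s = bhv$time_s[w0],
      t_sync_s = bhv$time_s[i],
      partner_id = bhv$nn_id[i]
    )
  }
  ev <- if (length(out)) do.call(rbind, out) else new_events()
  attr(ev, "n_unclassified") <- n_uncl
  attr(ev, "n_rejected_crowded") <- n_crowd
  attr(ev, "n_rejected_not_alone") <- n_not_alone
  attr(ev, "n_dropped_boundary") <- n_bound
  ev
}

#' Sample "random" control windows
#'
#' Window starts are drawn uniformly over `[t0, t1 - window_s]` under the
#' given seed. Random windows may overlap windows of other states (the
#' control is a baseline draw, not an exclusion).
#'
#' @param t0,t1 recording span, s (`t1 - t0 >= window_s`).
#' @param n number of windows (the caller typically matches the number of
#'   passive contacts).
#' @param cfg an [analysis_config()].
#' @param seed integer seed.
#' @return event data.frame with state "random".
#' @export
sample_random_windows <- function(t0, t1, n, cfg = analysis_config(),
                                  seed = 1L) {
  if (t1 - t0 < cfg$window_s) {
    stopf("recording span (%g s) is shorter than one %g s window",
          t1 - t0, cfg$window_s, class = "beesocial_config_error")
  }
  if (n == 0) return(new_events())
  starts <- with_seed(seed, stats::runif(n, t0, t1 - cfg$window_s))
  new_events("random", t_start_s = starts,
             t_sync_s = starts + cfg$sync_mark_s)
}

#' Classify the whole recording into a social-state event catalog
#'
#' Runs all detectors and adds count-matched random windows (as many as
#' there are passive contacts). Windows of the same state never overlap;
#' overlaps across states are permitted and counted in the
#' `n_cross_state_overlaps` attribute.
#'
#' @param bhv a [behavior_series()].
#' @param cfg an [analysis_config()].
#' @param seed seed for the random-window draw.
#' @return an event catalog data.frame sorted by window start, with columns
#'   `state`, `t_start_s`, `t_sync_s`, `partner_id`.
#' @export
classify_all <- function(bhv, cfg = analysis_config(), seed = 1L) {
  alone <- detect_alone(bhv, cfg)
  onset <- detect_walking_onset(bhv, cfg)
  contacts <- detect_contacts(bhv, cfg)
  n_passive <- sum(contacts$state == "passive_contact")
  rnd <- sample_random_windows(bhv$time_s[1],
                               bhv$time_s[nrow(bhv)] +
                                 1 / (attr(bhv, "frame_rate_hz") %||% 10),
                               n_passive, cfg, seed)
  cat_all <- rbind(alone, onset, contacts, rnd)
  cat_all <- cat_all[order(cat_all$t_start_s, cat_all$state), , drop = FALSE]
  rownames(cat_all) <- NULL
  # flag overlaps across states (same-state windows are non-overlapping by
  # construction of each detector)
  n_overlap <- 0L
  if (nrow(cat_all) > 1) {
    real <- cat_all[cat_all$state != "random", , drop = FALSE]
    if (nrow(real) > 1) {
      o <- order(real$t_start_s)
      st <- real$t_start_s[o]; en <- st + cfg$window_s
      n_overlap <- sum(st[-1] < en[-length(en)] + -1e-9)
    }
  }
  attr(cat_all, "n_cross_state_overlaps") <- n_overlap
  attr(cat_all, "n_unclassified_contacts") <- attr(contacts, "n_unclassified") %||% 0L
  class(cat_all) <- c("event_catalog", "data.frame")
  cat_all
}

#' Read and write event catalogs as CSV
#'
#' @param events event catalog data.frame.
#' @param path CSV path.
#' @return `read_events()` returns the catalog; `write_events()` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("state", "t_start_s", "t_sync_s", "partner_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stopf("event catalog is missing columns: %s", paste(miss, collapse = ", "),
          class = "beesocial_io_error")
  }
  df$partner_id <- as.character(df$partner_id)
  class(df) <- c("event_catalog", "data.frame")
  df
}
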
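# Behavioral covariates derived from the track table: walking speed,
# nearest-bee distance, gravity-relative and relative-body-axis angles.

one_bee <- function(tracks, id) {
  sub <- tracks[tracks$bee_id == id, , drop = FALSE]
  sub[order(sub$frame), , drop = FALSE]
}

#' Walking speed of one bee
#'
#' Speed at frame i is the centroid displacement from frame i-1 times the
#' frame rate; the first frame (and any frame following a tracker gap) has
#' speed `NA`, except that the very first frame is reported as 0 so the
#' series aligns with the frame grid. No smoothing is applied.
#'
#' @param bee_track rows of a `track_table` for a single bee.
#' @param frame_rate_hz frames per second.
#' @return data.frame with `frame`, `time_s`, `speed_cm_s`.
#' @export
walking_speed <- function(bee_track, frame_rate_hz = 10) {
  n <- nrow(bee_track)
  if (n < 2) {
    warning("walking_speed: fewer than 2 frames; returning empty series",
            call. = FALSE)
    return(data.frame(frame = integer(0), time_s = numeric(0),
                      speed_cm_s = numeric(0)))
  }
  dx <- diff(bee_track$x_cm)
  dy <- diff(bee_track$y_cm)
  dfr <- diff(bee_track$frame)
  sp <- sqrt(dx^2 + dy^2) * frame_rate_hz
  sp[dfr != 1L] <- NA_real_  # tracker gap: speed undefined after the gap
  data.frame(frame = bee_track$frame, time_s = bee_track$time_s,
             speed_cm_s = c(0, sp))
}

#' Distance to the nearest other bee, per frame
#'
#' Euclidean centroid-to-centroid distance from the focal bee to the nearest
#' tracked other bee in each frame. Ties are broken by lexicographic bee id.
#' Frames in which no other bee is tracked get `NA` distance and id. The
#' body reference point is the tracked centroid; note the 1 cm contact
#' threshold is sensitive to this choice.
#'
#' @param tracks a `track_table` containing the focal bee and any others.
#' @param focal_id id of the focal bee (default "focal").
#' @return data.frame with `frame`, `time_s`, `nn_dist_cm`, `nn_id`, and
#'   `nn2_dist_cm`, the distance to the second-nearest other bee (`NA` when
#'   fewer than two others are tracked) — used by the contact detector's
#'   "only one bee within contact radius" rule.
#' @export
nearest_bee <- function(tracks, focal_id = "focal") {
  focal <- one_bee(tracks, focal_id)
  if (nrow(focal) == 0) stopf("no rows for focal bee '%s'", focal_id)
  others <- sort(setdiff(unique(tracks$bee_id), focal_id))
  out <- data.frame(frame = focal$frame, time_s = focal$time_s,
                    nn_dist_cm = NA_real_, nn_id = NA_character_,
                    nn2_dist_cm = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(others) == 0) return(out)
  dmat <- matrix(NA_real_, nrow = nrow(focal), ncol = length(others))
  for (j in seq_along(others)) {
    ob <- one_bee(tracks, others[j])
    idx <- match(focal$frame, ob$frame)
    ok <- !is.na(idx)
    dmat[ok, j] <- sqrt((ob$x_cm[idx[ok]] - focal$x_cm[ok])^2 +
                        (ob$y_cm[idx[ok]] - focal$y_cm[ok])^2)
  }
  has <- rowSums(!is.na(dmat)) > 0
  if (any(has)) {
    dwork <- dmat
    dwork[is.na(dwork)] <- Inf
    jmin <- max.col(-dwork, ties.method = "first")
    out$nn_dist_cm[has] <- dwork[cbind(which(has), jmin[has])]
    out$nn_id[has] <- others[jmin[has]]
    if (length(others) >= 2) {
      dwork[cbind(seq_len(nrow(dwork)), jmin)] <- Inf
      jmin2 <- max.col(-dwork, ties.method = "first")
      d2 <- dwork[cbind(which(has), jmin2[has])]
      d2[!is.finite(d2)] <- NA_real_
      out$nn2_dist_cm[has] <- d2
    }
  }
  out
}

#' Body-axis orientation relative to gravity
#'
#' Converts the arena-frame body-axis angle into a gravity-relative angle on
#' the tilted floor, with 0 degrees = pointing up-slope and 180 degrees =
#' pointing down-slope. The arena +y axis is the up-slope direction and arena
#' angles are measured counterclockwise from +x, so the gravity-relative
#' angle is `(theta - 90) mod 360`: up-slope (theta = 90) maps to 0,
#' down-slope (theta = 270) maps to 180, cross-slope to 90 or 270.
#'
#' @param theta_deg body-axis angles in arena coordinates, degrees.
#' @return gravity-relative angles in degrees, `[0, 360)`.
#' @export
orientation_to_gravity <- function(theta_deg) {
  wrap_deg(theta_deg - 90)
}

#' Relative angle between the focal bee's and the nearest bee's body axes
#'
#' `(theta_nearest - theta_focal) mod 360`: 0 for parallel bees, 180 for
#' antiparallel. `NA` where no nearest bee is defined.
#'
#' @param theta_focal_deg,theta_nearest_deg aligned angle series, degrees.
#' @return relative angles in degrees, `[0, 360)`.
#' @export
relative_body_angle <- function(theta_focal_deg, theta_nearest_deg) {
  wrap_deg(theta_nearest_deg - theta_focal_deg)
}

#' Bearing of the nearest bee from the focal bee's body axis
#'
#' The alternative angular covariate: the direction from the focal bee to the
#' nearest bee (the approach bearing), measured relative to the focal bee's
#' long body axis. 0 means the other bee is dead ahead.
#'
#' @param tracks a `track_table`.
#' @param focal_id focal bee id.
#' @return data.frame with `frame`, `time_s`, `bearing_deg` (`NA` when no
#'   other bee is tracked).
#' @export
approach_bearing <- function(tracks, focal_id = "focal") {
  focal <- one_bee(tracks, focal_id)
  nn <- nearest_bee(tracks, focal_id)
  out <- data.frame(frame = nn$frame, time_s = nn$time_s,
                    bearing_deg = NA_real_)
  ok <- !is.na(nn$nn_id)
  if (!any(ok)) return(out)
  for (id in unique(nn$nn_id[ok])) {
    sel <- ok & nn$nn_id == id
    ob <- one_bee(tracks, id)
    idx <- match(nn$frame[sel], ob$frame)
    dx <- ob$x_cm[idx] - focal$x_cm[sel]
    dy <- ob$y_cm[idx] - focal$y_cm[sel]
    abs_bearing <- wrap_deg(atan2(dy, dx) * 180 / pi)
    out$bearing_deg[sel] <- wrap_deg(abs_bearing - focal$theta_deg[sel])
  }
  out
}

#' Mean spike rate per angular bin
#'
#' Averages frame-wise rates within angular bins (default 10 degrees, i.e.,
#' 36 bins `[0,10), [10,20), ...`). Frames with `NA` angle or rate are
#' skipped; empty bins are reported with `NA` mean.
#'
#' @param angles_deg frame-wise angles, degrees.
#' @param rates frame-wise spike rates, Hz (aligned with `angles_deg`).
#' @param bin_deg bin width in degrees; must divide 360.
#' @return data.frame with `bin_start_deg`, `bin_mid_deg`, `mean_rate`, `n`.
#' @export
angular_rate_profile <- function(angles_deg, rates, bin_deg = 10) {
  if (360 %% bin_deg != 0) {
    stopf("bin_deg (%g) must divide 360", bin_deg,
          class = "beesocial_config_error")
  }
  if (length(angles_deg) != length(rates)) {
    stopf("angles and rates must be aligned series of equal length")
  }
  n_bins <- 360 / bin_deg
  keep <- !is.na(angles_deg) & !is.na(rates)
  idx <- floor(wrap_deg(angles_deg[keep]) / bin_deg) + 1
  mean_rate <- rep(NA_real_, n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  sums <- rep(0, n_bins)
  if (length(idx)) {
    agg <- tapply(rates[keep], factor(idx, levels = seq_len(n_bins)), sum)
    sums <- ifelse(is.na(agg), 0, agg)
  }
  mean_rate[counts > 0] <- sums[counts > 0] / counts[counts > 0]
  data.frame(bin_start_deg = (seq_len(n_bins) - 1) * bin_deg,
             bin_mid_deg = (seq_len(n_bins) - 0.5) * bin_deg,
             mean_rate = mean_rate, n = counts)
}

#' Split a series into four contiguous equal-duration quarters
#'
#' Quarters are contiguous in time; when the length is not divisible by 4 the
#' remainder frames go to the fourth quarter, so the concatenation of the
#' quarters always reproduces the original series.
#'
#' @param x a vector or data.frame with at least 4 elements/rows.
#' @return a list of 4 pieces of the same type as `x`.
#' @export
quarter_split <- function(x) {
  n <- if (is.data.frame(x)) nrow(x) else length(x)
  if (n < 4) stopf("quarter_split needs at least 4 frames (got %d)", n)
  q <- n %/% 4
  starts <- c(1, q + 1, 2 * q + 1, 3 * q + 1)
  ends <- c(q, 2 * q, 3 * q, n)
  lapply(seq_len(4), function(i) {
    idx <- starts[i]:ends[i]
    if (is.data.frame(x)) x[idx, , drop = FALSE] else x[idx]
  })
}

#' Compare the focal bee's walking speed with a co-tracked bee's
#'
#' Sanity check that the electrode-carrying bee walks like its hive mates:
#' rank-sum test of the focal bee's frame-wise walking speeds against those
#' of a comparison bee drawn from the co-tracked pool. The comparison bee is
#' the one closest to the focal bee on average (smallest median distance),
#' so its behavioral context matches the focal bee's as closely as possible.
#'
#' @param tracks a `track_table` with the focal bee and at least one other.
#' @param focal_id focal bee id.
#' @param frame_rate_hz frames per second.
#' @return a `rank_sum_test` with attribute `comparison_bee`.
#' @export
compare_focal_vs_others_speed <- function(tracks, focal_id = "focal",
                                          frame_rate_hz = 10) {
  others <- sort(setdiff(unique(tracks$bee_id), focal_id))
  if (length(others) == 0) {
    stopf("no comparison bees are tracked", class = "beesocial_stats_error")
  }
  focal <- one_bee(tracks, focal_id)
  med_d <- vapply(others, function(id) {
    ob <- one_bee(tracks, id)
    idx <- match(focal$frame, ob$frame)
    ok <- !is.na(idx)
    stats::median(sqrt((ob$x_cm[idx[ok]] - focal$x_cm[ok])^2 +
                       (ob$y_cm[idx[ok]] - focal$y_cm[ok])^2))
  }, numeric(1))
  comp_id <- others[which.min(med_d)]
  sp_f <- walking_speed(focal, frame_rate_hz)$speed_cm_s
  sp_o <- walking_speed(one_bee(tracks, comp_id), frame_rate_hz)$speed_cm_s
  sp_f <- sp_f[!is.na(sp_f)]; sp_o <- sp_o[!is.na(sp_o)]
  res <- rank_sum_test(sp_f, sp_o)
  attr(res, "comparison_bee") <- comp_id
  res
}

#' Assemble the frame-wise behavior series
#'
#' Joins walking speed, nearest-bee distance/id, gravity-relative body
#' orientation, relative body-axis angle and approach bearing into one
#' data.frame on the frame grid of the focal bee.
#'
#' @param tracks a `track_table`.
#' @param focal_id focal bee id.
#' @param frame_rate_hz frames per second.
#' @return a `behavior_series` data.frame keyed by `frame`.
#' @export
behavior_series <- function(tracks, focal_id = "focal", frame_rate_hz = 10) {
  sel_f <- tracks$bee_id == focal_id
  if (!any(sel_f)) stopf("no rows for focal bee '%s'", focal_id)
  o_f <- order(tracks$frame[sel_f])
  f_frame <- tracks$frame[sel_f][o_f]
  f_t <- tracks$time_s[sel_f][o_f]
  f_x <- tracks$x_cm[sel_f][o_f]; f_y <- tracks$y_cm[sel_f][o_f]
  f_th <- tracks$theta_deg[sel_f][o_f]
  nf <- length(f_frame)
  dfr <- diff(f_frame)
  sp <- sqrt(diff(f_x)^2 + diff(f_y)^2) * frame_rate_hz
  sp[dfr != 1L] <- NA_real_
  speed <- c(0, sp)

  others <- sort(setdiff(unique(tracks$bee_id), focal_id))
  nb <- length(others)
  nn_dist <- rep(NA_real_, nf); nn_id <- rep(NA_character_, nf)
  nn2_dist <- rep(NA_real_, nf)
  bearing <- rep(NA_real_, nf); rel_axis <- rep(NA_real_, nf)
  if (nb > 0) {
    dmat <- matrix(NA_real_, nf, nb)
    othx <- matrix(NA_real_, nf, nb); othy <- matrix(NA_real_, nf, nb)
    othth <- matrix(NA_real_, nf, nb)
    for (j in seq_len(nb)) {
      sel <- tracks$bee_id == others[j]
      idx <- match(f_frame, tracks$frame[sel])
      ok <- !is.na(idx)
      bx <- tracks$x_cm[sel][idx[ok]]; by <- tracks$y_cm[sel][idx[ok]]
      othx[ok, j] <- bx; othy[ok, j] <- by
      othth[ok, j] <- tracks$theta_deg[sel][idx[ok]]
      dmat[ok, j] <- sqrt((bx - f_x[ok])^2 + (by - f_y[ok])^2)
    }
    has <- rowSums(!is.na(dmat)) > 0
    if (any(has)) {
      dwork <- dmat; dwork[is.na(dwork)] <- Inf
      jmin <- max.col(-dwork, ties.method = "first")
      rows <- which(has)
      pick <- cbind(rows, jmin[has])
      nn_dist[has] <- dwork[pick]
      nn_id[has] <- others[jmin[has]]
      bearing[has] <- wrap_deg(atan2(othy[pick] - f_y[has],
                                     othx[pick] - f_x[has]) * 180 / pi -
                                 f_th[has])
      rel_axis[has] <- relative_body_angle(f_th[has], othth[pick])
      if (nb >= 2) {
        dwork[pick] <- Inf
        jmin2 <- max.col(-dwork, ties.method = "first")
        d2 <- dwork[cbind(rows, jmin2[has])]
        d2[!is.finite(d2)] <- NA_real_
        nn2_dist[has] <- d2
      }
    }
  }
  out <- data.frame(
    frame = f_frame, time_s = f_t, speed_cm_s = speed,
    nn_dist_cm = nn_dist, nn_id = nn_id, nn2_dist_cm = nn2_dist,
    theta_deg = f_th, gravity_deg = orientation_to_gravity(f_th),
    bearing_deg = bearing, rel_axis_deg = rel_axis,
    stringsAsFactors = FALSE
  )
  attr(out, "frame_rate_hz") <- frame_rate_hz
  class(out) <- c("behavior_series", "data.frame")
  out
}
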
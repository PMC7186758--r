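# Event-aligned and covariate-resolved spike-rate analyses.

rate_bin_index <- function(rates, t) {
  bin_w <- attr(rates, "bin_w") %||% 0.1
  t0 <- attr(rates, "t0") %||% rates$t[1]
  round((t - t0) / bin_w) + 1
}

#' Perievent time histogram of relative spike rates
#'
#' For every event with a full `+/-half_span` context inside the recording,
#' the 100 ms rate bins spanning the context are extracted, each event's lag
#' vector is normalized by its own mean rate over the context (events with a
#' zero mean rate are dropped), and the normalized vectors are averaged
#' across events. Under this normalization the mean over lags of the mean
#' relative rate is exactly 1.
#'
#' @param rates a `rate_series` from [bin_spikes()] on the behavioral clock.
#' @param events event data.frame with a `t_sync_s` column.
#' @param half_span_s perievent half span, s (default 8).
#' @param normalize "per_event" (each event by its own context mean; default)
#'   or "grand" (all events by the grand mean rate of the series).
#' @return an object of class `peth`: list with `lag_s` (bin centers), `mean_rel`
#'   (mean relative rate per lag), `n_events`, `n_dropped` (no full context),
#'   `n_zero_rate` (zero-mean events dropped), and `per_event` (matrix).
#' @export
peth <- function(rates, events, half_span_s = 8,
                 normalize = c("per_event", "grand")) {
  normalize <- match.arg(normalize)
  bin_w <- attr(rates, "bin_w") %||% 0.1
  L <- round(half_span_s / bin_w)
  n <- nrow(rates)
  idx <- rate_bin_index(rates, events$t_sync_s)
  ok <- idx - L >= 1 & idx + L - 1 <= n
  n_dropped <- sum(!ok)
  idx <- idx[ok]
  if (length(idx) == 0) {
    stopf("no event has a full +/-%g s context inside the recording",
          half_span_s, class = "beesocial_neural_error")
  }
  mat <- t(vapply(idx, function(i) rates$rate[(i - L):(i + L - 1)],
                  numeric(2 * L)))
  if (normalize == "per_event") {
    mu <- rowMeans(mat)
    zero <- mu == 0
    mat <- mat[!zero, , drop = FALSE] / mu[!zero]
    n_zero <- sum(zero)
  } else {
    gm <- mean(rates$rate)
    if (gm == 0) stopf("grand mean rate is zero", class = "beesocial_neural_error")
    mat <- mat / gm
    n_zero <- 0L
  }
  if (nrow(mat) == 0) {
    stopf("all events were dropped (zero spike rate in context)",
          class = "beesocial_neural_error")
  }
  structure(
    list(lag_s = (seq_len(2 * L) - L - 0.5) * bin_w,
         mean_rel = colMeans(mat),
         n_events = nrow(mat), n_dropped = n_dropped, n_zero_rate = n_zero,
         bin_w = bin_w, normalize = normalize, per_event = mat),
    class = "peth"
  )
}

#' @export
print.peth <- function(x, ...) {
  cat(sprintf("<peth> %d events, %d lags of %g ms (+/-%g s), %s normalization\n",
              x$n_events, length(x$lag_s), 1000 * x$bin_w,
              max(x$lag_s) + x$bin_w / 2, x$normalize))
  if (x$n_dropped) cat(sprintf("  %d events dropped (incomplete context)\n", x$n_dropped))
  invisible(x)
}

#' Latency of the pre-event rate peak
#'
#' Smooths the perievent mean relative rate with a boxcar and returns the
#' lag of its maximum within the search interval before the event, as
#' positive seconds-before-event. When the histogram is flat (smoothed
#' maximum within 5% of the overall mean relative rate) there is no phasic
#' peak and `NA` is returned with `no_peak = TRUE`.
#'
#' @param p a [peth()].
#' @param search_s interval of lags searched, s (default `c(-4, 0)`).
#' @param smooth_s boxcar width, s (default 0.3).
#' @return list with `latency_s` (positive seconds before the event, or
#'   `NA`), `no_peak`, `peak_rel_rate`.
#' @export
peak_pre_event_latency <- function(p, search_s = c(-4, 0), smooth_s = 0.3) {
  k <- max(1, round(smooth_s / p$bin_w))
  if (k %% 2 == 0) k <- k + 1
  sm <- stats::filter(p$mean_rel, rep(1 / k, k), sides = 2)
  sm <- as.numeric(sm)
  half <- (k - 1) / 2
  # partial means at the edges so the search interval keeps full support
  for (i in seq_len(half)) {
    sm[i] <- mean(p$mean_rel[1:(i + half)])
    j <- length(sm) - i + 1
    sm[j] <- mean(p$mean_rel[(j - half):length(sm)])
  }
  in_search <- p$lag_s >= search_s[1] & p$lag_s <= search_s[2]
  if (!any(in_search)) stopf("search interval contains no lags")
  peak_val <- max(sm[in_search])
  if (peak_val < 1.05 * mean(p$mean_rel)) {
    return(list(latency_s = NA_real_, no_peak = TRUE, peak_rel_rate = peak_val))
  }
  lag_at_max <- p$lag_s[in_search][which.max(sm[in_search])]
  list(latency_s = -lag_at_max, no_peak = FALSE, peak_rel_rate = peak_val)
}

#' Spike-rate variance inside a state window
#'
#' The single "dark activity" parameter: the population variance (squared
#' differences from the mean, divided by the number of bins n, not n-1) of
#' the 100 ms spike rates inside the 4 s window, in Hz^2. It is independent
#' of the mean rate level and of the direction of rate changes.
#'
#' @param rates a `rate_series`.
#' @param t_start_s window start time(s), s.
#' @param window_s window length, s (default 4).
#' @return numeric vector of variances, one per window start.
#' @export
window_variance <- function(rates, t_start_s, window_s = 4) {
  bin_w <- attr(rates, "bin_w") %||% 0.1
  w <- round(window_s / bin_w)
  n <- nrow(rates)
  vapply(t_start_s, function(ts) {
    i0 <- rate_bin_index(rates, ts)
    i1 <- i0 + w - 1
    if (i0 < 1 || i1 > n) {
      stopf("window [%g, %g) s is not fully inside the recording",
            ts, ts + window_s, class = "beesocial_neural_error")
    }
    r <- rates$rate[i0:i1]
    mean((r - mean(r))^2)
  }, numeric(1))
}

#' Per-state spike-rate-variance samples from an event catalog
#'
#' @param rates a `rate_series`.
#' @param catalog an event catalog from [classify_all()].
#' @param window_s window length, s.
#' @return named list mapping each state present in the catalog to its
#'   numeric vector of window variances; windows not fully inside the
#'   recording are skipped (count in attribute `n_skipped`).
#' @export
variance_by_state <- function(rates, catalog, window_s = 4) {
  bin_w <- attr(rates, "bin_w") %||% 0.1
  w <- round(window_s / bin_w)
  n <- nrow(rates)
  i0 <- rate_bin_index(rates, catalog$t_start_s)
  ok <- i0 >= 1 & i0 + w - 1 <= n
  out <- lapply(split(catalog$t_start_s[ok], catalog$state[ok]),
                function(ts) window_variance(rates, ts, window_s))
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Decile analysis of spike rate versus nearest-bee distance
#'
#' Frames with a defined nearest-bee distance are sorted by spike rate and
#' split into 10 equal-count groups, group 1 holding the lowest and group 10
#' the highest rates; when the frame count is not divisible by 10 the
#' remainder is spread over the last groups (one extra frame each). With
#' 100 ms count bins, ties are massive (many bins share a count), and any
#' time-ordered tie-break would bias the tied part of each group toward one
#' end of the recording — which, since behavior is temporally
#' autocorrelated, invalidates the group comparison. Ties are therefore
#' broken by a deterministic integer hash of the frame index: reproducible,
#' but uncorrelated with time. Each group's distance distribution is summarized by
#' quartiles, and the distances of group 10 are compared with those of
#' group 1 by a rank-sum test.
#'
#' @param rates frame-wise spike rates, Hz.
#' @param distances_cm frame-wise nearest-bee distances, cm (`NA` = no other
#'   bee tracked; such frames are excluded).
#' @return list with `groups` (data.frame: group, n, rate ranges, distance
#'   quartiles), `test` (rank-sum of group 10 vs group 1 distances), and
#'   `group_index` (per kept frame).
#' @export
decile_distance_analysis <- function(rates, distances_cm) {
  if (length(rates) != length(distances_cm)) {
    stopf("rates and distances must be aligned")
  }
  keep <- which(!is.na(distances_cm) & !is.na(rates))
  n <- length(keep)
  if (n < 10) {
    stopf("need at least 10 frames with defined distance (got %d)", n,
          class = "beesocial_neural_error")
  }
  tie_hash <- (keep * 2654435761) %% 4294967296  # Knuth multiplicative hash
  o <- keep[order(rates[keep], tie_hash)]
  q <- n %/% 10
  r <- n %% 10
  sizes <- c(rep(q, 10 - r), rep(q + 1, r))
  grp <- rep(seq_len(10), times = sizes)
  groups <- do.call(rbind, lapply(seq_len(10), function(g) {
    idx <- o[grp == g]
    qs <- stats::quantile(distances_cm[idx], c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(idx),
               rate_min = min(rates[idx]), rate_max = max(rates[idx]),
               dist_q1 = qs[1], dist_median = qs[2], dist_q3 = qs[3])
  }))
  test <- rank_sum_test(distances_cm[o[grp == 10]], distances_cm[o[grp == 1]])
  gi <- rep(NA_integer_, length(rates))
  gi[o] <- grp
  list(groups = groups, test = test, group_index = gi)
}

#' Near/far spike-rate distributions split at a distance cut
#'
#' Splits frames at the distance cut (frames at exactly the cut count as
#' near) and reports the spike-rate distribution of each stratum for each
#' contiguous data quarter, so the stability of any distance effect over the
#' recording can be inspected.
#'
#' @param rates frame-wise spike rates, Hz.
#' @param distances_cm frame-wise nearest-bee distances, cm.
#' @param cut_cm distance cut, cm (default 5).
#' @return list with `summary` (data.frame: quarter, stratum, n, rate
#'   quartiles; empty strata are flagged with `empty = TRUE`) and
#'   `distributions` (nested list of the raw rate vectors).
#' @export
distance_split_profiles <- function(rates, distances_cm, cut_cm = 5) {
  if (length(rates) != length(distances_cm)) {
    stopf("rates and distances must be aligned")
  }
  quarters <- quarter_split(seq_along(rates))
  rows <- list(); dists <- list()
  for (qi in seq_len(4)) {
    idx <- quarters[[qi]]
    for (stratum in c("near", "far")) {
      sel <- if (stratum == "near") {
        idx[!is.na(distances_cm[idx]) & distances_cm[idx] <= cut_cm]
      } else {
        idx[!is.na(distances_cm[idx]) & distances_cm[idx] > cut_cm]
      }
      r <- rates[sel]
      empty <- length(r) == 0
      qs <- if (empty) rep(NA_real_, 3) else
        stats::quantile(r, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        quarter = qi, stratum = stratum, n = length(r), empty = empty,
        rate_q1 = qs[1], rate_median = qs[2], rate_q3 = qs[3])
      dists[[paste0("q", qi, "_", stratum)]] <- r
    }
  }
  list(summary = do.call(rbind, rows), distributions = dists)
}
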
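# Shared fixtures, built in code at test time.

# Build a track table from per-bee coordinate matrices (n x 2), all
# frame-aligned from frame 0 at 10 fps, body axis 0 unless given.
tracks_from_xy <- function(xy_list, theta = NULL, frame_rate_hz = 10) {
  n <- nrow(xy_list[[1]])
  ids <- names(xy_list)
  frames <- rep(seq_len(n) - 1L, length(ids))
  track_table(
    frame = frames,
    time_s = frames / frame_rate_hz,
    bee_id = rep(ids, each = n),
    x_cm = unlist(lapply(xy_list, function(m) m[, 1])),
    y_cm = unlist(lapply(xy_list, function(m) m[, 2])),
    theta_deg = if (is.null(theta)) rep(0, n * length(ids)) else
      unlist(theta),
    frame_rate_hz = frame_rate_hz
  )
}

# Stationary bee at (x, y) for n frames.
xy_still <- function(n, x = 5, y = 5) cbind(rep(x, n), rep(y, n))

# A stop -> walk trace along +x: still for n_still frames, then constant
# speed (cm/s) for the remaining frames.
xy_stop_go <- function(n_still, n_go, speed = 2, x0 = 5, y0 = 5,
                       frame_rate_hz = 10) {
  step <- speed / frame_rate_hz
  x <- c(rep(x0, n_still), x0 + cumsum(rep(step, n_go)))
  cbind(x, rep(y0, n_still + n_go))
}

# Partner approach along +x relative to a still focal at (fx, fy):
# distance 16 cm until frame j0, then closing 0.5 cm/frame down to 0.75 cm,
# holding, then retreating. Returns the partner coordinate matrix and the
# expected sync frame (0-based).
xy_approach <- function(n, j0, fx = 5, fy = 5) {
  d <- rep(16, n)
  closing <- pmax(16 - 0.5 * (seq_len(n) - j0 - 1), 0.75)
  sel <- seq_len(n) > j0
  d[sel] <- closing[sel]
  i_hold <- which(d <= 0.75)[1]
  if (!is.na(i_hold) && i_hold + 5 <= n) {
    ret <- 0.75 + 0.5 * seq_len(n - i_hold - 5)
    d[(i_hold + 6):n] <- pmin(ret, 16)
  }
  sync_frame <- j0 + 31  # first frame with d < 1 (d = 0.75)
  list(xy = cbind(fx + d, rep(fy, n)), sync_frame = sync_frame, d = d)
}

# One cached medium simulation shared across test files.
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(duration_s = 600, seed = 11, n_other_bees = 3)
      cache <<- c(simulate_recording(cfg), list(cfg = cfg))
    }
    cache
  }
})

# Brute-force rank-sum enumeration over all rank assignments (no ties).
brute_ranksum_p <- function(x, y, alternative = "two.sided") {
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  ws <- utils::combn(N, nx, FUN = sum)
  switch(alternative,
         less = mean(ws <= w_obs),
         greater = mean(ws >= w_obs),
         two.sided = {
           e <- nx * (N + 1) / 2
           mean(abs(ws - e) >= abs(w_obs - e) - 1e-12)
         })
}
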
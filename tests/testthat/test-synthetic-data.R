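no_effect_sigma <- c(alone = 0, random = 0, walking_onset = 0,
                     passive_contact = 0, active_contact = 0)

test_that("a colony without companions has no contacts and one trajectory", {
  sim <- simulate_colony(sim_config(duration_s = 60, n_other_bees = 0,
                                    seed = 3))
  expect_setequal(unique(sim$tracks$bee_id), "focal")
  expect_false(any(sim$truth$events$state %in%
                     c("passive_contact", "active_contact")))
})

test_that("simulation is reproducible under its seed", {
  cfg <- sim_config(duration_s = 120, seed = 21, n_other_bees = 2)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$tracks, b$tracks)
  expect_identical(as.numeric(a$spikes), as.numeric(b$spikes))
  expect_identical(a$truth$events, b$truth$events)
})

test_that("planted contact count follows the configured Poisson rate", {
  cfg <- sim_config(duration_s = 600, seed = 13,
                    approach_rate_passive_per_min = 1,
                    approach_rate_active_per_min = 1)
  sim <- simulate_colony(cfg)
  n_contacts <- sum(sim$truth$events$state %in%
                      c("passive_contact", "active_contact"))
  # 2 events/min for 600 s: Poisson(20) central 99% interval
  expect_gte(n_contacts, qpois(0.005, 20))
  expect_lte(n_contacts, qpois(0.995, 20))
})

test_that("the rate model reduces to its closed forms", {
  # all effects off: lambda is the constant baseline
  cfg <- sim_config(duration_s = 60, seed = 5, beta_dist_hz = 0,
                    alpha_hz = 0, sigma_state = no_effect_sigma)
  sim <- simulate_colony(cfg)
  lam <- compute_rate(sim$tracks, sim$truth, cfg)
  expect_true(all(lam$rate == cfg$baseline_hz))

  # distance kernel on a hand-built two-bee scene at the 3-4-5 distance
  tr <- tracks_from_xy(list(focal = xy_still(30, 5, 5),
                            bee01 = xy_still(30, 8, 9)))
  truth <- structure(list(
    events = data.frame(state = character(0), t_start_s = numeric(0),
                        t_sync_s = numeric(0), partner_id = character(0)),
    multipliers = data.frame(event = integer(0), state = character(0),
                             frame0 = integer(0), n_frames = integer(0),
                             m = numeric(0)),
    n_frames = 30L, frame_rate_hz = 10, duration_s = 3),
    class = "ground_truth")
  cfg2 <- sim_config(duration_s = 30, baseline_hz = 2, beta_dist_hz = 8,
                     dist_kernel_d0_cm = 3, alpha_hz = 0,
                     sigma_state = no_effect_sigma)
  lam2 <- compute_rate(tr, truth, cfg2)
  expect_equal(lam2$rate, rep(2 + 8 * exp(-5 / 3), 30), tolerance = 1e-9)

  # phasic bump: closed-form raised cosine peaking lead_s before the contact
  truth$events <- data.frame(state = "active_contact", t_start_s = 0.5,
                             t_sync_s = 2.5, partner_id = "bee01")
  cfg3 <- sim_config(duration_s = 30, baseline_hz = 2, beta_dist_hz = 0,
                     alpha_hz = 6, lead_s = 1.2, bump_width_s = 1,
                     sigma_state = no_effect_sigma)
  lam3 <- compute_rate(tr, truth, cfg3)
  peak_t <- 2.5 - 1.2
  g <- function(u) ifelse(abs(u - peak_t) <= 0.5,
                          0.5 * (1 + cos(2 * pi * (u - peak_t))), 0)
  expect_equal(lam3$rate, 2 + 6 * g(lam3$t), tolerance = 1e-9)
  expect_true(all(lam3$rate[lam3$t > 2.5] == 2))  # nothing after the contact
})

test_that("thinning produces Poisson statistics and honors zero-rate spans", {
  empty <- simulate_spikes(data.frame(t = numeric(0), count = numeric(0),
                                      rate = numeric(0)), seed = 1)
  expect_length(as.numeric(empty), 0)

  lam0 <- structure(data.frame(t = seq(0, 9.9, 0.1), count = NA, rate = 0),
                    bin_w = 0.1, t0 = 0, class = c("rate_series", "data.frame"))
  expect_length(as.numeric(simulate_spikes(lam0, seed = 2)), 0)

  # piecewise zero-then-20 Hz: no spikes may fall in the silent half
  lam_pw <- structure(data.frame(t = seq(0, 99.9, 0.1), count = NA,
                                 rate = rep(c(0, 20), each = 500)),
                      bin_w = 0.1, t0 = 0,
                      class = c("rate_series", "data.frame"))
  sp <- as.numeric(simulate_spikes(lam_pw, seed = 3))
  expect_true(all(sp >= 50))

  # constant-rate train: inter-spike intervals are exponential (KS, 1% level)
  lam10 <- structure(data.frame(t = seq(0, 999.9, 0.1), count = NA, rate = 10),
                     bin_w = 0.1, t0 = 0, class = c("rate_series", "data.frame"))
  tr <- as.numeric(simulate_spikes(lam10, seed = 4))
  expect_gt(length(tr), 9000)
  ks <- suppressWarnings(stats::ks.test(diff(tr), "pexp", 10))
  expect_gt(ks$p.value, 0.01)
})

test_that("increasing the distance coefficient raises close-proximity rates", {
  cfg0 <- sim_config(duration_s = 400, seed = 17, alpha_hz = 0,
                     sigma_state = no_effect_sigma, beta_dist_hz = 0)
  sim <- simulate_colony(cfg0)
  bhv <- behavior_series(sim$tracks)
  close <- which(!is.na(bhv$nn_dist_cm) & bhv$nn_dist_cm < 5)
  expect_gt(length(close), 10)
  means <- sapply(c(0, 5, 10), function(beta) {
    cfg <- cfg0; cfg$beta_dist_hz <- beta
    mean(compute_rate(sim$tracks, sim$truth, cfg)$rate[close])
  })
  expect_true(all(diff(means) > 0))
})

test_that("planted contacts satisfy the detector's geometric preconditions", {
  sim <- cached_sim()
  bhv <- behavior_series(sim$tracks)
  contacts <- sim$truth$events[sim$truth$events$state %in%
                                 c("passive_contact", "active_contact"), ]
  expect_gt(nrow(contacts), 0)
  for (k in seq_len(nrow(contacts))) {
    i <- round(contacts$t_sync_s[k] * 10) + 1
    expect_lt(bhv$nn_dist_cm[i], 1)                   # partner in contact
    expect_false(isTRUE(bhv$nn2_dist_cm[i] < 1))      # and only one bee
    d0 <- bhv$nn_dist_cm[i - 20]
    expect_true(is.na(d0) || d0 > 10)                 # alone at window start
  }
  expect_true(all(sim$truth$lambda$rate >= 0))
})

test_that("fixtures round-trip and are byte-identical across runs", {
  cfg <- sim_config(duration_s = 60, seed = 9, n_other_bees = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- make_fixture(cfg, d1)
  p2 <- make_fixture(cfg, d2)
  expect_true(all(file.exists(p1)))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  back <- read_tracks(p1[["tracks"]])
  expect_equal(nrow(back), 600 * 3)  # 60 s at 10 fps, focal + 2 others
  expect_equal(sum(back$bee_id == "focal"), 600)
  rec <- simulate_recording(cfg)
  expect_equal(back$x_cm, rec$tracks$x_cm)
  expect_equal(as.numeric(read_spikes(p1[["spikes"]])),
               as.numeric(rec$spikes))
})
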
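test_that("walking speed is displacement times frame rate", {
  still <- tracks_from_xy(list(focal = xy_still(20)))
  expect_true(all(walking_speed(still)$speed_cm_s == 0))
  # 1 mm per 100 ms frame = 1 cm/s
  steps <- tracks_from_xy(list(focal = cbind(5 + cumsum(rep(0.1, 20)), 5)))
  sp <- walking_speed(steps)
  expect_equal(sp$speed_cm_s[-1], rep(1, 19), tolerance = 1e-9)
  expect_equal(sp$speed_cm_s[1], 0)
  one <- tracks_from_xy(list(focal = xy_still(1)))
  expect_warning(out <- walking_speed(one), "fewer than 2")
  expect_equal(nrow(out), 0)
})

test_that("speed is invariant under rigid translation of the arena", {
  sim <- cached_sim()
  focal <- sim$tracks[sim$tracks$bee_id == "focal", ]
  shifted <- focal
  shifted$x_cm <- shifted$x_cm + 7.3
  shifted$y_cm <- shifted$y_cm - 2.1
  expect_equal(walking_speed(shifted)$speed_cm_s,
               walking_speed(focal)$speed_cm_s)
})

test_that("the simulated walking speed recovers the configured mean", {
  cfg <- sim_config(duration_s = 600, seed = 31,
                    approach_rate_passive_per_min = 0,
                    approach_rate_active_per_min = 0)
  sim <- simulate_colony(cfg)
  sp <- walking_speed(sim$tracks[sim$tracks$bee_id == "focal", ])
  go <- sim$truth$focal_moving
  v_hat <- mean(sp$speed_cm_s[go][-1], na.rm = TRUE)
  expect_lt(abs(v_hat - cfg$speed_mean_cm_s) / cfg$speed_mean_cm_s, 0.05)
})

test_that("nearest-bee distance follows Euclidean geometry and the tie rule", {
  tr <- tracks_from_xy(list(focal = xy_still(5, 0, 0),
                            bee01 = xy_still(5, 3, 4)))
  nn <- nearest_bee(tr)
  expect_equal(nn$nn_dist_cm, rep(5, 5))
  expect_equal(nn$nn_id, rep("bee01", 5))
  # equidistant bees: the lexicographically smaller id wins
  tr2 <- tracks_from_xy(list(focal = xy_still(3, 0, 0),
                             beeB = xy_still(3, 0, 2),
                             beeA = xy_still(3, 2, 0)))
  expect_equal(nearest_bee(tr2)$nn_id, rep("beeA", 3))
  # with exactly two bees each is the other's nearest
  expect_equal(nearest_bee(tr, focal_id = "bee01")$nn_id, rep("focal", 5))
})

test_that("nearest-bee search matches a brute-force all-pairs scan", {
  set.seed(12)
  n <- 40
  xy <- lapply(1:5, function(i) cbind(runif(n, 0, 55), runif(n, 0, 55)))
  names(xy) <- c("focal", "b1", "b2", "b3", "b4")
  tr <- tracks_from_xy(xy)
  nn <- nearest_bee(tr)
  for (i in seq_len(n)) {
    d <- sapply(2:5, function(b) sqrt(sum((xy[[b]][i, ] - xy[[1]][i, ])^2)))
    expect_equal(nn$nn_dist_cm[i], min(d))
    expect_equal(nn$nn_id[i], names(xy)[-1][which.min(d)])
    expect_equal(nn$nn2_dist_cm[i], sort(d)[2])
  }
})

test_that("gravity-relative orientation anchors 180 degrees to down-slope", {
  expect_equal(orientation_to_gravity(270), 180)  # pointing down-slope
  expect_equal(orientation_to_gravity(90), 0)     # pointing up-slope
  expect_equal(orientation_to_gravity(0), 270)    # cross-slope
  expect_equal(orientation_to_gravity(180), 90)   # the other cross-slope
})

test_that("approach bearing is measured from the focal body axis", {
  # partner due north of a focal bee whose axis points east: bearing 90
  tr <- tracks_from_xy(list(focal = xy_still(3, 0, 0),
                            bee01 = xy_still(3, 0, 5)))
  expect_equal(approach_bearing(tr)$bearing_deg, rep(90, 3))
  # same geometry seen from an axis pointing north: bearing 0
  tr2 <- tracks_from_xy(list(focal = xy_still(3, 0, 0),
                             bee01 = xy_still(3, 0, 5)),
                        theta = list(rep(90, 3), rep(0, 3)))
  expect_equal(approach_bearing(tr2)$bearing_deg, rep(0, 3))
})

test_that("relative body-axis angle is the wrapped difference", {
  expect_equal(relative_body_angle(45, 45), 0)     # parallel
  expect_equal(relative_body_angle(45, 225), 180)  # antiparallel
  expect_equal(relative_body_angle(30, 300), 270)
})

test_that("angular rate profiles bin, rotate and validate correctly", {
  # uniform rate at all angles: flat profile
  a <- seq(0, 359, by = 1)
  prof <- angular_rate_profile(a, rep(4, length(a)))
  expect_equal(prof$mean_rate, rep(4, 36))
  # rate mass only at 5 degrees
  prof2 <- angular_rate_profile(c(5, 100), c(7, 0))
  expect_equal(prof2$mean_rate[1], 7)
  expect_equal(prof2$mean_rate[11], 0)
  expect_true(all(is.na(prof2$mean_rate[-c(1, 11)])))
  # rotating all angles by 30 degrees shifts the profile by 3 bins
  set.seed(3)
  ang <- runif(500, 0, 360); r <- rexp(500)
  p0 <- angular_rate_profile(ang, r)$mean_rate
  p30 <- angular_rate_profile((ang + 30) %% 360, r)$mean_rate
  expect_equal(p30, c(p0[34:36], p0[1:33]))
  expect_error(angular_rate_profile(ang, r, bin_deg = 7),
               class = "beesocial_config_error")
})

test_that("angle-independent rates pass the Rayleigh test almost always", {
  # low per-bin spike probability, as in 100 ms bins at a few Hz, so spikes
  # are effectively independent angle observations
  set.seed(14)
  ps <- replicate(100, {
    ang <- runif(10000, 0, 360)
    w <- rpois(10000, 0.1)
    rayleigh_test(ang, w)$p.value
  })
  expect_gte(mean(ps > 0.05), 0.90)
})

test_that("quarter splits are contiguous, near-equal and exhaustive", {
  q <- quarter_split(1:400)
  expect_equal(lengths(q), rep(100, 4))
  q2 <- quarter_split(1:403)
  expect_equal(lengths(q2), c(100, 100, 100, 103))
  expect_equal(unlist(q2), 1:403)
  expect_error(quarter_split(1:3), "at least 4")
})

test_that("focal-versus-companion speed comparison detects only real shifts", {
  # identical trajectories, translated: z = 0, p = 1 (dyadic steps keep the
  # speed multisets exactly equal under translation)
  set.seed(41)
  steps <- matrix(sample(c(-0.25, 0, 0.25), 800, replace = TRUE), ncol = 2)
  path <- cbind(10 + cumsum(steps[, 1]), 20 + cumsum(steps[, 2]))
  tr_same <- tracks_from_xy(list(focal = path,
                                 bee01 = sweep(path, 2, c(25, 5), "+")))
  res <- compare_focal_vs_others_speed(tr_same)
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p.value, 1)
  # doubled speeds: decisively different at n = 1000 frames
  set.seed(8)
  stp <- cbind(rnorm(1000, 0, 0.15), rnorm(1000, 0, 0.15))
  tr_diff <- tracks_from_xy(list(
    focal = cbind(25 + cumsum(2 * stp[, 1]), 25 + cumsum(2 * stp[, 2])),
    bee01 = cbind(45 + cumsum(stp[, 1]), 45 + cumsum(stp[, 2]))))
  expect_lt(compare_focal_vs_others_speed(tr_diff)$p.value, 0.001)
  expect_error(compare_focal_vs_others_speed(
    tracks_from_xy(list(focal = xy_still(10)))),
    class = "beesocial_stats_error")
})
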
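acfg <- analysis_config()

test_that("movement flags implement the 1 mm / 2 s stillness rule", {
  mf0 <- movement_flags(rep(0, 60), acfg)
  expect_false(any(mf0$moving))
  expect_true(all(mf0$still_from[1:41]))
  mf2 <- movement_flags(rep(2, 60), acfg)
  expect_true(all(mf2$moving))
  expect_false(any(mf2$still_from[1:41]))
  # 0.4 mm total drift over 2 s stays below the 1 mm stillness threshold
  mf3 <- movement_flags(rep(0.02, 20), acfg)  # 0.002 cm/frame * 20 = 0.04 cm
  expect_true(mf3$still_from[1])
  # 1.2 mm over 2 s does not
  mf4 <- movement_flags(rep(0.06, 20), acfg)
  expect_false(mf4$still_from[1])
})

test_that("alone windows tile distance runs with the strict 10 cm rule", {
  # a lone focal bee for 60 s yields 15 four-second windows
  bhv <- behavior_series(tracks_from_xy(list(focal = xy_still(600))))
  ev <- detect_alone(bhv, acfg)
  expect_equal(nrow(ev), 15)
  expect_equal(ev$t_start_s, seq(0, 56, by = 4))
  expect_equal(ev$t_sync_s, ev$t_start_s + 2)
  # partner permanently at 5 cm: never alone
  bhv2 <- behavior_series(tracks_from_xy(list(focal = xy_still(600),
                                              bee01 = xy_still(600, 10, 5))))
  expect_equal(nrow(detect_alone(bhv2, acfg)), 0)
  # partner at 10.5 cm: strictly greater than 10 cm counts as alone
  bhv3 <- behavior_series(tracks_from_xy(list(focal = xy_still(600),
                                              bee01 = xy_still(600, 15.5, 5))))
  expect_equal(nrow(detect_alone(bhv3, acfg)), 15)
})

test_that("walking onsets need 2 s of stillness then 2 s of walking", {
  # stop 2.5 s then walk 3 s: exactly one onset, at the first moving frame
  tr <- tracks_from_xy(list(focal = xy_stop_go(25, 30)))
  bhv <- behavior_series(tr)
  ev <- detect_walking_onset(bhv, acfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$t_sync_s, 2.5)
  # continuous walking: no onset
  tr2 <- tracks_from_xy(list(focal = xy_stop_go(0, 60)))
  expect_equal(nrow(detect_walking_onset(behavior_series(tr2), acfg)), 0)
  # stillness of only 1.9 s: no onset
  tr3 <- tracks_from_xy(list(focal = xy_stop_go(19, 41)))
  expect_equal(nrow(detect_walking_onset(behavior_series(tr3), acfg)), 0)
})

test_that("contacts classify passive and active and reject crowded syncs", {
  n <- 120
  # passive: focal still for the whole window while a partner closes in
  ap <- xy_approach(n, j0 = 40)
  bhv_p <- behavior_series(tracks_from_xy(list(focal = xy_still(n),
                                               bee01 = ap$xy)))
  ev_p <- detect_contacts(bhv_p, acfg)
  expect_equal(nrow(ev_p), 1)
  expect_equal(ev_p$state, "passive_contact")
  expect_equal(ev_p$t_sync_s, ap$sync_frame / 10)
  expect_equal(ev_p$partner_id, "bee01")

  # active: focal starts walking toward the partner 0.5 s before contact
  sync <- ap$sync_frame + 1  # 0-based frame -> row index
  fx <- rep(5, n)
  walk_rows <- (sync - 5):(sync + 25)
  fx[walk_rows] <- 5 + 0.2 * seq_along(walk_rows)
  fx[(sync + 26):n] <- fx[sync + 25]
  focal_xy <- cbind(fx, rep(5, n))
  partner_xy <- cbind(fx + ap$d, rep(5, n))
  bhv_a <- behavior_series(tracks_from_xy(list(focal = focal_xy,
                                               bee01 = partner_xy)))
  ev_a <- detect_contacts(bhv_a, acfg)
  expect_equal(nrow(ev_a), 1)
  expect_equal(ev_a$state, "active_contact")

  # two bees simultaneously inside the contact radius: event rejected
  bhv_c <- behavior_series(tracks_from_xy(list(
    focal = xy_still(n), bee01 = ap$xy,
    bee02 = cbind(ap$xy[, 1], 5 + 0.3))))
  ev_c <- detect_contacts(bhv_c, acfg)
  expect_equal(nrow(ev_c), 0)
  expect_equal(attr(ev_c, "n_rejected_crowded"), 1)
})

test_that("random windows are uniform, seeded and count well-behaved", {
  expect_equal(nrow(sample_random_windows(0, 100, 0, acfg, 1)), 0)
  a <- sample_random_windows(0, 100, 25, acfg, seed = 42)
  b <- sample_random_windows(0, 100, 25, acfg, seed = 42)
  expect_identical(a, b)
  expect_true(all(a$t_start_s >= 0 & a$t_start_s <= 96))
  big <- sample_random_windows(0, 1000, 10000, acfg, seed = 7)
  ks <- suppressWarnings(stats::ks.test(big$t_start_s, "punif", 0, 996))
  expect_gt(ks$p.value, 0.01)
})

test_that("the catalog recovers every planted event with nothing spurious", {
  sim <- cached_sim()
  det <- run_detect(sim$tracks, acfg, seed = sim$cfg$seed)
  truth <- sim$truth$events
  for (st in c("alone", "walking_onset", "passive_contact", "active_contact")) {
    tt <- sort(truth$t_sync_s[truth$state == st])
    dd <- sort(det$catalog$t_sync_s[det$catalog$state == st])
    expect_equal(dd, tt, info = st)
  }
  expect_equal(sum(det$catalog$state == "random"),
               sum(det$catalog$state == "passive_contact"))
})

test_that("no contact is simultaneously passive and active", {
  sim <- cached_sim()
  det <- run_detect(sim$tracks, acfg, seed = 1)
  contacts <- det$catalog[det$catalog$state %in%
                            c("passive_contact", "active_contact"), ]
  expect_false(any(duplicated(contacts$t_sync_s)))
})

test_that("shrinking the alone radius never loses alone windows", {
  sim <- cached_sim()
  bhv <- behavior_series(sim$tracks)
  n10 <- nrow(detect_alone(bhv, analysis_config(alone_radius_cm = 10)))
  n8 <- nrow(detect_alone(bhv, analysis_config(alone_radius_cm = 8)))
  expect_gte(n8, n10)
})

test_that("catalogs are stable under re-runs and round-trip as CSV", {
  sim <- cached_sim()
  c1 <- run_detect(sim$tracks, acfg, seed = 5)$catalog
  c2 <- run_detect(sim$tracks, acfg, seed = 5)$catalog
  expect_identical(c1, c2)
  p <- withr::local_tempfile(fileext = ".csv")
  write_events(c1, p)
  back <- read_events(p)
  expect_equal(back$t_sync_s, c1$t_sync_s)
  expect_equal(back$state, c1$state)
})
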
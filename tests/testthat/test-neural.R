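make_rates <- function(rate_vec, bin_w = 0.1) {
  structure(data.frame(t = (seq_along(rate_vec) - 1) * bin_w,
                       count = rate_vec * bin_w, rate = rate_vec),
            bin_w = bin_w, t0 = 0, class = c("rate_series", "data.frame"))
}

test_that("perievent histograms normalize per event to mean 1", {
  rates <- make_rates(rep(10, 400))
  ev <- data.frame(t_sync_s = 20)
  p <- peth(rates, ev)
  expect_equal(p$mean_rel, rep(1, 160))
  expect_equal(p$lag_s[1], -7.95)
  expect_equal(p$lag_s[160], 7.95)
  expect_equal(mean(p$mean_rel), 1)
  # events without a full context are dropped and counted
  p2 <- peth(rates, data.frame(t_sync_s = c(20, 3, 39)))
  expect_equal(p2$n_events, 1)
  expect_equal(p2$n_dropped, 2)
  expect_error(peth(rates, data.frame(t_sync_s = 3)),
               class = "beesocial_neural_error")
})

test_that("a planted bump elevates the histogram only around its support", {
  cfg <- sim_config(duration_s = 1500, seed = 23,
                    approach_rate_passive_per_min = 0,
                    approach_rate_active_per_min = 2,
                    alpha_hz = 15, beta_dist_hz = 0, lead_s = 1.2,
                    sigma_state = c(alone = 0, random = 0, walking_onset = 0,
                                    passive_contact = 0, active_contact = 0))
  rec <- simulate_recording(cfg)
  det <- run_detect(rec$tracks, seed = cfg$seed)
  rates <- bin_spikes(rec$spikes, 0, cfg$duration_s)
  ev <- det$catalog[det$catalog$state == "active_contact", ]
  expect_gt(nrow(ev), 30)
  p <- peth(rates, ev)
  inside <- p$lag_s > -1.7 & p$lag_s < -0.7     # bump support
  outside <- p$lag_s < -2.5 | p$lag_s > 1
  expect_gt(max(p$mean_rel[inside]), 1.5)
  # away from the bump the histogram is flat up to sampling noise
  nu_bar <- mean(rates$rate) * 0.1
  expect_lt(max(abs(p$mean_rel[outside] - 1)),
            4.5 / sqrt(p$n_events * nu_bar))
  # and the peak latency recovers the planted lead
  lat <- peak_pre_event_latency(p)
  expect_false(lat$no_peak)
  expect_lt(abs(lat$latency_s - 1.2), 0.2)
})

test_that("a flat histogram yields the no-peak marker", {
  rates <- make_rates(rep(10, 400))
  p <- peth(rates, data.frame(t_sync_s = c(15, 20, 25)))
  lat <- peak_pre_event_latency(p)
  expect_true(lat$no_peak)
  expect_true(is.na(lat$latency_s))
})

test_that("window variance is the population variance of the 40 bin rates", {
  expect_equal(window_variance(make_rates(rep(7, 100)), 2), 0)
  alternating <- make_rates(rep(c(0, 20), 50))
  expect_equal(window_variance(alternating, 0), 100)
  expect_error(window_variance(make_rates(rep(1, 30)), 0),
               class = "beesocial_neural_error")
})

test_that("planted state-variance ordering shows up in the samples", {
  cfg <- sim_config(duration_s = 1200, seed = 29,
                    approach_rate_passive_per_min = 1.2,
                    approach_rate_active_per_min = 1.2,
                    alpha_hz = 0, beta_dist_hz = 0,
                    sigma_state = c(alone = 0, random = 0, walking_onset = 0.3,
                                    passive_contact = 0.3, active_contact = 1))
  rec <- simulate_recording(cfg)
  det <- run_detect(rec$tracks, seed = cfg$seed)
  rates <- bin_spikes(rec$spikes, 0, cfg$duration_s)
  vs <- variance_by_state(rates, det$catalog)
  expect_gt(median(vs$active_contact), median(vs$random))
  expect_gt(median(vs$active_contact), median(vs$passive_contact))
})

test_that("decile groups are equal-count with the remainder spread at the top", {
  set.seed(5)
  d <- decile_distance_analysis(rpois(100, 3) * 10, runif(100, 0, 40))
  expect_equal(d$groups$n, rep(10, 10))
  d2 <- decile_distance_analysis(rpois(103, 3) * 10, runif(103, 0, 40))
  expect_equal(d2$groups$n, c(rep(10, 7), 11, 11, 11))
  expect_equal(sum(d2$groups$n), 103)
  # every kept frame lands in exactly one group
  expect_equal(sum(!is.na(d2$group_index)), 103)
  expect_error(decile_distance_analysis(1:5, rep(1, 5)),
               class = "beesocial_neural_error")
})

test_that("rates rise monotonically toward the top decile groups", {
  set.seed(6)
  r <- rpois(1000, 2) * 10
  d <- decile_distance_analysis(r, runif(1000))
  expect_true(all(diff(d$groups$rate_min) >= 0))
  expect_true(all(d$groups$rate_max[-10] <= d$groups$rate_min[-1] + 1e-9))
})

test_that("the 5 cm split partitions frames and flags empty strata", {
  rates <- rep(5, 100)
  near_only <- distance_split_profiles(rates, rep(2, 100))
  s <- near_only$summary
  expect_true(all(s$empty[s$stratum == "far"]))
  expect_true(all(!s$empty[s$stratum == "near"]))
  # distance exactly at the cut counts as near
  mix <- distance_split_profiles(rates, rep(c(5, 6), 50))
  sm <- mix$summary
  expect_equal(sum(sm$n[sm$stratum == "near"]), 50)
  expect_equal(sum(sm$n), 100)  # split-then-merge covers every frame
})
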
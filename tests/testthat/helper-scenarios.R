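# Study-condition scenarios for the recovery checks. Each function runs the
# full pipeline (simulate -> detect -> analyze) under one planted condition.

zero_sigma <- c(alone = 0, random = 0, walking_onset = 0,
                passive_contact = 0, active_contact = 0)

# Planted variance modulation: sigma(active) = 1 versus sigma(random) = 0.
# Returns the rank-sum p-value of the active-vs-random variance comparison
# at 50 windows per state.
variance_power_run <- function(seed) {
  cfg <- sim_config(duration_s = 3600, seed = seed,
                    approach_rate_passive_per_min = 1.1,
                    approach_rate_active_per_min = 1.1,
                    alpha_hz = 0, beta_dist_hz = 0,
                    sigma_state = c(alone = 0, random = 0,
                                    walking_onset = 0.3,
                                    passive_contact = 0.3,
                                    active_contact = 1))
  rec <- simulate_recording(cfg)
  det <- run_detect(rec$tracks, seed = cfg$seed)
  rates <- bin_spikes(rec$spikes, 0, cfg$duration_s)
  vs <- variance_by_state(rates, det$catalog)
  vs <- lapply(vs, function(v) v[seq_len(min(50, length(v)))])
  tab <- pairwise_variance_comparisons(vs)
  tab$p[(tab$state1 == "active_contact" & tab$state2 == "random") |
          (tab$state2 == "active_contact" & tab$state1 == "random")]
}

# Equal sigmas everywhere: TRUE when any of the six Bonferroni-corrected
# pairs comes out significant (a family-wise false positive).
variance_null_run <- function(seed) {
  cfg <- sim_config(duration_s = 1200, seed = seed,
                    approach_rate_passive_per_min = 1.5,
                    approach_rate_active_per_min = 1.5,
                    alpha_hz = 0, beta_dist_hz = 0, sigma_state = zero_sigma)
  rec <- simulate_recording(cfg)
  det <- run_detect(rec$tracks, seed = cfg$seed)
  rates <- bin_spikes(rec$spikes, 0, cfg$duration_s)
  vs <- variance_by_state(rates, det$catalog)
  tab <- pairwise_variance_comparisons(vs)
  any(tab$tested & tab$p <= bonferroni_threshold(0.05, 6))
}

# Planted pre-contact bump: recover the peak latency from >= 60 active
# contacts.
latency_run <- function(lead, seed) {
  cfg <- sim_config(duration_s = 2700, seed = seed,
                    approach_rate_passive_per_min = 0,
                    approach_rate_active_per_min = 2,
                    alpha_hz = 15, baseline_hz = 5, beta_dist_hz = 0,
                    lead_s = lead, sigma_state = zero_sigma)
  rec <- simulate_recording(cfg)
  det <- run_detect(rec$tracks, seed = cfg$seed)
  rates <- bin_spikes(rec$spikes, 0, cfg$duration_s)
  ev <- det$catalog[det$catalog$state == "active_contact", ]
  p <- peth(rates, ev)
  c(n = nrow(ev), latency = peak_pre_event_latency(p)$latency_s)
}

# Distance-coupled rate (or its null): p-value of the top-versus-bottom
# spike-rate-decile distance comparison on 10^4 frames.
decile_run <- function(seed, beta) {
  cfg <- sim_config(duration_s = 1000, seed = seed,
                    approach_rate_passive_per_min = 2,
                    approach_rate_active_per_min = 2,
                    alpha_hz = 0, beta_dist_hz = beta,
                    sigma_state = zero_sigma)
  rec <- simulate_recording(cfg)
  bhv <- behavior_series(rec$tracks)
  rates <- bin_spikes(rec$spikes, 0, cfg$duration_s)
  decile_distance_analysis(rates$rate, bhv$nn_dist_cm)$test$p.value
}

# Noise-free planted fixture: per-state detector precision and recall
# against ground truth (sync times compared exactly).
fidelity_run <- function(seed) {
  cfg <- sim_config(duration_s = 600, seed = seed, n_other_bees = 3)
  sim <- simulate_colony(cfg)
  det <- run_detect(sim$tracks, seed = cfg$seed)
  truth <- sim$truth$events
  out <- list()
  for (st in c("alone", "walking_onset", "passive_contact",
               "active_contact")) {
    tt <- truth$t_sync_s[truth$state == st]
    dd <- det$catalog$t_sync_s[det$catalog$state == st]
    hits <- sum(round(dd * 10) %in% round(tt * 10))
    out[[st]] <- c(precision = if (length(dd)) hits / length(dd) else NA,
                   recall = if (length(tt)) hits / length(tt) else NA,
                   n = length(tt))
  }
  out$random_count_matched <-
    sum(det$catalog$state == "random") ==
    sum(det$catalog$state == "passive_contact")
  out
}

# Homogeneous-Poisson control: maximum absolute deviation of the perievent
# histogram from 1, and its theoretical 4/sqrt(n nu) bound.
peth_null_run <- function(seed, n_events = 100) {
  cfg <- sim_config(duration_s = 800, seed = seed, baseline_hz = 10,
                    approach_rate_passive_per_min = 0,
                    approach_rate_active_per_min = 0,
                    alpha_hz = 0, beta_dist_hz = 0, sigma_state = zero_sigma)
  rec <- simulate_recording(cfg)
  rates <- bin_spikes(rec$spikes, 0, cfg$duration_s)
  ev <- sample_random_windows(8, cfg$duration_s - 8, n_events,
                              seed = seed + 1)
  p <- peth(rates, ev)
  nu_bar <- mean(rates$rate) * 0.1
  c(max_dev = max(abs(p$mean_rel - 1)),
    bound = 4 / sqrt(p$n_events * nu_bar), n = p$n_events)
}
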
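# beesocial

Social-state detection and single-unit spike-rate analysis for a freely
behaving honeybee.

A honeybee carrying a chronic extracellular electrode walks freely in an
observation hive (55 cm × 55 cm wax floor, tilted 17° to the horizontal)
among untethered nest mates while one mushroom-body extrinsic neuron — an
output neuron of the insect brain's multimodal integration center — is
recorded. `beesocial` implements the full analysis chain relating that
unit's activity to the bee's self-initiated behavior, for
behavioral-neuroscience users with multi-animal tracking tables and sorted
spike times:

* **I/O on the behavioral clock** — tracking CSV and spike-time readers and
  writers; spikes binned in half-open 100 ms bins aligned to the 10 Hz
  frame grid (`read_tracks()`, `read_spikes()`, `bin_spikes()`).
* **Behavioral covariates** — walking speed, nearest-bee distance,
  body-axis orientation relative to gravity (180° = down-slope) and
  relative to the closest bee (`behavior_series()`).
* **Social states** — each 4 s window, synchronized at its 2 s mark, is
  classified as *alone* (no bee within 10 cm), *walking onset* (< 1 mm of
  motion for 2 s, then ≥ 2 s continuous walking), *passive contact* /
  *active contact* (alone beforehand, exactly one bee crossing 1 cm at the
  sync mark, split by whether the focal bee initiated walking in the last
  second before contact), plus count-matched *random* controls
  (`classify_all()`).
* **Event-aligned rate analyses** — perievent time histograms of relative
  spike rate over ±8 s (`peth()`), the pre-contact peak latency
  (`peak_pre_event_latency()`), the within-window spike-rate variance
  (population variance of the 40 bin rates, `window_variance()`), spike-rate
  deciles versus nearest-bee distance (`decile_distance_analysis()`), and
  the 5 cm near/far split per data quarter.
* **Statistics** — Wilcoxon rank-sum (exact for small samples, tie-corrected
  normal otherwise), the spike-weighted Rayleigh test of circular
  uniformity, and Bonferroni-corrected pairwise state comparisons at the
  α/6 star levels 0.0083 / 0.0017 / 0.00083
  (`rank_sum_test()`, `rayleigh_test()`, `pairwise_variance_comparisons()`).
* **A synthetic colony generator** — stop/go random-walk locomotion,
  scripted approach episodes planting passive and active contacts, and an
  inhomogeneous-Poisson unit whose rate is
  `λ(t) = [β₀ + β_d·exp(−d(t)/d₀) + α·g(t)]·m(t)`
  (distance kernel, pre-contact bump peaking `lead_s` before contact,
  state-dependent log-normal rate multipliers), with complete ground truth
  (`simulate_recording()`). Every downstream stage is tested by recovering
  these planted parameters.

The methods vignette (`vignettes/methods.Rmd`) documents the models,
thresholds, numerical conventions and the generator's assumptions and
limits.

## Worked example

Simulate half an hour of colony life with planted effects, detect the
social states, and run the analyses:

```r
library(beesocial)

cfg <- sim_config(duration_s = 1800, seed = 4, n_other_bees = 4,
                  approach_rate_passive_per_min = 1.2,
                  approach_rate_active_per_min = 1.2)
rec <- simulate_recording(cfg)          # tracks + spikes + ground truth
det <- run_detect(rec$tracks, seed = cfg$seed)
table(det$catalog$state)
#>  active_contact           alone passive_contact          random   walking_onset
#>              32             348              37              37              86

rates <- bin_spikes(rec$spikes, 0, cfg$duration_s)
ev <- det$catalog[det$catalog$state == "active_contact", ]
peak_pre_event_latency(peth(rates, ev))$latency_s
#> [1] 1.15      # planted pre-contact bump peaked 1.2 s before contact

bhv <- behavior_series(rec$tracks)
dec <- decile_distance_analysis(rates$rate, bhv$nn_dist_cm)
dec$groups$dist_median[c(1, 10)]; dec$test$p.value
#> [1] 28.2 23.1  # highest-rate frames sit closest to the nearest bee
#> [1] 1.39e-43
```

The detector recovers exactly the planted events (32 active and 37 passive
contacts here, with one random window per passive contact), the perievent
peak lands within one 100 ms bin of the planted 1.2 s lead, and the
top-rate decile sits at shorter nearest-bee distances than the bottom
decile. The state-resolved variance comparison shows the planted
modulation (σ_active = 1 by default) at the printed star levels:

```r
vs <- variance_by_state(rates, det$catalog)
pairwise_variance_comparisons(vs)[, c("state1", "state2", "p", "stars")]
#>            state1          state2        p stars
#> 1          random   walking_onset 5.39e-02
#> 2          random passive_contact 1.32e-03    **
#> 3          random  active_contact 7.23e-08   ***
#> 4   walking_onset passive_contact 3.30e-01
#> 5   walking_onset  active_contact 7.47e-07   ***
#> 6 passive_contact  active_contact 1.23e-09   ***
```

`run_all(cfg, out_dir)` chains simulate → detect → analyze → report and
writes the fixture files, the event catalog, all analysis tables and a run
manifest (config, seeds, file digests) under `out_dir`.

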
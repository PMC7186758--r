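#' Simulation configuration for the synthetic colony generator
#'
#' Bundles every parameter of the synthetic colony and spike-train generator.
#' The arena geometry and frame rate default to the recording setup the
#' package emulates: a 55 cm x 55 cm observation-hive floor tilted by 17
#' degrees to the horizontal, filmed at 10 frames per second. All remaining
#' parameters describe the generative model (see the package vignette):
#' a stop/go Markov locomotion chain per bee, scripted approach events that
#' plant passive and active social contacts, and a firing-rate model
#' \deqn{\lambda(t) = [\beta_0 + \beta_d e^{-d(t)/d_0} + \alpha g(t)] m(t)}
#' with a distance kernel, a pre-contact bump g peaking `lead_s` seconds
#' before each planted active contact, and a per-window log-normal rate
#' multiplier m whose log-sd depends on the window's social state.
#'
#' @param arena_width_cm,arena_height_cm arena dimensions in cm.
#' @param tilt_deg arena tilt relative to horizontal, degrees. The +y axis of
#'   the arena frame is the up-slope direction.
#' @param frame_rate_hz video frame rate (behavioral clock), Hz.
#' @param duration_s recording duration in seconds; must exceed 16 s so that
#'   a full +/-8 s perievent context fits.
#' @param n_other_bees number of non-focal bees simulated.
#' @param p_stop_to_go,p_go_to_stop per-frame transition probabilities of the
#'   stop/go locomotion chain.
#' @param speed_mean_cm_s mean walking speed during "go" bouts, cm/s.
#' @param speed_sdlog log-sd of the per-frame log-normal walking speed.
#' @param heading_sd_deg sd of the wrapped-normal per-frame heading change.
#' @param approach_rate_passive_per_min rate of scripted other-approaches-focal
#'   events (planted passive contacts), events per minute.
#' @param approach_rate_active_per_min rate of scripted focal-initiated
#'   approach events (planted active contacts), events per minute.
#' @param avoid_radius_cm non-partner bees are kept at least this far from the
#'   focal bee, so that every sub-1 cm contact in a simulation is scripted and
#'   ground truth is complete.
#' @param baseline_hz baseline firing rate, Hz.
#' @param beta_dist_hz amplitude of the distance-dependent rate component, Hz
#'   (rate increase as nearest-bee distance approaches 0).
#' @param dist_kernel_d0_cm length scale of the exponential distance kernel, cm.
#' @param alpha_hz amplitude of the phasic pre-contact bump, Hz.
#' @param lead_s time before the contact moment at which the planted bump
#'   peaks, s.
#' @param bump_width_s full width of the raised-cosine pre-contact bump, s.
#' @param sigma_state named numeric vector, one entry per social state: the
#'   log-sd of the median-preserving log-normal rate multipliers drawn per
#'   `mult_segment_s` segment inside that state's windows.
#' @param mult_segment_s length of the constant-multiplier segments inside a
#'   4 s state window, s. Within-window segment-to-segment multiplier changes
#'   are what raises spike-rate variance for states with larger sigma.
#' @param focal_walk_speed_cm_s scripted walking speed of the focal bee during
#'   planted active contacts, cm/s.
#' @param active_onset_lead_s how long before the contact moment the focal bee
#'   starts walking in a planted active contact, s (must be within (0, 1]).
#' @param min_event_gap_s minimum separation between planted event sync times, s.
#' @param seed integer seed making the whole simulation reproducible.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_colony()], [simulate_recording()]
#' @export
sim_config <- function(arena_width_cm = 55,
                       arena_height_cm = 55,
                       tilt_deg = 17,
                       frame_rate_hz = 10,
                       duration_s = 600,
                       n_other_bees = 5,
                       p_stop_to_go = 0.05,
                       p_go_to_stop = 0.05,
                       speed_mean_cm_s = 2,
                       speed_sdlog = 0.25,
                       heading_sd_deg = 20,
                       approach_rate_passive_per_min = 1,
                       approach_rate_active_per_min = 1,
                       avoid_radius_cm = 12,
                       baseline_hz = 5,
                       beta_dist_hz = 10,
                       dist_kernel_d0_cm = 3,
                       alpha_hz = 10,
                       lead_s = 1.2,
                       bump_width_s = 1,
                       sigma_state = c(alone = 0, random = 0,
                                       walking_onset = 0.4,
                                       passive_contact = 0.4,
                                       active_contact = 1),
                       mult_segment_s = 0.5,
                       focal_walk_speed_cm_s = 2,
                       active_onset_lead_s = 0.5,
                       min_event_gap_s = 12,
                       seed = 1L) {
  cfg <- list(
    arena_width_cm = arena_width_cm, arena_height_cm = arena_height_cm,
    tilt_deg = tilt_deg, frame_rate_hz = frame_rate_hz,
    duration_s = duration_s, n_other_bees = n_other_bees,
    p_stop_to_go = p_stop_to_go, p_go_to_stop = p_go_to_stop,
    speed_mean_cm_s = speed_mean_cm_s, speed_sdlog = speed_sdlog,
    heading_sd_deg = heading_sd_deg,
    approach_rate_passive_per_min = approach_rate_passive_per_min,
    approach_rate_active_per_min = approach_rate_active_per_min,
    avoid_radius_cm = avoid_radius_cm,
    baseline_hz = baseline_hz, beta_dist_hz = beta_dist_hz,
    dist_kernel_d0_cm = dist_kernel_d0_cm,
    alpha_hz = alpha_hz, lead_s = lead_s, bump_width_s = bump_width_s,
    sigma_state = sigma_state, mult_segment_s = mult_segment_s,
    focal_walk_speed_cm_s = focal_walk_speed_cm_s,
    active_onset_lead_s = active_onset_lead_s,
    min_event_gap_s = min_event_gap_s,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  assert_scalar_num(cfg$arena_width_cm, "arena_width_cm", lower = 1)
  assert_scalar_num(cfg$arena_height_cm, "arena_height_cm", lower = 1)
  assert_scalar_num(cfg$frame_rate_hz, "frame_rate_hz", lower = 1)
  assert_scalar_num(cfg$duration_s, "duration_s")
  if (cfg$duration_s <= 16) {
    stopf("duration_s must exceed 16 s to accommodate +/-8 s perievent windows (got %g s)",
          cfg$duration_s, class = "beesocial_config_error")
  }
  assert_scalar_num(cfg$n_other_bees, "n_other_bees", lower = 0)
  assert_scalar_num(cfg$p_stop_to_go, "p_stop_to_go", 0, 1)
  assert_scalar_num(cfg$p_go_to_stop, "p_go_to_stop", 0, 1)
  assert_scalar_num(cfg$speed_mean_cm_s, "speed_mean_cm_s", lower = 0)
  assert_scalar_num(cfg$speed_sdlog, "speed_sdlog", lower = 0)
  assert_scalar_num(cfg$heading_sd_deg, "heading_sd_deg", lower = 0)
  assert_scalar_num(cfg$approach_rate_passive_per_min, "approach_rate_passive_per_min", lower = 0)
  assert_scalar_num(cfg$approach_rate_active_per_min, "approach_rate_active_per_min", lower = 0)
  assert_scalar_num(cfg$avoid_radius_cm, "avoid_radius_cm", lower = 1)
  assert_scalar_num(cfg$baseline_hz, "baseline_hz", lower = 0)
  assert_scalar_num(cfg$beta_dist_hz, "beta_dist_hz", lower = 0)
  assert_scalar_num(cfg$dist_kernel_d0_cm, "dist_kernel_d0_cm", lower = 1e-6)
  assert_scalar_num(cfg$alpha_hz, "alpha_hz", lower = 0)
  assert_scalar_num(cfg$lead_s, "lead_s", lower = 0)
  assert_scalar_num(cfg$bump_width_s, "bump_width_s", lower = 0)
  assert_scalar_num(cfg$mult_segment_s, "mult_segment_s", lower = 0.1)
  assert_scalar_num(cfg$focal_walk_speed_cm_s, "focal_walk_speed_cm_s", lower = 0)
  assert_scalar_num(cfg$active_onset_lead_s, "active_onset_lead_s", lower = 1e-6, upper = 1)
  assert_scalar_num(cfg$min_event_gap_s, "min_event_gap_s", lower = 11)
  if (!is.numeric(cfg$sigma_state) || is.null(names(cfg$sigma_state))) {
    stopf("sigma_state must be a named numeric vector", class = "beesocial_config_error")
  }
  missing <- setdiff(social_state_levels(), names(cfg$sigma_state))
  if (length(missing)) {
    stopf("sigma_state is missing states: %s", paste(missing, collapse = ", "),
          class = "beesocial_config_error")
  }
  if (any(cfg$sigma_state < 0)) {
    stopf("sigma_state entries must be >= 0", class = "beesocial_config_error")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  arena: %g x %g cm, tilt %g deg, %g fps, %g s\n",
              x$arena_width_cm, x$arena_height_cm, x$tilt_deg,
              x$frame_rate_hz, x$duration_s))
  cat(sprintf("  bees: focal + %d others; approach rates %g + %g /min\n",
              x$n_other_bees, x$approach_rate_passive_per_min,
              x$approach_rate_active_per_min))
  cat(sprintf("  rate model: base %g Hz, beta_dist %g Hz (d0 %g cm), alpha %g Hz (lead %g s)\n",
              x$baseline_hz, x$beta_dist_hz, x$dist_kernel_d0_cm,
              x$alpha_hz, x$lead_s))
  cat(sprintf("  sigma_state: %s\n",
              paste(sprintf("%s=%g", names(x$sigma_state), x$sigma_state),
                    collapse = ", ")))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Social state labels
#'
#' The five social states a 4 s window can be assigned to.
#' @return character vector of state labels.
#' @export
social_state_levels <- function() {
  c("alone", "random", "walking_onset", "passive_contact", "active_contact")
}

#' Analysis configuration: every threshold and window in one place
#'
#' Collects the thresholds and windows of the social-state rule set and the
#' event-aligned spike analyses: the 4 s state window with its 2 s sync mark,
#' the 10 cm "alone" radius, the 1 cm contact radius, the 1 mm / 2 s
#' stillness rule, the 1 s--2 s active-onset interval, the +/-8 s perievent
#' span with 100 ms bins, the 10 degree angular bin, the 5 cm distance split,
#' and the alpha/6 Bonferroni family.
#'
#' Two parameters are the package's own operational choices (the rule set is
#' silent on them): `moving_speed_threshold_cm_s`, the frame-level speed above
#' which a bee counts as moving, and `moving_fraction`, the fraction of frames
#' in a span that must be moving for the span to count as continuous walking
#' (tolerates tracker jitter).
#'
#' @param window_s state window length, s.
#' @param sync_mark_s position of the synchronization mark inside the window, s.
#' @param alone_radius_cm no other bee within this radius means "alone", cm.
#' @param contact_radius_cm a bee closer than this is "in contact", cm.
#' @param still_displacement_mm a span counts as still if the focal bee moves
#'   less than this total path length, mm.
#' @param still_span_s length of the stillness span, s.
#' @param active_onset_window_s interval before the contact moment within
#'   which walking must start for a contact to be "active", s (two values,
#'   marks measured back from the sync mark).
#' @param moving_speed_threshold_cm_s frame-level moving/still speed cut, cm/s.
#' @param moving_fraction required fraction of moving frames in a
#'   continuous-walking span.
#' @param bin_w_s width of the spike-count bins (the behavioral clock), s.
#' @param peth_half_span_s perievent half span, s.
#' @param peak_search_s interval, in seconds before the event, searched for
#'   the pre-event rate peak.
#' @param peak_smooth_s boxcar width used to smooth the perievent histogram
#'   before peak picking, s.
#' @param angle_bin_deg angular bin width for orientation-resolved rate
#'   profiles, degrees; must divide 360.
#' @param distance_cut_cm near/far distance split, cm.
#' @param family_alpha family-wise error level for the pairwise variance
#'   comparisons.
#' @param n_comparisons size of the Bonferroni family (6 = the pairs among
#'   the four non-alone states).
#' @param random_overlap_ok may "random" windows overlap other state windows?
#' @return an object of class `analysis_config`.
#' @export
analysis_config <- function(window_s = 4,
                            sync_mark_s = 2,
                            alone_radius_cm = 10,
                            contact_radius_cm = 1,
                            still_displacement_mm = 1,
                            still_span_s = 2,
                            active_onset_window_s = c(0, 1),
                            moving_speed_threshold_cm_s = 0.5,
                            moving_fraction = 0.9,
                            bin_w_s = 0.1,
                            peth_half_span_s = 8,
                            peak_search_s = c(-4, 0),
                            peak_smooth_s = 0.3,
                            angle_bin_deg = 10,
                            distance_cut_cm = 5,
                            family_alpha = 0.05,
                            n_comparisons = 6,
                            random_overlap_ok = TRUE) {
  cfg <- list(
    window_s = window_s, sync_mark_s = sync_mark_s,
    alone_radius_cm = alone_radius_cm, contact_radius_cm = contact_radius_cm,
    still_displacement_mm = still_displacement_mm, still_span_s = still_span_s,
    active_onset_window_s = active_onset_window_s,
    moving_speed_threshold_cm_s = moving_speed_threshold_cm_s,
    moving_fraction = moving_fraction,
    bin_w_s = bin_w_s, peth_half_span_s = peth_half_span_s,
    peak_search_s = peak_search_s, peak_smooth_s = peak_smooth_s,
    angle_bin_deg = angle_bin_deg, distance_cut_cm = distance_cut_cm,
    family_alpha = family_alpha, n_comparisons = n_comparisons,
    random_overlap_ok = isTRUE(random_overlap_ok)
  )
  class(cfg) <- "analysis_config"
  validate_analysis_config(cfg)
}

validate_analysis_config <- function(cfg) {
  assert_scalar_num(cfg$window_s, "window_s", lower = 0.2)
  assert_scalar_num(cfg$sync_mark_s, "sync_mark_s", lower = 1e-9)
  if (cfg$sync_mark_s >= cfg$window_s) {
    stopf("sync_mark_s must lie strictly inside the window (0 < sync < window)",
          class = "beesocial_config_error")
  }
  assert_scalar_num(cfg$alone_radius_cm, "alone_radius_cm", lower = 0)
  assert_scalar_num(cfg$contact_radius_cm, "contact_radius_cm", lower = 0)
  if (cfg$contact_radius_cm >= cfg$alone_radius_cm) {
    stopf("contact_radius_cm must be smaller than alone_radius_cm",
          class = "beesocial_config_error")
  }
  assert_scalar_num(cfg$still_displacement_mm, "still_displacement_mm", lower = 0)
  assert_scalar_num(cfg$still_span_s, "still_span_s", lower = 0.1)
  assert_scalar_num(cfg$moving_speed_threshold_cm_s, "moving_speed_threshold_cm_s", lower = 0)
  assert_scalar_num(cfg$moving_fraction, "moving_fraction", 0, 1)
  assert_scalar_num(cfg$bin_w_s, "bin_w_s", lower = 1e-6)
  assert_scalar_num(cfg$peth_half_span_s, "peth_half_span_s", lower = cfg$window_s / 2)
  assert_scalar_num(cfg$peak_smooth_s, "peak_smooth_s", lower = 0)
  assert_scalar_num(cfg$angle_bin_deg, "angle_bin_deg", lower = 1e-6)
  assert_scalar_num(cfg$distance_cut_cm, "distance_cut_cm", lower = 0)
  assert_scalar_num(cfg$family_alpha, "family_alpha", 1e-12, 1 - 1e-12)
  assert_scalar_num(cfg$n_comparisons, "n_comparisons", lower = 1)
  if (length(cfg$active_onset_window_s) != 2 ||
      cfg$active_onset_window_s[1] >= cfg$active_onset_window_s[2]) {
    stopf("active_onset_window_s must be two increasing marks (s before sync)",
          class = "beesocial_config_error")
  }
  cfg
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("<analysis_config>\n")
  cat(sprintf("  window %g s (sync at %g s); alone > %g cm; contact < %g cm\n",
              x$window_s, x$sync_mark_s, x$alone_radius_cm, x$contact_radius_cm))
  cat(sprintf("  still: < %g mm over %g s; moving: >= %g cm/s in >= %g%% of frames\n",
              x$still_displacement_mm, x$still_span_s,
              x$moving_speed_threshold_cm_s, 100 * x$moving_fraction))
  cat(sprintf("  perievent: +/-%g s in %g ms bins; peak search [%g, %g] s, %g s boxcar\n",
              x$peth_half_span_s, 1000 * x$bin_w_s,
              x$peak_search_s[1], x$peak_search_s[2], x$peak_smooth_s))
  cat(sprintf("  angular bins %g deg; distance split %g cm; Bonferroni alpha/%d at alpha = %g\n",
              x$angle_bin_deg, x$distance_cut_cm, x$n_comparisons, x$family_alpha))
  invisible(x)
}

#' Read or write a configuration as YAML
#'
#' @param path file path (plain or gzip-compressed YAML).
#' @param type which configuration type the file holds.
#' @return `read_config()` returns a `sim_config` or `analysis_config`;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path, type = c("analysis", "sim")) {
  type <- match.arg(type)
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$sigma_state)) vals$sigma_state <- unlist(vals$sigma_state)
  maker <- if (type == "analysis") analysis_config else sim_config
  do.call(maker, vals)
}

#' @rdname read_config
#' @param cfg configuration object to serialize.
#' @export
write_config <- function(cfg, path) {
  vals <- unclass(cfg)
  if (!is.null(vals$sigma_state)) vals$sigma_state <- as.list(vals$sigma_state)
  yaml::write_yaml(vals, path)
  invisible(path)
}
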
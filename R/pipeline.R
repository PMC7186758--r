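# Orchestration: simulate -> detect -> analyze -> report, with a run
# manifest for reproducibility. Ground truth is written by the simulate
# stage for the test harness only; detection and analysis never read it.

#' Run the simulate stage
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory for the fixture files.
#' @param rules an [analysis_config()].
#' @return list with the fixture `paths` and the run `manifest`.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir,
                         rules = analysis_config()) {
  paths <- make_fixture(cfg, out_dir, rules)
  manifest <- make_manifest("simulate", cfg = cfg, rules = rules,
                            files = paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  list(paths = paths, manifest = manifest)
}

#' Run the detect stage: behavior series and social-state catalog
#'
#' @param tracks a `track_table` or path to a tracks CSV.
#' @param rules an [analysis_config()].
#' @param seed seed for the random-window draw.
#' @param frame_rate_hz frame rate, used when reading from file.
#' @return list with `behavior` (the [behavior_series()]) and `catalog`
#'   (the [classify_all()] event catalog).
#' @export
run_detect <- function(tracks, rules = analysis_config(), seed = 1L,
                       frame_rate_hz = 10) {
  if (is.character(tracks)) tracks <- read_tracks(tracks, frame_rate_hz)
  bhv <- behavior_series(tracks, frame_rate_hz = attr(tracks, "frame_rate_hz") %||%
                           frame_rate_hz)
  catalog <- classify_all(bhv, rules, seed)
  list(behavior = bhv, catalog = catalog)
}

#' Run the analyze stage: all rate-behavior analyses
#'
#' Computes the full analysis set on one recording: gravity-relative and
#' relative-body-axis angular rate profiles (whole recording and per
#' quarter) with Rayleigh tests, the decile distance analysis, the 5 cm
#' near/far split per quarter, perievent time histograms and pre-event peak
#' latencies for the three movement-linked states, per-state spike-rate
#' variance samples with the Bonferroni-corrected pairwise comparisons, and
#' the focal-versus-companion walking-speed check. Analyses that need
#' social contacts are marked not applicable when the catalog has none.
#'
#' @param detect result of [run_detect()].
#' @param spikes a `spike_train` or path to a spike-time file.
#' @param tracks the `track_table` (for the speed comparison).
#' @param rules an [analysis_config()].
#' @return a list of tables, of class `bee_analysis`.
#' @export
run_analyze <- function(detect, spikes, tracks, rules = analysis_config()) {
  if (is.character(spikes)) spikes <- read_spikes(spikes)
  bhv <- detect$behavior
  catalog <- detect$catalog
  rate_hz <- attr(bhv, "frame_rate_hz") %||% 10
  t0 <- bhv$time_s[1]
  t1 <- bhv$time_s[nrow(bhv)] + 1 / rate_hz
  rates <- bin_spikes(spikes, t0, t1, rules$bin_w_s)
  frame_rates <- rates$rate[seq_len(min(nrow(rates), nrow(bhv)))]
  nfr <- length(frame_rates)

  ang_profile <- function(angles) {
    whole <- angular_rate_profile(angles[seq_len(nfr)], frame_rates,
                                  rules$angle_bin_deg)
    quarters <- lapply(quarter_split(seq_len(nfr)), function(idx) {
      angular_rate_profile(angles[idx], frame_rates[idx], rules$angle_bin_deg)
    })
    counts <- rates$count[seq_len(nfr)]
    ok <- !is.na(angles[seq_len(nfr)])
    test <- if (sum(counts[ok]) > 0) {
      rayleigh_test(angles[seq_len(nfr)][ok], counts[ok])
    } else NULL
    list(profile = whole, quarters = quarters, rayleigh = test)
  }
  gravity <- ang_profile(bhv$gravity_deg)
  rel_axis <- ang_profile(bhv$rel_axis_deg)
  bearing <- ang_profile(bhv$bearing_deg)

  dist <- bhv$nn_dist_cm[seq_len(nfr)]
  decile <- if (sum(!is.na(dist)) >= 10) {
    decile_distance_analysis(frame_rates, dist)
  } else NULL
  split5 <- distance_split_profiles(frame_rates, dist, rules$distance_cut_cm)

  peth_states <- c("walking_onset", "passive_contact", "active_contact")
  peths <- list(); latencies <- list()
  for (st in peth_states) {
    ev <- catalog[catalog$state == st, , drop = FALSE]
    if (nrow(ev) == 0) {
      peths[[st]] <- NULL
      latencies[[st]] <- list(latency_s = NA_real_, no_peak = NA,
                              not_applicable = TRUE)
      next
    }
    p <- tryCatch(peth(rates, ev, rules$peth_half_span_s),
                  beesocial_neural_error = function(e) NULL)
    peths[[st]] <- p
    latencies[[st]] <- if (is.null(p)) {
      list(latency_s = NA_real_, no_peak = NA, not_applicable = TRUE)
    } else {
      peak_pre_event_latency(p, rules$peak_search_s, rules$peak_smooth_s)
    }
  }

  var_samples <- variance_by_state(rates, catalog, rules$window_s)
  has_contacts <- any(catalog$state %in% c("passive_contact", "active_contact"))
  var_comp <- pairwise_variance_comparisons(var_samples,
                                            alpha = rules$family_alpha)
  speed_check <- tryCatch(
    compare_focal_vs_others_speed(tracks, frame_rate_hz = rate_hz),
    beesocial_stats_error = function(e) NULL)

  structure(list(
    rates = rates, gravity = gravity, rel_axis = rel_axis, bearing = bearing,
    decile = decile, split5 = split5, peths = peths, latencies = latencies,
    variance_samples = var_samples, variance_comparisons = var_comp,
    speed_check = speed_check,
    contacts_applicable = has_contacts,
    state_counts = table(catalog$state)
  ), class = "bee_analysis")
}

#' Run the report stage: summary JSON and CSV tables
#'
#' Writes the analysis tables (angular profiles, decile table, perievent
#' histograms, variance comparison table) as CSV plus a JSON summary; when
#' the recording contains no social contacts the contact-dependent entries
#' are marked `"not applicable"`, and figures are skipped unless requested.
#'
#' @param analysis a `bee_analysis` from [run_analyze()].
#' @param out_dir output directory.
#' @param figures also write simple overview figures (PNG)?
#' @return invisible character vector of written paths.
#' @export
run_report <- function(analysis, out_dir, figures = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  wr(analysis$gravity$profile, "angular_profile_gravity.csv")
  wr(analysis$rel_axis$profile, "angular_profile_rel_axis.csv")
  for (q in 1:4) {
    wr(analysis$gravity$quarters[[q]],
       sprintf("angular_profile_gravity_q%d.csv", q))
  }
  if (!is.null(analysis$decile)) wr(analysis$decile$groups, "decile_distance.csv")
  wr(analysis$split5$summary, "distance_split.csv")
  for (st in names(analysis$peths)) {
    p <- analysis$peths[[st]]
    if (!is.null(p)) {
      wr(data.frame(lag_s = p$lag_s, mean_rel_rate = p$mean_rel),
         sprintf("peth_%s.csv", st))
    }
  }
  wr(analysis$variance_comparisons, "variance_comparisons.csv")
  summary <- list(
    state_counts = as.list(analysis$state_counts),
    contacts = if (analysis$contacts_applicable) "present" else "not applicable",
    rayleigh_gravity_p = if (!is.null(analysis$gravity$rayleigh))
      analysis$gravity$rayleigh$p.value else NA,
    rayleigh_rel_axis_p = if (!is.null(analysis$rel_axis$rayleigh))
      analysis$rel_axis$rayleigh$p.value else NA,
    decile_top_vs_bottom_p = if (!is.null(analysis$decile))
      analysis$decile$test$p.value else "not applicable",
    latencies = lapply(analysis$latencies, function(l) {
      if (isTRUE(l$not_applicable)) "not applicable" else l$latency_s
    }),
    speed_check_p = if (!is.null(analysis$speed_check))
      analysis$speed_check$p.value else "not applicable"
  )
  sp <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summary, sp, auto_unbox = TRUE, digits = 10,
                       null = "null", na = "null")
  paths <- c(paths, sp)
  if (figures) {
    fp <- file.path(out_dir, "overview.png")
    grDevices::png(fp, width = 1200, height = 800)
    on.exit(grDevices::dev.off(), add = TRUE)
    graphics::par(mfrow = c(2, 2))
    plot_angular_profile(analysis$gravity$profile,
                         main = "Rate vs gravity angle")
    if (!is.null(analysis$decile)) plot_decile(analysis$decile)
    for (st in names(analysis$peths)[1:2]) {
      if (!is.null(analysis$peths[[st]])) plot_peth(analysis$peths[[st]],
                                                    main = st)
    }
    paths <- c(paths, fp)
  }
  invisible(paths)
}

#' Run the whole pipeline on a synthetic recording
#'
#' simulate -> detect -> analyze -> report in one call, writing fixture,
#' tables and manifest under `out_dir`.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory.
#' @param rules an [analysis_config()].
#' @param figures write figures?
#' @return list with `paths`, `catalog`, `analysis`, `manifest` (invisibly).
#' @export
run_all <- function(cfg = sim_config(), out_dir,
                    rules = analysis_config(), figures = FALSE) {
  sim <- run_simulate(cfg, out_dir, rules)
  det <- run_detect(sim$paths[["tracks"]], rules, seed = cfg$seed)
  write_events(det$catalog, file.path(out_dir, "catalog.csv"))
  ana <- run_analyze(det, sim$paths[["spikes"]],
                     read_tracks(sim$paths[["tracks"]]), rules)
  rep_paths <- run_report(ana, out_dir, figures = figures)
  manifest <- make_manifest("run_all", cfg = cfg, rules = rules,
                            files = c(sim$paths,
                                      catalog = file.path(out_dir, "catalog.csv"),
                                      rep_paths),
                            counts = as.list(table(det$catalog$state)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, null = "null")
  invisible(list(paths = rep_paths, catalog = det$catalog, analysis = ana,
                 manifest = manifest))
}

make_manifest <- function(stage, cfg, rules, files = character(0),
                          counts = NULL) {
  files <- files[file.exists(unlist(files))]
  list(
    stage = stage,
    package = "beesocial",
    version = as.character(utils::packageVersion("beesocial")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    sim_config = unclass(cfg),
    analysis_config = unclass(rules),
    seed = cfg$seed,
    file_md5 = as.list(tools::md5sum(unlist(files))),
    counts = counts
  )
}

# --- minimal base-graphics helpers (headless-safe; tables are the contract)

#' Plot an angular rate profile
#' @param profile output of [angular_rate_profile()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_angular_profile <- function(profile, ...) {
  graphics::plot(profile$bin_mid_deg, profile$mean_rate, type = "h",
                 xlab = "angle (deg)", ylab = "mean rate (Hz)", ...)
}

#' Plot a perievent time histogram
#' @param p a [peth()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_peth <- function(p, ...) {
  graphics::plot(p$lag_s, p$mean_rel, type = "l",
                 xlab = "lag (s)", ylab = "relative rate", ...)
  graphics::abline(v = 0, lty = 2)
  graphics::abline(h = 1, col = "grey")
}

#' Plot the decile distance analysis
#' @param dec output of [decile_distance_analysis()].
#' @param ... passed to [graphics::plot()].
#' @export
plot_decile <- function(dec, ...) {
  g <- dec$groups
  graphics::plot(g$group, g$dist_median, ylim = range(c(g$dist_q1, g$dist_q3)),
                 xlab = "spike-rate decile", ylab = "distance (cm)",
                 pch = 19, ...)
  graphics::segments(g$group, g$dist_q1, g$group, g$dist_q3)
}

#' Plot the focal bee's trajectory colored by spike rate
#'
#' Visual place inspection: the trajectory with warmer colors at higher
#' spike rates (no quantitative place statistic is computed).
#'
#' @param tracks a `track_table`.
#' @param rates a `rate_series` on the frame grid.
#' @param focal_id focal bee id.
#' @export
plot_trajectory_rate <- function(tracks, rates, focal_id = "focal") {
  focal <- tracks[tracks$bee_id == focal_id, , drop = FALSE]
  r <- rates$rate[seq_len(min(nrow(focal), nrow(rates)))]
  cols <- grDevices::heat.colors(64, rev = TRUE)[
    pmin(64, 1 + floor(63 * r / max(r, 1e-9)))]
  graphics::plot(focal$x_cm[seq_along(r)], focal$y_cm[seq_along(r)],
                 col = cols, pch = 16, cex = 0.4, asp = 1,
                 xlab = "x (cm)", ylab = "y (cm)")
}
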
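#' Pipeline run configuration
#'
#' Bundles the module configurations for a reproducible end-to-end run.
#'
#' @param seed Global integer seed; every stochastic stage derives from it.
#' @param sim A [simulation_config()]; its `seed` is overwritten by `seed`.
#' @param fit A [fit_config()].
#' @param threshold_um Telomere-vicinity distance rule (um).
#' @param grouping `"pooled"` (all tracks together) or `"per_cell"`
#'   (reserved for multi-cell track tables with a `cell` column).
#' @param classify_method Passed to [classify_tracks()].
#' @param t_half_telo,t_half_non True dwell half-lives (s) used by the
#'   slow-mode dwell simulation for the telomeric and non-telomeric groups.
#' @param n_events_slow Binding events per group in slow mode.
#' @param residence_model Exponential model for [fit_residence()].
#' @param n_boot Bootstrap resamples for residence CIs.
#' @param n_null_rotations Foci rotations used for the chance-share
#'   randomization null in fast mode (deterministic angles).
#' @param out_dir Optional output directory for reports.
#' @param verbose Emit per-stage log messages.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, sim = simulation_config("fast"),
                       fit = fit_config(), threshold_um = 0.48,
                       grouping = c("pooled", "per_cell"),
                       classify_method = "mean_position",
                       t_half_telo = 2.3, t_half_non = 0.7,
                       n_events_slow = 5000,
                       residence_model = "one_exp", n_boot = 200,
                       n_null_rotations = 2,
                       out_dir = NULL, verbose = FALSE) {
  grouping <- match.arg(grouping)
  cfg <- list(seed = as.integer(seed), sim = sim, fit = fit,
              threshold_um = threshold_um, grouping = grouping,
              classify_method = classify_method,
              t_half_telo = t_half_telo, t_half_non = t_half_non,
              n_events_slow = n_events_slow,
              residence_model = residence_model, n_boot = n_boot,
              n_null_rotations = n_null_rotations,
              out_dir = out_dir, verbose = verbose)
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), c("out_dir", "verbose"))])
  structure(cfg, class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(paste0("[stage ", stage, "] ", conditionMessage(e)),
                        class = class(e)[class(e) != "simpleError"]))
  })
}

log_stage <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) message(sprintf(fmt, ...))
}

#' Run the fast-mode (kinetic) analysis end to end
#'
#' Simulates foci and two-state molecule tracks at the fast acquisition
#' geometry, classifies tracks against the foci with the distance rule,
#' fits the two-state jump-length model overall and per group, and
#' combines the group fits into the telomere-bound share (raw and
#' chance-colocalization corrected).
#'
#' @param config A [run_config()] whose `sim` uses `mode = "fast"`.
#' @param tracks,foci Optional pre-computed `track_table` / `foci_set`
#'   (skips simulation; e.g. tracks linked from a real movie).
#' @return A list of class `cell_report`.
#' @export
run_fast_mode <- function(config = run_config(), tracks = NULL, foci = NULL) {
  stopifnot(inherits(config, "run_config"))
  sim <- config$sim
  sim$seed <- config$seed
  if (is.null(foci)) {
    log_stage(config, "simulate: %d foci", sim$n_foci)
    foci <- with_stage("simulate_foci", simulate_foci(sim))
  }
  if (is.null(tracks)) {
    log_stage(config, "simulate: %d molecules x %d frames", sim$n_molecules,
              sim$n_frames)
    tracks <- with_stage("simulate_tracks", simulate_tracks(sim, foci)$tracks)
  }
  log_stage(config, "tracks in: %d", n_tracks(tracks))
  # measure the photobleaching rate from the per-frame detection counts
  # (the track-table analogue of the integrated channel intensity) and feed
  # it to the sampling-aware defocalization correction
  fitcfg <- config$fit
  bleach_hat <- NULL
  if (fitcfg$z_corr_mode == "monte_carlo" && nrow(tracks) > 0) {
    trace <- tabulate(tracks$frame + 1L, nbins = max(tracks$frame) + 1L)
    bl <- with_stage("fit_bleach", fit_bleach(trace, sim$frame_interval))
    if (bl$k_bleach > 0) fitcfg$k_bleach <- bl$k_bleach
    bleach_hat <- bl$k_bleach
  }
  cls <- with_stage("classify",
                    classify_tracks(tracks, foci, config$threshold_um,
                                    method = config$classify_method))
  groups <- split_by_classification(tracks, cls)
  log_stage(config, "classified: %d telomeric / %d non-telomeric tracks",
            n_tracks(groups$telomeric), n_tracks(groups$non_telomeric))

  h_all <- with_stage("fit", compile_histograms(tracks, fitcfg))
  fit_all <- with_stage("fit", fit_two_state(h_all, fitcfg))
  h_telo <- compile_histograms(groups$telomeric, fitcfg)
  h_non <- compile_histograms(groups$non_telomeric, fitcfg)
  fit_telo <- with_stage("fit_telomeric", fit_two_state(h_telo, fitcfg))
  fit_non <- with_stage("fit_non_telomeric", fit_two_state(h_non, fitcfg))

  share_raw <- with_stage("share",
                          telomere_bound_share(fit_telo, sum(h_telo$n_jumps),
                                               fit_non, sum(h_non$n_jumps)))
  # occupancy-units share (counted jumps are converted to molecule-time via
  # the per-state jump yields)
  occ_share <- function(f_t, n_t, f_n, n_n) {
    bt <- bound_occupancy_mass(f_t, n_t, fitcfg)
    bn <- bound_occupancy_mass(f_n, n_n, fitcfg)
    if (bt + bn > 0) bt / (bt + bn) else 0
  }
  share_occ <- occ_share(fit_telo, sum(h_telo$n_jumps),
                         fit_non, sum(h_non$n_jumps))
  # rotation null: the same statistic against foci rotated about the
  # nuclear centre estimates the chance-colocalization share, including
  # every bias of the classification and fitting machinery
  null_angles <- 2 * pi * seq_len(config$n_null_rotations) /
    (config$n_null_rotations + 1)
  null_shares <- vapply(null_angles, function(a) {
    fr <- rotate_foci(foci, a)
    gr <- split_by_classification(tracks, classify_tracks(
      tracks, fr, config$threshold_um, method = config$classify_method))
    ht <- compile_histograms(gr$telomeric, fitcfg)
    hn <- compile_histograms(gr$non_telomeric, fitcfg)
    tryCatch(occ_share(fit_two_state(ht, fitcfg), sum(ht$n_jumps),
                       fit_two_state(hn, fitcfg), sum(hn$n_jumps)),
             error = function(e) NA_real_)
  }, numeric(1))
  chance_null <- mean(null_shares, na.rm = TRUE)
  chance_point <- chance_colocalization(foci, sim$nucleus_radius,
                                        config$threshold_um)
  if (!is.finite(chance_null)) chance_null <- chance_point
  share_corr <- corrected_share(share_occ, chance_null)

  report <- structure(list(
    mode = "fast", seed = config$seed, config_hash = config$hash,
    n_tracks = n_tracks(tracks),
    n_jumps = sum(h_all$n_jumps),
    k_bleach_estimate = bleach_hat,
    fit_overall = unclass(fit_all),
    fit_telomeric = unclass(fit_telo),
    fit_non_telomeric = unclass(fit_non),
    n_jumps_telomeric = sum(h_telo$n_jumps),
    n_jumps_non_telomeric = sum(h_non$n_jumps),
    telomere_bound_share_raw = share_raw,
    telomere_bound_share_occupancy = share_occ,
    chance_share_rotation_null = chance_null,
    chance_colocalization = chance_point,
    telomere_bound_share = share_corr), class = "cell_report")
  maybe_write_report(report, config, "fast_report.json")
  report
}

#' Run the slow-mode (residence-time) analysis end to end
#'
#' Simulates binding dwell times for the telomeric and non-telomeric
#' groups at the slow acquisition geometry, truncated by photobleaching
#' and the movie length; builds the photobleaching intensity trace from
#' the same bleaching draws; fits each group's survival curve with
#' bleaching-corrected exponential kinetics and compares the groups.
#'
#' @param config A [run_config()]; slow-mode parameters are taken from
#'   `config$sim` when it uses `mode = "slow"`, otherwise from the slow
#'   preset.
#' @return A list of class `cell_report` with the two `residence_fit`s and
#'   the group comparison.
#' @export
run_slow_mode <- function(config = run_config(sim = simulation_config("slow"))) {
  stopifnot(inherits(config, "run_config"))
  sim <- if (config$sim$mode == "slow") config$sim else simulation_config("slow")
  t_movie <- sim$n_frames * sim$frame_interval
  groups <- list(telomeric = config$t_half_telo,
                 non_telomeric = config$t_half_non)
  fits <- list(); curves <- list(); bleaches <- list()
  for (gi in seq_along(groups)) {
    g <- names(groups)[gi]
    dw <- with_stage("simulate_dwells", simulate_dwell_times(
      config$n_events_slow, groups[[g]], k_bleach = sim$k_bleach,
      frame_interval = sim$frame_interval, max_duration = t_movie,
      seed = config$seed + 101L * gi))
    # integrated channel intensity: unbleached emitters per frame
    ft <- (seq_len(sim$n_frames) - 1L) * sim$frame_interval
    trace <- vapply(ft, function(t) sum(dw$bleach_time > t), numeric(1))
    bl <- with_stage("fit_bleach", fit_bleach(trace, sim$frame_interval))
    dur <- dw$duration[dw$duration > 0]
    log_stage(config, "%s: %d durations, k_bleach_hat = %.3f/s", g,
              length(dur), bl$k_bleach)
    sc <- with_stage("survival", survival_curve(dur))
    fits[[g]] <- with_stage("fit_residence", fit_residence(
      sc, bl, model = config$residence_model, n_boot = config$n_boot,
      seed = config$seed + 7L))
    curves[[g]] <- sc; bleaches[[g]] <- bl
  }
  cmp <- with_stage("compare", compare_groups(fits$telomeric,
                                              fits$non_telomeric))
  report <- structure(list(
    mode = "slow", seed = config$seed, config_hash = config$hash,
    residence_telomeric = unclass(fits$telomeric),
    residence_non_telomeric = unclass(fits$non_telomeric),
    bleach_telomeric = unclass(bleaches$telomeric),
    bleach_non_telomeric = unclass(bleaches$non_telomeric),
    half_life_ratio = cmp), class = "cell_report")
  attr(report, "curves") <- curves
  maybe_write_report(report, config, "slow_report.json")
  report
}

maybe_write_report <- function(report, config, filename) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(report, file.path(config$out_dir, filename))
}

#' Serialize / read a cell report
#'
#' Reports are written as JSON at full numeric precision so that a report
#' round-trips through its file format without loss.
#'
#' @param report A `cell_report`.
#' @param path Output path.
#' @return `read_report` returns the report as a list.
#' @export
write_report <- function(report, path) {
  clean <- rapply(unclass(report), function(x)
    if (is.numeric(x)) unname(x) else x, how = "replace")
  jsonlite::write_json(clean, path, digits = NA, auto_unbox = TRUE,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Perturbation presets for simulated comparisons
#'
#' Returns a modified [simulation_config()] mimicking the biological
#' perturbations studied with this kind of experiment, expressed purely as
#' simulator parameter changes: `"atpase_dead"` (binding unchanged, free
#' diffusivity raised), `"trf2_degraded"` (reduced binding rate and
#' shortened telomeric dwell, i.e. lower `p_telo`), `"s_phase"` (raised
#' bound fraction, lowered free diffusivity) relative to an asynchronous
#' baseline.
#'
#' @param base A [simulation_config()].
#' @param which One of `"s_phase"`, `"atpase_dead"`, `"trf2_degraded"`.
#' @return A modified `simulation_config`.
#' @export
perturbation_preset <- function(base = simulation_config("fast"),
                                which = c("s_phase", "atpase_dead",
                                          "trf2_degraded")) {
  which <- match.arg(which)
  b <- unclass(base)
  mod <- switch(which,
                s_phase = list(),  # the defaults are S-phase-like
                atpase_dead = list(D_free = b$D_free * 1.2,
                                   k_on = b$k_off_sim * 0.25 / 0.75),
                trf2_degraded = list(k_on = b$k_on * 0.6, p_telo = 0.01))
  b[names(mod)] <- mod
  do.call(simulation_config, c(list(mode = b$mode),
                               b[setdiff(names(b), "mode")]))
}
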
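#' Optics configuration for movie rendering
#'
#' Parameters of the simulated microscope used by [render_movie()]. The
#' point-spread function is approximated by a 2D Gaussian of standard
#' deviation `0.21 * emission_wavelength / numerical_aperture`.
#'
#' @param numerical_aperture Objective NA (dimensionless, > 0).
#' @param emission_wavelength Emission wavelength in micrometres.
#' @param photons_per_molecule_per_frame Expected photons collected from one
#'   molecule in one frame.
#' @param background_rate Background photons per pixel per frame.
#' @param camera_gain,camera_offset Linear camera model: counts =
#'   offset + gain * photons.
#' @return A list of class `optics_config`.
#' @export
optics_config <- function(numerical_aperture = 1.49,
                          emission_wavelength = 0.672,
                          photons_per_molecule_per_frame = 500,
                          background_rate = 10,
                          camera_gain = 1,
                          camera_offset = 100) {
  check_pos(numerical_aperture, "numerical_aperture")
  check_pos(emission_wavelength, "emission_wavelength")
  check_nonneg(photons_per_molecule_per_frame, "photons_per_molecule_per_frame")
  check_nonneg(background_rate, "background_rate")
  structure(list(numerical_aperture = numerical_aperture,
                 emission_wavelength = emission_wavelength,
                 photons_per_molecule_per_frame = photons_per_molecule_per_frame,
                 background_rate = background_rate,
                 camera_gain = camera_gain,
                 camera_offset = camera_offset),
            class = "optics_config")
}

#' Gaussian PSF standard deviation (micrometres)
#'
#' Gaussian approximation of the Airy disk, `0.21 * lambda / NA`.
#' @param optics An [optics_config()].
#' @return PSF sd in micrometres.
#' @export
psf_sigma <- function(optics) {
  0.21 * optics$emission_wavelength / optics$numerical_aperture
}

#' Simulation configuration
#'
#' Ground-truth conditions for the two-state (free/bound) nuclear-diffusion
#' simulator. Defaults describe S-phase-like imaging of a low-abundance
#' telomere-interacting helicase: free diffusion at ~1.5 um^2/s, a bound
#' fraction near one third set by `k_on/(k_on + k_off_sim)`, 5% of binding
#' events at one of 160 near-static telomere foci, a 0.7 um axial detection
#' slice, and 134 fps (`"fast"`) or 5 fps (`"slow"`) acquisition.
#'
#' @param mode `"fast"` (7.5 ms frames, 10 s movie, high laser power and
#'   fast in-slice photobleaching) or `"slow"` (200 ms frames, 90 s movie,
#'   low power, slow bleaching).
#' @param n_molecules Number of labelled molecules.
#' @param D_free,D_bound Diffusion coefficients (um^2/s) of the free and
#'   bound state.
#' @param k_on,k_off_sim Switching rates (1/s): free->bound and bound->free.
#' @param p_telo Probability that a binding event occurs at a telomere focus.
#' @param n_foci Number of telomere marker foci.
#' @param D_foci Focus diffusion coefficient (um^2/s).
#' @param nucleus_radius,nucleus_thickness Cylindrical nuclear geometry (um),
#'   reflecting boundaries.
#' @param dZ Axial detection slice thickness (um); molecules are detectable
#'   when `|z| <= dZ/2`. May be `Inf` (no optical sectioning).
#' @param frame_interval,exposure Frame spacing and exposure (s).
#' @param n_frames Number of frames in the movie.
#' @param sigma_loc Localization error sd per axis (um).
#' @param k_bleach Photobleaching rate (1/s). The bleaching clock runs
#'   continuously: in inclined-sheet illumination the beam traverses the
#'   nucleus, so fluorophores bleach whether or not they are in focus.
#' @param p_miss Per-frame missed-detection probability.
#' @param pixel_size Camera pixel size (um).
#' @param seed Integer seed; drives per-molecule L'Ecuyer RNG substreams.
#' @param optics An [optics_config()].
#' @param telo_jitter Gaussian sd (um) of the binding position around a
#'   focus centroid (a telomere is not a point).
#' @param init_state `"stationary"` (draw the initial state from the
#'   stationary two-state distribution), `"free"` or `"bound"`.
#' @param track_gap_frames Detection gaps up to this many frames are bridged
#'   when the simulator emits its ready-linked track table, mirroring the
#'   linker's gap closing.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(mode = c("fast", "slow"),
                              n_molecules = 300,
                              D_free = 1.5,
                              D_bound = 0.005,
                              k_on = 0.466,
                              k_off_sim = log(2) / 0.7,
                              p_telo = 0.05,
                              n_foci = 160,
                              D_foci = 5e-4,
                              nucleus_radius = 8.5,
                              nucleus_thickness = 4,
                              dZ = 0.7,
                              frame_interval = NULL,
                              exposure = NULL,
                              n_frames = NULL,
                              sigma_loc = 0.035,
                              k_bleach = NULL,
                              p_miss = 0,
                              pixel_size = 0.16,
                              seed = NULL,
                              optics = optics_config(),
                              telo_jitter = 0.03,
                              init_state = c("stationary", "free", "bound"),
                              track_gap_frames = 2) {
  mode <- match.arg(mode)
  init_state <- match.arg(init_state)
  if (mode == "fast") {
    frame_interval <- frame_interval %||% 0.0075
    exposure <- exposure %||% 0.0075
    n_frames <- n_frames %||% 1340L
    k_bleach <- k_bleach %||% 12
  } else {
    frame_interval <- frame_interval %||% 0.2
    exposure <- exposure %||% 0.1
    n_frames <- n_frames %||% 450L
    k_bleach <- k_bleach %||% log(2) / 5
  }
  check_count(n_molecules, "n_molecules")
  check_nonneg(D_free, "D_free"); check_nonneg(D_bound, "D_bound")
  check_nonneg(k_on, "k_on"); check_nonneg(k_off_sim, "k_off_sim")
  check_prob(p_telo, "p_telo"); check_prob(p_miss, "p_miss")
  check_count(n_foci, "n_foci"); check_nonneg(D_foci, "D_foci")
  check_pos(nucleus_radius, "nucleus_radius")
  check_pos(nucleus_thickness, "nucleus_thickness")
  check_pos(dZ, "dZ")
  if (is.finite(dZ) && dZ > nucleus_thickness)
    abort_param("`dZ` must not exceed `nucleus_thickness`")
  check_pos(frame_interval, "frame_interval")
  check_pos(exposure, "exposure")
  if (frame_interval < exposure)
    abort_param("`frame_interval` must be >= `exposure`")
  check_count(n_frames, "n_frames")
  check_nonneg(sigma_loc, "sigma_loc"); check_nonneg(k_bleach, "k_bleach")
  check_pos(pixel_size, "pixel_size")
  check_nonneg(telo_jitter, "telo_jitter")
  structure(list(mode = mode, n_molecules = as.integer(n_molecules),
                 D_free = D_free, D_bound = D_bound, k_on = k_on,
                 k_off_sim = k_off_sim, p_telo = p_telo,
                 n_foci = as.integer(n_foci), D_foci = D_foci,
                 nucleus_radius = nucleus_radius,
                 nucleus_thickness = nucleus_thickness, dZ = dZ,
                 frame_interval = frame_interval, exposure = exposure,
                 n_frames = as.integer(n_frames), sigma_loc = sigma_loc,
                 k_bleach = k_bleach, p_miss = p_miss,
                 pixel_size = pixel_size, seed = seed, optics = optics,
                 telo_jitter = telo_jitter, init_state = init_state,
                 track_gap_frames = as.integer(track_gap_frames)),
            class = "simulation_config")
}

# Per-molecule RNG substreams (L'Ecuyer-CMRG), so molecule m's trajectory is
# reproducible regardless of how many molecules are simulated before it.
rng_streams <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  suppressWarnings(set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG"))
  cur <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- cur
    cur <- parallel::nextRNGStream(cur)
  }
  streams
}

use_stream <- function(stream) {
  if (is.null(stream)) return(invisible(NULL))
  RNGkind("L'Ecuyer-CMRG")
  assign(".Random.seed", stream, envir = globalenv())
  invisible(NULL)
}

#' Simulate telomere marker foci
#'
#' Places `n_foci` focus centroids uniformly in the nuclear projection and,
#' when `D_foci > 0`, lets them perform slow Brownian motion with reflection
#' at the nuclear boundary. Telomere marker foci diffuse extremely slowly,
#' so the default motion is barely perceptible over a movie.
#'
#' @param config A [simulation_config()].
#' @return A tibble of class `foci_set` with columns `focus_id`, `frame`
#'   (`NA` for static foci), `x_um`, `y_um`.
#' @export
simulate_foci <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_foci < 0) abort_param("`n_foci` must be >= 0")
  if (!is.null(config$seed)) {
    old_kind <- RNGkind()
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      RNGkind(old_kind[1], old_kind[2], old_kind[3])
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    })
    use_stream(rng_streams(config$seed + 1L, 1L)[[1L]])
  }
  R <- config$nucleus_radius
  n <- config$n_foci
  if (n == 0L) {
    out <- tibble::tibble(focus_id = integer(), frame = integer(),
                          x_um = numeric(), y_um = numeric())
    return(new_foci_set(out, static = TRUE))
  }
  p0 <- runif_disk(n, R)
  if (config$D_foci <= 0) {
    out <- tibble::tibble(focus_id = seq_len(n), frame = NA_integer_,
                          x_um = p0[, 1], y_um = p0[, 2])
    return(new_foci_set(out, static = TRUE))
  }
  nf <- config$n_frames
  sd_step <- sqrt(2 * config$D_foci * config$frame_interval)
  x <- apply(rbind(p0[, 1], matrix(rnorm((nf - 1) * n, sd = sd_step), nf - 1, n)), 2, cumsum)
  y <- apply(rbind(p0[, 2], matrix(rnorm((nf - 1) * n, sd = sd_step), nf - 1, n)), 2, cumsum)
  # radial reflection, adequate for the tiny per-step displacements of foci
  r <- sqrt(x^2 + y^2)
  bad <- r > R
  if (any(bad)) {
    scl <- ifelse(bad, pmax(2 * R - r, 0.01 * R) / r, 1)
    x <- x * scl; y <- y * scl
  }
  out <- tibble::tibble(focus_id = rep(seq_len(n), each = nf),
                        frame = rep(seq_len(nf) - 1L, times = n),
                        x_um = as.vector(x), y_um = as.vector(y))
  new_foci_set(out, static = FALSE)
}

new_foci_set <- function(df, static = NA) {
  class(df) <- c("foci_set", class(df))
  attr(df, "static") <- static
  df
}

#' Static focus centroid positions
#'
#' Collapses a `foci_set` to one centroid per focus (time average for moving
#' foci).
#' @param foci A `foci_set`.
#' @return Matrix with columns `x_um`, `y_um`; one row per focus.
#' @export
foci_positions <- function(foci) {
  if (nrow(foci) == 0) return(matrix(numeric(), 0, 2, dimnames = list(NULL, c("x_um", "y_um"))))
  xs <- tapply(foci$x_um, foci$focus_id, mean)
  ys <- tapply(foci$y_um, foci$focus_id, mean)
  cbind(x_um = as.numeric(xs), y_um = as.numeric(ys))
}

# continuous-time two-state path: returns transition times in (0, t_total)
switch_times <- function(s0_bound, k_on, k_off, t_total) {
  t <- 0; bound <- s0_bound; out <- numeric(0)
  repeat {
    rate <- if (bound) k_off else k_on
    if (rate <= 0) break
    t <- t + rexp(1L, rate)
    if (t >= t_total) break
    out <- c(out, t)
    bound <- !bound
  }
  out
}

#' Simulate two-state molecule trajectories
#'
#' Molecules switch between free 3D Brownian diffusion (`D_free`) and a
#' chromatin-bound state (`D_bound`) with exact continuous-time kinetics
#' (rates `k_on`, `k_off_sim`). A fraction `p_telo` of binding events pins
#' the molecule at the nearest telomere focus centroid (plus Gaussian jitter
#' of sd `telo_jitter`); other events bind it at a uniformly drawn chromatin
#' point. Molecules photobleach at rate `k_bleach`, and localizations are
#' emitted (with Gaussian error `sigma_loc`) only when the molecule is
#' unbleached, within `dZ/2` of the focal plane, and not dropped by
#' `p_miss`.
#'
#' @param config A [simulation_config()].
#' @param foci A `foci_set` from [simulate_foci()] (or `NULL` for none).
#' @return A list with elements `truth` (ground-truth table: `molecule`,
#'   `frame`, `x_um`, `y_um`, `z_um`, `state`, `bleached`, `detected`,
#'   `relocated`) and `tracks` (a `track_table` of observed localizations
#'   with ground-truth `state` labels; detection gaps up to
#'   `track_gap_frames` are bridged, longer invisibility starts a new
#'   track, and the discontinuous jump introduced by a binding relocation
#'   starts a new track, as a displacement-gated tracker would).
#' @export
simulate_tracks <- function(config, foci = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  n_mol <- config$n_molecules
  empty_truth <- tibble::tibble(molecule = integer(), frame = integer(),
                                x_um = numeric(), y_um = numeric(),
                                z_um = numeric(), state = character(),
                                bleached = logical(), detected = logical(),
                                relocated = logical())
  if (n_mol == 0L) {
    return(list(truth = empty_truth,
                tracks = new_track_table(
                  tibble::tibble(track_id = integer(), molecule = integer(),
                                 frame = integer(), x_um = numeric(),
                                 y_um = numeric(), state = character()),
                  frame_interval = config$frame_interval,
                  pixel_size = config$pixel_size, source = "simulation")))
  }
  if (config$k_on == 0 && config$k_off_sim == 0 &&
      config$init_state == "stationary")
    abort_param("k_on = k_off_sim = 0 leaves the initial state undefined; set `init_state`")

  fp <- if (!is.null(foci) && nrow(foci) > 0) foci_positions(foci) else
    matrix(numeric(), 0, 2)
  R <- config$nucleus_radius
  hz <- config$nucleus_thickness / 2
  dz2 <- config$dZ / 2
  dt <- config$frame_interval
  nf <- config$n_frames
  t_total <- nf * dt
  frame_t <- (seq_len(nf) - 1L) * dt
  p_bound0 <- switch(config$init_state,
                     stationary = if (config$k_on + config$k_off_sim > 0)
                       config$k_on / (config$k_on + config$k_off_sim) else NA_real_,
                     free = 0, bound = 1)

  streams <- rng_streams(config$seed, n_mol + 1L)
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })

  res <- vector("list", n_mol)
  for (m in seq_len(n_mol)) {
    if (!is.null(streams)) use_stream(streams[[m + 1L]])
    res[[m]] <- simulate_one_molecule(m, config, fp, R, hz, dz2, dt, nf,
                                      t_total, frame_t, p_bound0)
  }
  truth <- tibble::tibble(
    molecule = unlist(lapply(res, `[[`, "molecule")),
    frame = unlist(lapply(res, `[[`, "frame")),
    x_um = unlist(lapply(res, `[[`, "x_um")),
    y_um = unlist(lapply(res, `[[`, "y_um")),
    z_um = unlist(lapply(res, `[[`, "z_um")),
    state = unlist(lapply(res, `[[`, "state")),
    bleached = unlist(lapply(res, `[[`, "bleached")),
    detected = unlist(lapply(res, `[[`, "detected")),
    relocated = unlist(lapply(res, `[[`, "relocated")))
  if (!is.null(streams)) use_stream(streams[[1L]])  # localization-noise stream
  tracks <- build_sim_tracks(truth, config)
  list(truth = truth, tracks = tracks)
}

simulate_one_molecule <- function(m, config, fp, R, hz, dz2, dt, nf,
                                  t_total, frame_t, p_bound0) {
  pos <- c(runif_disk(1, R), runif(1, -hz, hz))
  bound0 <- runif(1) < p_bound0
  # photobleaching is path-independent, so the trajectory only needs to be
  # propagated until the bleach frame
  bleach_time <- if (config$k_bleach > 0) rexp(1, config$k_bleach) else Inf
  nfm <- if (is.finite(bleach_time))
    min(nf, as.integer(floor(bleach_time / dt)) + 2L) else nf
  frame_t <- frame_t[seq_len(nfm)]
  t_total <- nfm * dt
  tr <- switch_times(bound0, config$k_on, config$k_off_sim, t_total)
  bnd <- c(0, tr, t_total)
  n_seg <- length(bnd) - 1L
  seg_bound <- rep(c(bound0, !bound0), length.out = n_seg)

  x <- numeric(nfm); y <- numeric(nfm); z <- numeric(nfm)
  state <- character(nfm)
  reloc <- logical(nfm)
  cur <- pos
  for (s in seq_len(n_seg)) {
    t0 <- bnd[s]; t1 <- bnd[s + 1L]
    idx <- which(frame_t >= t0 & frame_t < t1)
    lab <- "free"
    if (seg_bound[s]) {
      # choose the binding site at the event start
      telo <- nrow(fp) > 0 && runif(1) < config$p_telo
      if (telo) {
        d2 <- (fp[, 1] - cur[1])^2 + (fp[, 2] - cur[2])^2
        k <- which.min(d2)
        site <- c(fp[k, 1] + rnorm(1, sd = config$telo_jitter),
                  fp[k, 2] + rnorm(1, sd = config$telo_jitter), cur[3])
        lab <- "bound_telomeric"
      } else {
        # a uniformly drawn chromatin point; the emitted track table splits
        # tracks at relocation jumps beyond the linking gate, as a tracker
        # would
        site <- c(runif_disk(1, R), runif(1, -hz, hz))
        lab <- "bound_nontelomeric"
      }
      # the binding event moves the molecule discontinuously; mark the
      # first frame affected so the emitted track table can split there
      fidx <- if (length(idx)) idx[1] else which(frame_t >= t0)[1]
      if (!is.na(fidx)) reloc[fidx] <- TRUE
      tt <- c(t0, frame_t[idx], t1)
      sdv <- sqrt(2 * config$D_bound * diff(tt))
      np <- length(sdv)
      dx <- cumsum(rnorm(np, sd = sdv)); dy <- cumsum(rnorm(np, sd = sdv))
      dzv <- cumsum(rnorm(np, sd = sdv))
      if (length(idx)) {
        x[idx] <- site[1] + dx[seq_along(idx)]
        y[idx] <- site[2] + dy[seq_along(idx)]
        z[idx] <- reflect_interval(site[3] + dzv[seq_along(idx)], -hz, hz)
        state[idx] <- lab
      }
      cur <- c(site[1] + dx[np], site[2] + dy[np],
               reflect_interval(site[3] + dzv[np], -hz, hz))
    } else {
      tt <- c(t0, frame_t[idx], t1)
      sdv <- sqrt(2 * config$D_free * diff(tt))
      np <- length(sdv)
      dx <- cumsum(rnorm(np, sd = sdv)); dy <- cumsum(rnorm(np, sd = sdv))
      dzv <- cumsum(rnorm(np, sd = sdv))
      xs <- cur[1] + dx; ys <- cur[2] + dy
      zs <- reflect_interval(cur[3] + dzv, -hz, hz)
      rr <- sqrt(xs^2 + ys^2)
      if (any(rr > R)) {
        # sequential radial reflection from the first boundary contact
        first <- which(rr > R)[1]
        px <- if (first > 1) xs[first - 1] else cur[1]
        py <- if (first > 1) ys[first - 1] else cur[2]
        for (j in first:np) {
          px <- px + (if (j == 1) dx[1] else dx[j] - dx[j - 1])
          py <- py + (if (j == 1) dy[1] else dy[j] - dy[j - 1])
          r1 <- sqrt(px^2 + py^2)
          while (r1 > R) {
            scl <- (2 * R - r1) / r1
            if (scl <= 0) { scl <- 0.5 * R / r1 }  # pathological huge step
            px <- px * scl; py <- py * scl
            r1 <- sqrt(px^2 + py^2)
          }
          xs[j] <- px; ys[j] <- py
        }
      }
      if (length(idx)) {
        x[idx] <- xs[seq_along(idx)]; y[idx] <- ys[seq_along(idx)]
        z[idx] <- zs[seq_along(idx)]
        state[idx] <- "free"
      }
      cur <- c(xs[np], ys[np], zs[np])
    }
  }

  in_slice <- if (is.finite(dz2)) abs(z) <= dz2 else rep(TRUE, nfm)
  bleached <- frame_t >= bleach_time
  detected <- !bleached & in_slice
  if (config$p_miss > 0) detected <- detected & (runif(nfm) >= config$p_miss)
  list(molecule = rep.int(m, nfm), frame = seq_len(nfm) - 1L, x_um = x,
       y_um = y, z_um = z, state = state, bleached = bleached,
       detected = detected, relocated = reloc)
}

# split detected localizations into tracks, bridging short detection gaps,
# and add localization noise
build_sim_tracks <- function(truth, config) {
  det <- truth[truth$detected, , drop = FALSE]
  if (nrow(det) == 0) {
    return(new_track_table(
      tibble::tibble(track_id = integer(), molecule = integer(),
                     frame = integer(), x_um = numeric(), y_um = numeric(),
                     state = character()),
      frame_interval = config$frame_interval,
      pixel_size = config$pixel_size, source = "simulation"))
  }
  ord <- order(det$molecule, det$frame)
  det <- det[ord, ]
  n <- nrow(det)
  gap_max <- config$track_gap_frames + 1L
  # split on long invisibility and at binding relocations: a tracker would
  # not connect the discontinuous jump a binding event introduces
  new_seg <- c(TRUE, diff(det$frame) > gap_max | diff(det$molecule) != 0) |
    det$relocated
  track_id <- cumsum(new_seg)
  out <- tibble::tibble(
    track_id = track_id,
    molecule = det$molecule,
    frame = det$frame,
    x_um = det$x_um + rnorm(n, sd = config$sigma_loc),
    y_um = det$y_um + rnorm(n, sd = config$sigma_loc),
    state = det$state)
  new_track_table(out, frame_interval = config$frame_interval,
                  pixel_size = config$pixel_size, source = "simulation")
}

#' Simulate observed binding dwell times under photobleaching
#'
#' True dwell times are exponential with half-life `t_half_true`; the
#' observation of each dwell is cut short by photobleaching (rate
#' `k_bleach`) and by the end of the movie (`max_duration`), and is
#' discretized to whole frame intervals (a dwell observed over `k + 1`
#' frames has duration `k * frame_interval`).
#'
#' @param n Number of binding events.
#' @param t_half_true True dwell half-life (s), > 0.
#' @param k_bleach Photobleaching rate (1/s).
#' @param frame_interval Frame spacing (s).
#' @param max_duration Maximum observable duration (s), may be `Inf`.
#' @param seed Optional integer seed.
#' @return Tibble with `dwell_true`, `bleach_time`, `duration` (discretized
#'   observed duration, s) and `censored` (`TRUE` when the observation was
#'   cut short by bleaching or the movie end).
#' @export
simulate_dwell_times <- function(n, t_half_true, k_bleach = 0,
                                 frame_interval = 0.2, max_duration = Inf,
                                 seed = NULL) {
  check_count(n, "n")
  check_pos(t_half_true, "t_half_true")
  check_nonneg(k_bleach, "k_bleach")
  check_pos(frame_interval, "frame_interval")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L)
    return(tibble::tibble(dwell_true = numeric(), bleach_time = numeric(),
                          duration = numeric(), censored = logical()))
  dw <- rexp(n, log(2) / t_half_true)
  bl <- if (k_bleach > 0) rexp(n, k_bleach) else rep(Inf, n)
  obs <- pmin(dw, bl, max_duration)
  tibble::tibble(dwell_true = dw, bleach_time = bl,
                 duration = floor(obs / frame_interval) * frame_interval,
                 censored = obs < dw)
}
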
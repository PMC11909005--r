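#' Two-state jump-length fit configuration
#'
#' Defaults reproduce the kinetic-modelling settings used for 134 fps
#' nuclear single-particle tracking: 7.5 ms time gap, a 0.7 um axial
#' detection slice, two bridged gap frames, nine time points (eight
#' displacement lags), 10 nm histogram bins, at most four jumps per track
#' per lag, PDF fitting, and free/bound diffusivity boxes of [0.5, 10] and
#' [0.0001, 0.5] um^2/s.
#'
#' @param time_gap Frame spacing (s).
#' @param dZ Axial detection slice thickness (um).
#' @param gaps_allowed Bridged gap frames within tracks.
#' @param time_points Number of positions per track considered; lags run
#'   `1 .. time_points - 1` frames.
#' @param bin_width Histogram bin width (um).
#' @param jumps_to_consider Maximum jumps per track per lag (earliest
#'   first), mitigating the over-representation of long-lived bound tracks.
#' @param fit_mode `"PDF"` (per-bin probability masses) or `"CDF"`
#'   (cumulative curve).
#' @param D_free_bounds,D_bound_bounds Fit boxes (um^2/s).
#' @param sigma_loc Localization error sd (um) entering the displacement
#'   variance as `s^2 = D * dt + sigma_loc^2`.
#' @param fit_sigma Fit `sigma_loc` as a fourth parameter instead of
#'   fixing it.
#' @param z_corr_mode Defocalization correction for the free component:
#'   `"monte_carlo"` (sampling-aware axial random-walk correction with
#'   re-entry, the gap-bridging rule, the per-track jump cap and
#'   photobleaching — i.e. the exact counting semantics of
#'   [compile_histograms()]; the default), `"series"` (absorbing-boundary
#'   spectral solution) or `"none"`.
#' @param k_bleach Photobleaching rate (1/s) assumed by the sampling-aware
#'   correction; track lengths (and hence how often the per-track jump cap
#'   binds) are bleaching-limited. Estimate it from the channel intensity
#'   decay with [fit_bleach()]; must be > 0 in `"monte_carlo"` mode.
#' @param min_jumps Minimum pooled jump count required to fit.
#' @param n_starts Multi-start count (Latin hypercube over the box).
#' @param fit_seed Sub-seed for the multistart design and the Monte-Carlo
#'   correction table (fixed so fits are deterministic).
#' @param z_walkers Walkers per grid point for the Monte-Carlo correction.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(time_gap = 0.0075, dZ = 0.7, gaps_allowed = 2,
                       time_points = 9, bin_width = 0.01,
                       jumps_to_consider = 4,
                       fit_mode = c("PDF", "CDF"),
                       D_free_bounds = c(0.5, 10),
                       D_bound_bounds = c(1e-4, 0.5),
                       sigma_loc = 0.035, fit_sigma = FALSE,
                       z_corr_mode = c("monte_carlo", "series", "none"),
                       k_bleach = 12, min_jumps = 1000, n_starts = 8,
                       fit_seed = 17, z_walkers = 4e4) {
  fit_mode <- match.arg(fit_mode)
  z_corr_mode <- match.arg(z_corr_mode)
  check_pos(time_gap, "time_gap"); check_pos(dZ, "dZ")
  check_count(gaps_allowed, "gaps_allowed")
  if (time_points < 2) abort_param("`time_points` must be >= 2")
  check_pos(bin_width, "bin_width")
  check_count(jumps_to_consider, "jumps_to_consider")
  if (diff(D_free_bounds) <= 0 || diff(D_bound_bounds) <= 0)
    abort_param("diffusivity bounds must be ordered (lower < upper)")
  check_nonneg(sigma_loc, "sigma_loc")
  structure(list(time_gap = time_gap, dZ = dZ,
                 gaps_allowed = as.integer(gaps_allowed),
                 time_points = as.integer(time_points),
                 bin_width = bin_width,
                 jumps_to_consider = as.integer(jumps_to_consider),
                 fit_mode = fit_mode, D_free_bounds = D_free_bounds,
                 D_bound_bounds = D_bound_bounds, sigma_loc = sigma_loc,
                 fit_sigma = fit_sigma, z_corr_mode = z_corr_mode,
                 k_bleach = k_bleach, min_jumps = min_jumps,
                 n_starts = as.integer(n_starts),
                 fit_seed = fit_seed, z_walkers = z_walkers),
            class = "fit_config")
}

#' Compile jump-length histograms across time lags
#'
#' For each lag `g = 1 .. time_points - 1`, collects planar displacements
#' between localizations `g` frames apart within the same track (at most
#' `jumps_to_consider` per track per lag, earliest first). A displacement
#' spanning a bridged gap contributes to the lag equal to its true frame
#' separation.
#'
#' @param tracks A `track_table` whose frame interval equals
#'   `config$time_gap`.
#' @param config A [fit_config()].
#' @return An object of class `jump_histograms`: list with `lags`,
#'   `bin_edges`, `counts` (bins x lags matrix), `n_jumps` (per lag) and
#'   `config`.
#' @export
compile_histograms <- function(tracks, config = fit_config()) {
  stopifnot(inherits(config, "fit_config"))
  lags <- seq_len(config$time_points - 1L)
  bw <- config$bin_width
  if (nrow(tracks) == 0) {
    edges <- seq(0, bw, by = bw)
    return(structure(list(lags = lags, bin_edges = edges,
                          counts = matrix(0L, 1, length(lags)),
                          n_jumps = rep(0L, length(lags)), config = config),
                     class = "jump_histograms"))
  }
  tr <- tracks[order(tracks$track_id, tracks$frame), ]
  K <- max(tr$frame) + config$time_points + 2
  key <- as.numeric(tr$track_id) * K + tr$frame
  jumps <- vector("list", length(lags))
  for (gi in seq_along(lags)) {
    g <- lags[gi]
    j <- match(key + g, key)
    ok <- !is.na(j)
    if (!any(ok)) { jumps[[gi]] <- numeric(0); next }
    i <- which(ok); j <- j[ok]
    # earliest-first cap per track (rows are frame-ordered within track)
    nth <- stats::ave(rep(1, length(i)), tr$track_id[i], FUN = cumsum)
    keep <- nth <= config$jumps_to_consider
    i <- i[keep]; j <- j[keep]
    jumps[[gi]] <- sqrt((tr$x_um[j] - tr$x_um[i])^2 +
                        (tr$y_um[j] - tr$y_um[i])^2)
  }
  rmax <- max(c(unlist(jumps), bw))
  edges <- seq(0, (floor(rmax / bw) + 1) * bw, by = bw)
  counts <- vapply(jumps, function(r) {
    if (!length(r)) return(integer(length(edges) - 1L))
    tabulate(findInterval(r, edges, rightmost.closed = FALSE,
                          left.open = FALSE), length(edges) - 1L)
  }, integer(length(edges) - 1L))
  structure(list(lags = lags, bin_edges = edges,
                 counts = matrix(counts, ncol = length(lags)),
                 n_jumps = vapply(jumps, length, 1L), config = config),
            class = "jump_histograms")
}

#' @export
print.jump_histograms <- function(x, ...) {
  cat(sprintf("<jump_histograms> lags %s; n_jumps: %s (total %d)\n",
              paste(range(x$lags), collapse = "-"),
              paste(x$n_jumps, collapse = ", "), sum(x$n_jumps)))
  invisible(x)
}

#' Fraction of diffusing molecules still counted inside the axial slice
#'
#' A molecule with diffusivity `D`, initially uniform in a slice of
#' thickness `dZ`, is observed again after time `t` only if it has not been
#' lost from the detection slice. `mode = "series"` gives the
#' absorbing-boundary spectral solution
#' `S = sum_{k odd} (8 / (k^2 pi^2)) exp(-k^2 pi^2 D t / dZ^2)` (a molecule
#' leaving the slice never returns). `mode = "monte_carlo"` samples the
#' axial random walk at frame resolution and permits re-entry: the
#' molecule must be inside the slice at both endpoint frames and must not
#' be outside for more than `gaps_allowed` consecutive intermediate frames
#' (which would split the track). `mode = "none"` returns 1.
#'
#' @param D Diffusivity (um^2/s), >= 0.
#' @param t Elapsed time (s), > 0.
#' @param dZ Slice thickness (um), > 0.
#' @param mode `"series"`, `"monte_carlo"` or `"none"`.
#' @param frame_interval Frame spacing for the Monte-Carlo walk; defaults
#'   to `t` (single step, endpoint-only criterion).
#' @param gaps_allowed Bridged gap frames for the Monte-Carlo walk.
#' @param n_walkers Monte-Carlo sample size.
#' @param seed Seed for the Monte-Carlo walk (local to the call).
#' @return Probability in (0, 1].
#' @export
defocalization_fraction <- function(D, t, dZ,
                                    mode = c("series", "monte_carlo", "none"),
                                    frame_interval = NULL, gaps_allowed = 0,
                                    n_walkers = 1e5, seed = 1) {
  mode <- match.arg(mode)
  if (dZ <= 0) abort_param("`dZ` must be positive")
  check_nonneg(D, "D"); check_pos(t, "t")
  if (mode == "none" || D == 0) return(1)
  if (mode == "series") {
    tau <- D * t / dZ^2
    kmax <- ceiling(6 / (pi * sqrt(max(tau, 1e-12)))) + 11
    k <- seq(1, max(kmax, 11), by = 2)
    return(min(1, sum(8 / (k^2 * pi^2) * exp(-k^2 * pi^2 * tau))))
  }
  dt <- frame_interval %||% t
  n_steps <- max(1L, as.integer(round(t / dt)))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  z_survival_mc(D, dZ, dt, n_steps, gaps_allowed, n_walkers)
}

# Monte-Carlo survival of the axial coordinate: inside at step 0 and
# n_steps, never outside for > gaps consecutive intermediate steps.
z_survival_mc <- function(D, dZ, dt, n_steps, gaps, n_walkers) {
  half <- dZ / 2
  z <- runif(n_walkers, -half, half)
  run <- integer(n_walkers)    # current consecutive-out run length
  broken <- logical(n_walkers)
  sdstep <- sqrt(2 * D * dt)
  for (s in seq_len(n_steps)) {
    z <- z + rnorm(n_walkers, sd = sdstep)
    out <- abs(z) > half
    run <- ifelse(out, run + 1L, 0L)
    if (s < n_steps) broken <- broken | run > gaps
  }
  mean(!broken & abs(z) <= half)
}

# Sampling-aware Monte-Carlo correction -------------------------------------
#
# The per-lag weight of the free component in the fitted mixture must equal
# the ratio of counted free jumps to counted bound jumps per unit in-slice
# occupancy, under the exact counting semantics of compile_histograms():
# detection only inside the slice, tracks split after more than
# `gaps_allowed` invisible frames, at most `jumps_to_consider` jumps per
# track per lag (earliest first), and both jump endpoints unbleached.
#
# Bound molecules hold their axial position, so their per-occupancy yield
# has a closed form: with per-frame fluorophore survival s =
# exp(-k_bleach * dt) and cap c, a bound track's visible length L is
# geometric (P(L >= l) = s^(l-1)) and
#   Y_b(g) = E[min(c, (L-g)^+)] / E[L] = s^g * (1 - s^c).
# The free-state yield Y_f(g, D) is estimated by simulating the axial
# random walk with the same bleaching, gap and cap rules. The correction
# passed to the mixture is Z_g(D) = Y_f(g, D) / Y_b(g), interpolated over a
# log-spaced diffusivity grid (one monotone spline per lag); results are
# cached per configuration signature.

telospt_cache <- new.env(parent = emptyenv())

free_jump_yield <- function(D, config, n_walkers) {
  dt <- config$time_gap
  half <- config$dZ / 2
  gaps <- config$gaps_allowed
  cap <- config$jumps_to_consider
  gmax <- config$time_points - 1L
  s <- exp(-config$k_bleach * dt)
  Tmax <- min(200L, as.integer(ceiling(log(0.001) / log(s))) + 1L)
  M <- as.integer(n_walkers)
  L <- pmin(1L + stats::rgeom(M, 1 - s), Tmax)     # visible frames
  W <- half + 3 * sqrt(2 * D * dt * mean(L))       # start window (slab is
  z <- runif(M, -W, W)                             # locally unbounded)
  sdstep <- sqrt(2 * D * dt)
  fragid <- integer(M); runout <- integer(M)
  capcnt <- matrix(0L, M, gmax)
  ring_vis <- matrix(FALSE, M, gmax + 1L)
  ring_frag <- matrix(0L, M, gmax + 1L)
  slots <- 0; pairs <- numeric(gmax)
  for (t in 0:(Tmax - 1L)) {
    if (t > 0) {
      alive <- L > t
      z[alive] <- z[alive] + rnorm(sum(alive), sd = sdstep)
      vis <- alive & abs(z) <= half
    } else vis <- abs(z) <= half
    newfrag <- vis & (fragid == 0L | runout > gaps)
    if (any(newfrag)) {
      fragid[newfrag] <- fragid[newfrag] + 1L
      capcnt[newfrag, ] <- 0L
    }
    runout[vis] <- 0L
    runout[!vis] <- runout[!vis] + 1L
    col <- t %% (gmax + 1L) + 1L
    ring_vis[, col] <- vis
    ring_frag[, col] <- ifelse(vis, fragid, -1L)
    slots <- slots + sum(vis)
    for (g in seq_len(min(t, gmax))) {
      colg <- (t - g) %% (gmax + 1L) + 1L
      ok <- vis & ring_vis[, colg] & ring_frag[, colg] == fragid &
        capcnt[, g] < cap
      if (any(ok)) {
        pairs[g] <- pairs[g] + sum(ok)
        capcnt[ok, g] <- capcnt[ok, g] + 1L
      }
    }
  }
  if (slots == 0) return(rep(0, gmax))
  pairs / slots
}

z_corr_table <- function(config) {
  key <- config_hash(list(config$time_gap, config$dZ, config$gaps_allowed,
                          config$time_points, config$jumps_to_consider,
                          config$k_bleach, config$z_walkers,
                          config$fit_seed, config$D_free_bounds))
  hit <- telospt_cache[[key]]
  if (!is.null(hit)) return(hit)
  if (config$k_bleach <= 0)
    abort_param("the sampling-aware z correction requires `k_bleach` > 0; use z_corr_mode = \"series\" for bleaching-free data")
  lags <- seq_len(config$time_points - 1L)
  s <- exp(-config$k_bleach * config$time_gap)
  yb <- s^lags * (1 - s^config$jumps_to_consider)
  Dgrid <- exp(seq(log(config$D_free_bounds[1] * 0.8),
                   log(config$D_free_bounds[2] * 1.2), length.out = 14))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$fit_seed)
  vals <- matrix(NA_real_, length(Dgrid), length(lags))
  for (d in seq_along(Dgrid)) {
    vals[d, ] <- free_jump_yield(Dgrid[d], config, config$z_walkers) / yb
  }
  vals[vals <= 0] <- 1e-6
  splines <- lapply(seq_along(lags), function(gi)
    stats::splinefun(log(Dgrid), vals[, gi], method = "monoH.FC"))
  out <- function(D, lag) pmax(1e-6, splines[[lag]](log(D)))
  telospt_cache[[key]] <- out
  out
}

z_corr_fun <- function(config) {
  switch(config$z_corr_mode,
         none = function(D, lag) 1,
         series = function(D, lag) {
           defocalization_fraction(D, lag * config$time_gap, config$dZ,
                                   mode = "series")
         },
         monte_carlo = z_corr_table(config))
}

#' Two-state jump-length probability density
#'
#' Rayleigh mixture of a bound and a free component with per-component
#' displacement variance `s^2(D) = D * dt + sigma_loc^2` at lag time
#' `dt = lag * time_gap`. The free component is attenuated by the
#' defocalization fraction `Z_g` and the mixture is renormalized to
#' integrate to one over `r in [0, Inf)`:
#' `w_b = F / (F + Z_g (1 - F))`.
#'
#' @param r Jump lengths (um), >= 0.
#' @param lag Lag in frames.
#' @param params List with `D_free`, `D_bound`, `F_bound` (and optionally
#'   `sigma_loc` overriding the config value), e.g. a `two_state_fit`.
#' @param config A [fit_config()].
#' @return Density values (per um) at `r`.
#' @export
model_pdf <- function(r, lag, params, config = fit_config()) {
  if (any(r < 0)) abort_param("`r` must be non-negative")
  p <- check_two_state_params(params, config)
  dtl <- lag * config$time_gap
  s2b <- p$D_bound * dtl + p$sigma_loc^2
  s2f <- p$D_free * dtl + p$sigma_loc^2
  Z <- z_corr_fun(config)(p$D_free, lag)
  wb <- p$F_bound / (p$F_bound + Z * (1 - p$F_bound))
  wb * rayleigh_pdf(r, s2b) + (1 - wb) * rayleigh_pdf(r, s2f)
}

rayleigh_pdf <- function(r, s2) r / (2 * s2) * exp(-r^2 / (4 * s2))
rayleigh_cdf <- function(r, s2) 1 - exp(-r^2 / (4 * s2))

check_two_state_params <- function(params, config) {
  p <- list(D_free = params$D_free, D_bound = params$D_bound,
            F_bound = params$F_bound,
            sigma_loc = params$sigma_loc %||% config$sigma_loc)
  if (is.null(p$D_free) || is.null(p$D_bound) || is.null(p$F_bound))
    abort_param("params must provide D_free, D_bound and F_bound")
  if (p$F_bound < 0 || p$F_bound > 1)
    abort_param("F_bound must lie in [0, 1]")
  if (p$D_free < config$D_free_bounds[1] - 1e-9 ||
      p$D_free > config$D_free_bounds[2] + 1e-9)
    abort_param("D_free outside the configured bounds")
  if (p$D_bound < config$D_bound_bounds[1] - 1e-9 ||
      p$D_bound > config$D_bound_bounds[2] + 1e-9)
    abort_param("D_bound outside the configured bounds")
  p
}

# per-bin model probability masses for one lag (exact bin integrals)
model_bin_mass <- function(edges, lag, D_free, D_bound, F_bound, sigma,
                           config, zfun) {
  dtl <- lag * config$time_gap
  s2b <- D_bound * dtl + sigma^2
  s2f <- D_free * dtl + sigma^2
  Z <- zfun(D_free, lag)
  wb <- F_bound / (F_bound + Z * (1 - F_bound))
  cdf <- wb * rayleigh_cdf(edges, s2b) + (1 - wb) * rayleigh_cdf(edges, s2f)
  diff(cdf)
}

#' Fit the two-state bound/free model to jump-length histograms
#'
#' Weighted least squares of the two-state Rayleigh-mixture bin masses
#' (or cumulative curve in CDF mode) against the empirical per-lag
#' probability masses, jointly over all lags with per-lag weights
#' proportional to jump counts. The bounded box is explored with a
#' Latin-hypercube multistart and L-BFGS-B.
#'
#' @param histograms A `jump_histograms` from [compile_histograms()].
#' @param config A [fit_config()] (defaults to the one stored in
#'   `histograms`).
#' @return An object of class `two_state_fit`: `D_free`, `D_bound`,
#'   `F_bound`, `sigma_loc_used`, `residual_norm`, `n_jumps_total`,
#'   `converged`, `n_starts_converged`.
#' @export
fit_two_state <- function(histograms, config = NULL) {
  stopifnot(inherits(histograms, "jump_histograms"))
  config <- config %||% histograms$config
  n_total <- sum(histograms$n_jumps)
  if (n_total < config$min_jumps)
    abort_insufficient(sprintf(
      "insufficient data: %d jumps pooled, but at least %d are required",
      n_total, config$min_jumps))
  edges <- histograms$bin_edges
  use <- which(histograms$n_jumps > 0)
  emp <- lapply(use, function(gi)
    histograms$counts[, gi] / histograms$n_jumps[gi])
  if (config$fit_mode == "CDF") emp <- lapply(emp, cumsum)
  w <- histograms$n_jumps[use] / n_total
  zfun <- z_corr_fun(config)
  lags <- histograms$lags

  obj <- function(par) {
    Df <- exp(par[1]); Db <- exp(par[2]); Fb <- par[3]
    sg <- if (config$fit_sigma) par[4] else config$sigma_loc
    ss <- 0
    for (k in seq_along(use)) {
      m <- model_bin_mass(edges, lags[use[k]], Df, Db, Fb, sg, config, zfun)
      if (config$fit_mode == "CDF") m <- cumsum(m)
      ss <- ss + w[k] * sum((emp[[k]] - m)^2)
    }
    ss
  }

  lo <- c(log(config$D_free_bounds[1]), log(config$D_bound_bounds[1]), 0)
  hi <- c(log(config$D_free_bounds[2]), log(config$D_bound_bounds[2]), 1)
  if (config$fit_sigma) { lo <- c(lo, 0.005); hi <- c(hi, 0.1) }

  # deterministic Latin-hypercube multistart
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(config$fit_seed)
  starts <- lhs::randomLHS(max(1L, config$n_starts - 1L), length(lo))
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  starts <- t(t(starts) * (hi - lo) + lo)
  centre <- (lo + hi) / 2; centre[3] <- 0.3
  starts <- rbind(centre, starts)

  best <- NULL; n_conv <- 0L
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 500, factr = 1e9)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) n_conv <- n_conv + 1L
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("two-state fit failed from every start")
  p <- best$par
  structure(list(D_free = exp(p[1]), D_bound = exp(p[2]), F_bound = p[3],
                 sigma_loc_used = if (config$fit_sigma) p[4] else config$sigma_loc,
                 residual_norm = sqrt(best$value),
                 n_jumps_total = n_total,
                 converged = best$convergence == 0,
                 n_starts_converged = n_conv,
                 z_corr_mode = config$z_corr_mode,
                 fit_mode = config$fit_mode),
            class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  cat(sprintf(paste0("<two_state_fit> D_free = %.3f um^2/s, D_bound = %.4f ",
                     "um^2/s, bound fraction = %.1f%% (n = %d jumps, %s)\n"),
              x$D_free, x$D_bound, 100 * x$F_bound, x$n_jumps_total,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Bound-state occupancy mass of a fitted track group
#'
#' Counted jumps are not proportional to molecule-time: per unit in-slice
#' occupancy a bound molecule yields `Y_b(g)` counted jumps at lag `g` and
#' a free molecule `Z_g(D) * Y_b(g)` (see the sampling-aware correction in
#' [fit_config()]). The total count `N` of a group with bound fraction `F`
#' therefore scales as `(O_b + O_f) * sum_g Y_b(g) (F + Z_g (1-F))`, and
#' the group's bound occupancy is
#' `O_b = N * F / sum_g [Y_b(g) (F + Z_g(D)(1-F))]` (up to a common
#' constant). Comparing groups from the same movie by this mass is the
#' occupancy-correct way to combine per-group fits.
#'
#' @param fit A `two_state_fit` for the group.
#' @param n_jumps_total Pooled jump count of the group.
#' @param config The [fit_config()] used for the fit.
#' @return Bound occupancy mass (arbitrary common units).
#' @export
bound_occupancy_mass <- function(fit, n_jumps_total, config) {
  FB <- fit$F_bound
  lags <- seq_len(config$time_points - 1L)
  if (config$z_corr_mode == "monte_carlo") {
    s <- exp(-config$k_bleach * config$time_gap)
    yb <- s^lags * (1 - s^config$jumps_to_consider)
  } else {
    yb <- rep(1, length(lags))
  }
  zf <- z_corr_fun(config)
  zz <- vapply(lags, function(g) zf(fit$D_free, g), numeric(1))
  n_jumps_total * FB / sum(yb * (FB + zz * (1 - FB)))
}

#' Compile histograms and fit in one call
#'
#' @param tracks A `track_table`.
#' @param config A [fit_config()].
#' @return A `two_state_fit` with the histograms attached as attribute
#'   `histograms`.
#' @export
fit_tracks <- function(tracks, config = fit_config()) {
  h <- compile_histograms(tracks, config)
  f <- fit_two_state(h, config)
  attr(f, "histograms") <- h
  f
}
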
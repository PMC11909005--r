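# shared fixtures built in code

# binding rate that yields a target stationary bound fraction
kon_for <- function(f_bound, k_off) k_off * f_bound / (1 - f_bound)

K_OFF_NON <- log(2) / 0.7   # non-telomeric unbinding (t1/2 = 0.7 s)

# S-phase-like fast-mode conditions at a chosen bound fraction / mobility
fast_sim <- function(f_bound, D_free, n_molecules, p_telo = 0, n_foci = 0,
                     ...) {
  simulation_config("fast", n_molecules = n_molecules, D_free = D_free,
                    D_bound = 0.005, k_on = kon_for(f_bound, K_OFF_NON),
                    k_off_sim = K_OFF_NON, sigma_loc = 0.035,
                    p_telo = p_telo, n_foci = n_foci, ...)
}

# independent absorbing-boundary Monte-Carlo oracle for the axial survival
# fraction: sub-stepped walk with Brownian-bridge boundary-crossing
# correction
absorbing_mc_oracle <- function(D, t, dZ, n = 2e5, substeps = 50, seed = 42) {
  set.seed(seed)
  del <- t / substeps
  sdv <- sqrt(2 * D * del)
  z <- runif(n, 0, dZ)
  alive <- rep(TRUE, n)
  for (s in seq_len(substeps)) {
    z2 <- z + rnorm(n, sd = sdv)
    inside <- z2 > 0 & z2 < dZ
    p0 <- exp(-z * z2 / (D * del))
    pL <- exp(-(dZ - z) * (dZ - z2) / (D * del))
    u <- runif(n)
    alive <- alive & inside & (u > pmax(p0 + pL - p0 * pL, 0))
    z <- z2
  }
  mean(alive)
}

# deterministic sparse localization field: k well-separated random walks
# (spacing >> r_max), optionally with missing frames
make_sparse_tracks <- function(n_tracks = 4, n_frames = 60, step_sd = 0.05,
                               spacing = 6, drop = NULL, seed = 99) {
  set.seed(seed)
  centres <- expand.grid(x = spacing * (0:1), y = spacing * (0:1))
  centres <- centres[seq_len(n_tracks), ]
  loc <- do.call(rbind, lapply(seq_len(n_tracks), function(k) {
    data.frame(truth_id = k, frame = 0:(n_frames - 1),
               x_um = centres$x[k] + cumsum(rnorm(n_frames, sd = step_sd)),
               y_um = centres$y[k] + cumsum(rnorm(n_frames, sd = step_sd)))
  }))
  if (!is.null(drop)) loc <- loc[!(loc$truth_id == drop$id & loc$frame %in% drop$frames), ]
  loc[order(loc$frame, loc$truth_id), ]
}

# render one Gaussian spot + iid Gaussian noise into an image
spot_image <- function(nx = 64, ny = 64, x_px = 12.3, y_px = 45.7,
                       amplitude = 80, noise_sd = 8, bg = 100,
                       sigma_px = 0.21 * 0.672 / 1.49 / 0.16, seed = 7) {
  set.seed(seed)
  img <- matrix(rnorm(nx * ny, bg, noise_sd), ny, nx)
  cols <- matrix(rep(seq_len(nx) - 0.5, each = ny), ny, nx)
  rows <- matrix(rep(seq_len(ny) - 0.5, times = nx), ny, nx)
  img + amplitude * exp(-((cols - x_px)^2 + (rows - y_px)^2) / (2 * sigma_px^2))
}
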
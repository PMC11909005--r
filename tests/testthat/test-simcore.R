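test_that("simulate_foci handles the empty and static cases", {
  cfg <- simulation_config("fast", n_foci = 0, seed = 1)
  expect_equal(nrow(simulate_foci(cfg)), 0)

  cfg <- simulation_config("fast", n_foci = 160, D_foci = 0, seed = 1)
  foci <- simulate_foci(cfg)
  expect_equal(nrow(foci), 160)
  expect_true(all(is.na(foci$frame)))
  expect_true(all(sqrt(foci$x_um^2 + foci$y_um^2) <= cfg$nucleus_radius))
})

test_that("focus Brownian steps match the analytic RMS displacement", {
  cfg <- simulation_config("slow", n_foci = 250, n_frames = 500,
                           D_foci = 5e-4, seed = 2)
  foci <- simulate_foci(cfg)
  steps <- do.call(rbind, lapply(split(foci, foci$focus_id), function(f) {
    f <- f[order(f$frame), ]
    cbind(diff(f$x_um), diff(f$y_um))
  }))
  expect_gt(nrow(steps), 1e5)
  rms <- sqrt(mean(steps[, 1]^2 + steps[, 2]^2))
  expect_equal(rms, sqrt(4 * 5e-4 * 0.2), tolerance = 0.03)
})

test_that("simulate_tracks handles empty and degenerate-rate inputs", {
  cfg <- simulation_config("fast", n_molecules = 0, seed = 1)
  out <- simulate_tracks(cfg)
  expect_equal(nrow(out$truth), 0)
  expect_equal(nrow(out$tracks), 0)

  cfg <- simulation_config("fast", n_molecules = 2, k_on = 0, k_off_sim = 0,
                           seed = 1)
  expect_error(simulate_tracks(cfg), class = "telospt_parameter_error")
})

test_that("an absorbing bound state with no losses spans the whole movie", {
  cfg <- simulation_config("fast", n_molecules = 20, n_frames = 200,
                           k_on = 1, k_off_sim = 0, init_state = "bound",
                           k_bleach = 0, p_miss = 0, dZ = Inf, p_telo = 0,
                           n_foci = 0, seed = 3)
  tr <- simulate_tracks(cfg)$tracks
  lens <- tapply(tr$frame, tr$track_id, length)
  expect_equal(n_tracks(tr), 20)
  expect_true(all(lens == 200))
})

test_that("free-state frame-to-frame jumps match the analytic MSD", {
  cfg <- simulation_config("fast", n_molecules = 80, n_frames = 1340,
                           D_free = 1.5, k_on = 0, k_off_sim = 1,
                           init_state = "free", dZ = Inf, sigma_loc = 0,
                           k_bleach = 0, p_telo = 0, n_foci = 0, seed = 4)
  tr <- simulate_tracks(cfg)$tracks
  tr <- tr[order(tr$track_id, tr$frame), ]
  ok <- diff(tr$frame) == 1 & diff(tr$track_id) == 0
  expect_gt(sum(ok), 1e5)
  msd <- mean(diff(tr$x_um)[ok]^2 + diff(tr$y_um)[ok]^2)
  expect_equal(msd, 4 * 1.5 * 0.0075, tolerance = 0.03)
})

test_that("photobleaching is absorbing and ends the ground-truth record", {
  cfg <- simulation_config("fast", n_molecules = 150, n_frames = 300,
                           seed = 5)
  truth <- simulate_tracks(cfg, simulate_foci(cfg))$truth
  for (df in split(truth, truth$molecule)) {
    df <- df[order(df$frame), ]
    expect_true(all(diff(df$bleached) >= 0))       # never un-bleaches
    expect_true(all(!df$detected[df$bleached]))
    if (any(df$bleached))                          # record stops at bleach
      expect_equal(sum(df$bleached), 1L)
  }
})

test_that("long-run bound-state occupancy matches k_on/(k_on + k_off)", {
  cfg <- simulation_config("fast", n_molecules = 1000, n_frames = 1000,
                           k_on = 2, k_off_sim = 4, k_bleach = 0,
                           p_telo = 0, n_foci = 0, seed = 6)
  truth <- simulate_tracks(cfg)$truth
  expect_gte(nrow(truth), 1e6)
  fb <- mean(grepl("bound", truth$state))
  expect_equal(fb, 2 / 6, tolerance = 0.02)
})

test_that("emitted localizations stay inside the nuclear projection", {
  cfg <- simulation_config("fast", n_molecules = 200, n_frames = 300,
                           seed = 7)
  tr <- simulate_tracks(cfg, simulate_foci(cfg))$tracks
  r <- sqrt(tr$x_um^2 + tr$y_um^2)
  expect_true(all(r <= cfg$nucleus_radius + 5 * cfg$sigma_loc))
})

test_that("with p_telo = 1 every bound localization sits at a focus", {
  cfg <- simulation_config("fast", n_molecules = 150, n_frames = 400,
                           p_telo = 1, n_foci = 40, D_foci = 0, D_bound = 0,
                           sigma_loc = 0.01, seed = 8)
  foci <- simulate_foci(cfg)
  fp <- foci_positions(foci)
  tr <- simulate_tracks(cfg, foci)$tracks
  bnd <- tr[tr$state == "bound_telomeric", ]
  expect_gt(nrow(bnd), 50)
  d2 <- outer(bnd$x_um, fp[, 1], `-`)^2 + outer(bnd$y_um, fp[, 2], `-`)^2
  dmin <- sqrt(apply(d2, 1, min))
  expect_true(all(dmin <= cfg$telo_jitter * 4 + 3 * cfg$sigma_loc))
})

test_that("dwell-time simulation matches the exponential mean and limits", {
  expect_equal(nrow(simulate_dwell_times(0, 2.3)), 0)
  expect_error(simulate_dwell_times(10, -1), class = "telospt_parameter_error")

  dw <- simulate_dwell_times(1e5, 2.3, k_bleach = 0, frame_interval = 0.001,
                             max_duration = Inf, seed = 9)
  expect_equal(mean(dw$duration), 2.3 / log(2), tolerance = 0.03)
  expect_true(all(abs(dw$duration / 0.001 - round(dw$duration / 0.001)) < 1e-9))

  # bleach-dominated limit: observed durations decay at the bleaching rate
  dwb <- simulate_dwell_times(1e5, 1e9, k_bleach = 0.5, frame_interval = 0.001,
                              max_duration = Inf, seed = 10)
  expect_equal(mean(dwb$duration), 1 / 0.5, tolerance = 0.03)
  expect_true(all(dwb$censored))
})
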
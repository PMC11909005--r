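test_that("histogram compilation follows the lag, cap and binning rules", {
  fc <- fit_config()
  # five consecutive frames: exactly 4 lag-1 jumps (the per-track cap)
  tr5 <- track_table(data.frame(track_id = 1, frame = 0:4,
                                x_um = 0.1 * (0:4), y_um = 0),
                     frame_interval = 0.0075)
  h <- compile_histograms(tr5, fc)
  expect_equal(h$n_jumps[1], 4L)
  expect_equal(h$n_jumps[4], 1L)
  # a long track is still capped at 4 per lag
  tr12 <- track_table(data.frame(track_id = 1, frame = 0:11,
                                 x_um = 0.05 * (0:11), y_um = 0),
                      frame_interval = 0.0075)
  expect_equal(compile_histograms(tr12, fc)$n_jumps[1], 4L)
  # displacement 0.034 um lands in the [0.03, 0.04) bin
  tr2 <- track_table(data.frame(track_id = 1, frame = 0:1,
                                x_um = c(0, 0.034), y_um = 0),
                     frame_interval = 0.0075)
  h2 <- compile_histograms(tr2, fc)
  bin <- findInterval(0.034, h2$bin_edges)
  expect_equal(h2$counts[bin, 1], 1L)
  expect_equal(sum(h2$counts[, 1]), 1L)
  # a bridged gap contributes at its true frame separation
  trg <- track_table(data.frame(track_id = 1, frame = c(0, 2),
                                x_um = c(0, 0.05), y_um = 0),
                     frame_interval = 0.0075)
  hg <- compile_histograms(trg, fc)
  expect_equal(hg$n_jumps[1], 0L)
  expect_equal(hg$n_jumps[2], 1L)
  # empty input
  he <- compile_histograms(track_table(
    data.frame(track_id = integer(), frame = integer(), x_um = numeric(),
               y_um = numeric()), frame_interval = 0.0075), fc)
  expect_true(all(he$n_jumps == 0))
})

test_that("defocalization fraction has the right limits and monotonicity", {
  expect_equal(defocalization_fraction(0, 0.01, 0.7, "series"), 1)
  expect_equal(defocalization_fraction(0, 0.01, 0.7, "monte_carlo"), 1)
  expect_equal(defocalization_fraction(3, 0.0075, 0.7, "none"), 1)
  expect_gte(defocalization_fraction(1e-4, 0.0075, 100, "series"), 0.999)
  expect_error(defocalization_fraction(1, 0.01, -1, "series"),
               class = "telospt_parameter_error")
  dd <- vapply(c(0.5, 1, 2, 4, 8), defocalization_fraction,
               numeric(1), t = 0.0075, dZ = 0.7, mode = "series")
  expect_true(all(diff(dd) < 0))
  tt <- vapply(c(1, 2, 4, 8) * 0.0075, function(t)
    defocalization_fraction(2, t, 0.7, "series"), numeric(1))
  expect_true(all(diff(tt) < 0))
  zz <- vapply(c(0.4, 0.7, 1.2, 2), function(z)
    defocalization_fraction(2, 0.0075, z, "series"), numeric(1))
  expect_true(all(diff(zz) > 0))
  expect_true(all(c(dd, tt, zz) > 0 & c(dd, tt, zz) <= 1))
})

test_that("series solution agrees with an absorbing Monte-Carlo oracle", {
  for (D in c(0.5, 3, 8)) {
    s <- defocalization_fraction(D, 0.0075, 0.7, "series")
    m <- absorbing_mc_oracle(D, 0.0075, 0.7, n = 2e5, substeps = 50)
    expect_lt(abs(s - m) / m, 0.005)
  }
  # re-entry (endpoint-only criterion) can only increase survival
  mc <- defocalization_fraction(3, 0.0075, 0.7, "monte_carlo",
                                n_walkers = 2e5)
  expect_gt(mc, defocalization_fraction(3, 0.0075, 0.7, "series") - 0.002)
})

test_that("model_pdf reduces to a Rayleigh density and normalizes to one", {
  fc <- fit_config(sigma_loc = 0, z_corr_mode = "series")
  p <- list(D_free = 2, D_bound = 0.01, F_bound = 1)
  r <- seq(0, 0.5, by = 0.001)
  s2 <- 0.01 * fc$time_gap
  expect_equal(model_pdf(r, 1, p, fc),
               r / (2 * s2) * exp(-r^2 / (4 * s2)), tolerance = 1e-12)
  expect_equal(model_pdf(0, 3, list(D_free = 2, D_bound = 0.01,
                                    F_bound = 0.4), fc), 0)
  for (pars in list(list(D_free = 1, D_bound = 0.001, F_bound = 0.3),
                    list(D_free = 6, D_bound = 0.3, F_bound = 0.85),
                    list(D_free = 0.6, D_bound = 0.0002, F_bound = 0.05))) {
    for (lag in c(1, 4, 8)) {
      I <- integrate(function(x) model_pdf(x, lag, pars, fit_config(
        z_corr_mode = "series")), 0, Inf, rel.tol = 1e-9)
      expect_equal(I$value, 1, tolerance = 1e-6)
    }
  }
  expect_error(model_pdf(r, 1, list(D_free = 50, D_bound = 0.01,
                                    F_bound = 0.5), fc),
               class = "telospt_parameter_error")
})

test_that("the mixture second moment matches the component variances", {
  fc <- fit_config(sigma_loc = 0.03, z_corr_mode = "series")
  pars <- list(D_free = 2.5, D_bound = 0.01, F_bound = 0.35)
  lag <- 2
  dtl <- lag * fc$time_gap
  s2b <- pars$D_bound * dtl + fc$sigma_loc^2
  s2f <- pars$D_free * dtl + fc$sigma_loc^2
  Z <- defocalization_fraction(pars$D_free, dtl, fc$dZ, "series")
  wb <- pars$F_bound / (pars$F_bound + Z * (1 - pars$F_bound))
  m2 <- integrate(function(x) x^2 * model_pdf(x, lag, pars, fc), 0, Inf,
                  rel.tol = 1e-10)$value
  expect_equal(m2, wb * 4 * s2b + (1 - wb) * 4 * s2f, tolerance = 1e-4)
})

test_that("fitting errors out without enough jumps", {
  fc <- fit_config()
  he <- compile_histograms(track_table(
    data.frame(track_id = integer(), frame = integer(), x_um = numeric(),
               y_um = numeric()), frame_interval = 0.0075), fc)
  expect_error(fit_two_state(he, fc), "1000",
               class = "telospt_insufficient_data")
})

test_that("free-only tracks fit to a near-zero bound fraction", {
  cfg <- simulation_config("fast", n_molecules = 6500, D_free = 2,
                           k_on = 0, k_off_sim = 1, init_state = "free",
                           sigma_loc = 0.035, p_telo = 0, n_foci = 0,
                           seed = 15)
  tr <- simulate_tracks(cfg)$tracks
  h <- compile_histograms(tr, fit_config())
  expect_gte(sum(h$n_jumps), 2e4)
  f <- fit_two_state(h, fit_config())
  expect_lte(f$F_bound, 0.05)
})

test_that("two-state parameters are recovered from a synthetic mixture", {
  cfg <- fast_sim(0.30, 1.5, n_molecules = 6000, seed = 16)
  tr <- simulate_tracks(cfg)$tracks
  h <- compile_histograms(tr, fit_config())
  expect_gte(sum(h$n_jumps), 2e4)
  f <- fit_two_state(h, fit_config())
  expect_true(f$converged)
  expect_equal(f$F_bound, 0.30, tolerance = 0.03 / 0.30)
  expect_equal(f$D_free, 1.5, tolerance = 0.10)
})

test_that("fits are invariant to track relabelling and frame shifts", {
  cfg <- fast_sim(0.3, 1.5, n_molecules = 400, seed = 17)
  tr <- simulate_tracks(cfg)$tracks
  h0 <- compile_histograms(tr, fit_config())
  tr2 <- tr
  ids <- unique(tr2$track_id)
  map <- setNames(rev(seq_along(ids)) * 7L, ids)
  tr2$track_id <- map[as.character(tr2$track_id)]
  tr2$frame <- tr2$frame + 1000L
  h2 <- compile_histograms(
    track_table(as.data.frame(tr2), frame_interval = 0.0075), fit_config())
  expect_equal(h2$counts, h0$counts)
  expect_equal(h2$n_jumps, h0$n_jumps)
})

test_that("recovery is calibrated across bound fractions and mobilities", {
  fc <- fit_config()
  dev_D <- c(); dev_F <- c()
  for (fb in c(0.1, 0.3, 0.5)) {
    for (Df in c(1, 2, 4)) {
      cfg <- fast_sim(fb, Df, n_molecules = 8000,
                      seed = 1000 + round(100 * fb) + Df)
      h <- compile_histograms(simulate_tracks(cfg)$tracks, fc)
      f <- fit_two_state(h, fc)
      dev_D <- c(dev_D, abs(f$D_free - Df) / Df)
      dev_F <- c(dev_F, abs(f$F_bound - fb))
    }
  }
  expect_lte(median(dev_D), 0.10)
  expect_lte(median(dev_F), 0.03)
})
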
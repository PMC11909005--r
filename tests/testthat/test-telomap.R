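test_that("pixel threshold conversion is exact", {
  expect_equal(pixel_threshold(3, 0.16), 0.48)
  expect_equal(pixel_threshold(0, 0.16), 0)
  expect_equal(pixel_threshold(5, 0.2), 1.0)
  expect_error(pixel_threshold(-1, 0.16), class = "telospt_parameter_error")
})

test_that("foci detection finds rendered centroids and merges close pairs", {
  expect_equal(nrow(detect_foci(matrix(100, 60, 60), min_intensity = 150)), 0)

  px <- 0.16
  img <- matrix(100, 80, 80)
  truth_px <- rbind(c(20.3, 25.7), c(55.8, 30.2), c(35.5, 60.4))
  for (k in 1:3)
    img <- teloSPT:::add_gaussians(img, (truth_px[k, 1]) * px,
                                   (truth_px[k, 2]) * px, 3000, 0.0947, px,
                                   half = 0)
  fd <- detect_foci(img, min_intensity = 120, merge_radius = 0.3,
                    pixel_size = px, origin_um = 0)
  expect_equal(nrow(fd), 3)
  for (k in 1:3) {
    d <- sqrt((fd$x_um / px - truth_px[k, 1])^2 +
                (fd$y_um / px - truth_px[k, 2])^2)
    expect_lt(min(d), 0.1)
  }

  # two foci closer than merge_radius collapse to the weighted midpoint
  img2 <- matrix(100, 80, 80)
  img2 <- teloSPT:::add_gaussians(img2, 40 * px, 40 * px, 3000, 0.0947, px, 0)
  img2 <- teloSPT:::add_gaussians(img2, 41 * px, 40 * px, 3000, 0.0947, px, 0)
  fd2 <- detect_foci(img2, min_intensity = 120, merge_radius = 0.3,
                     pixel_size = px, origin_um = 0)
  expect_equal(nrow(fd2), 1)
  expect_equal(fd2$x_um / px, 40.5, tolerance = 0.02)
})

test_that("track classification applies the boundary-inclusive distance rule", {
  foci <- teloSPT:::new_foci_set(
    tibble::tibble(focus_id = 1L, frame = NA_integer_, x_um = 1, y_um = 1),
    static = TRUE)
  mk <- function(x0) track_table(
    data.frame(track_id = 1, frame = 0:3, x_um = x0, y_um = 1),
    frame_interval = 0.0075)
  cl0 <- classify_tracks(mk(1), foci, 0.48)
  expect_equal(cl0$label, "telomeric")
  expect_equal(cl0$distance_um, 0, tolerance = 1e-12)
  expect_equal(classify_tracks(mk(1.49), foci, 0.48)$label, "non_telomeric")
  expect_equal(classify_tracks(mk(1.48), foci, 0.48)$label, "telomeric")

  empty_foci <- teloSPT:::new_foci_set(
    tibble::tibble(focus_id = integer(), frame = integer(),
                   x_um = numeric(), y_um = numeric()), static = TRUE)
  expect_equal(classify_tracks(mk(1), empty_foci, 0.48)$label,
               "non_telomeric")
})

test_that("classification partitions tracks and grows with the threshold", {
  cfg <- simulation_config("fast", n_molecules = 200, n_frames = 200,
                           seed = 18)
  foci <- simulate_foci(cfg)
  tr <- simulate_tracks(cfg, foci)$tracks
  sizes <- c()
  prev <- NULL
  for (th in c(0.1, 0.3, 0.48, 0.8)) {
    cl <- classify_tracks(tr, foci, th)
    expect_equal(nrow(cl), n_tracks(tr))
    expect_true(all(cl$label %in% c("telomeric", "non_telomeric")))
    telo <- sort(cl$track_id[cl$label == "telomeric"])
    if (!is.null(prev)) expect_true(all(prev %in% telo))
    prev <- telo
    sizes <- c(sizes, length(telo))
  }
  expect_true(all(diff(sizes) >= 0))
})

test_that("telomere-bound share combines group fits as bound-mass ratios", {
  fit <- function(F) list(F_bound = F, converged = TRUE)
  expect_equal(telomere_bound_share(fit(0.4), 50, fit(0.4), 950), 0.05)
  expect_equal(telomere_bound_share(fit(0.6), 100, fit(0.3), 1900),
               60 / 630)
  expect_equal(telomere_bound_share(fit(0), 100, fit(0.3), 1900), 0)
  expect_equal(telomere_bound_share(fit(0), 0, fit(0), 0), 0)
  expect_error(telomere_bound_share(fit(0.5), -1, fit(0.5), 10),
               class = "telospt_parameter_error")
})

test_that("rotation and chance-share helpers behave geometrically", {
  cfg <- simulation_config("fast", n_foci = 160, D_foci = 0, seed = 19)
  foci <- simulate_foci(cfg)
  rot <- rotate_foci(foci, pi / 3)
  expect_equal(sqrt(rot$x_um^2 + rot$y_um^2),
               sqrt(foci$x_um^2 + foci$y_um^2), tolerance = 1e-12)
  cc <- chance_colocalization(foci, cfg$nucleus_radius, 0.48)
  # expected coverage of 160 disks of radius 0.48 um in this nucleus
  lambda <- 160 / (pi * cfg$nucleus_radius^2)
  expect_equal(cc, 1 - exp(-lambda * pi * 0.48^2), tolerance = 0.05)
  expect_equal(corrected_share(cc, cc), 0)
  expect_equal(corrected_share(1, 0.5), 1)
  expect_equal(corrected_share(0.5, 0), 0.5)
})
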
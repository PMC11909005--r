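test_that("detection returns nothing on blank or constant frames", {
  expect_equal(nrow(detect_spots(matrix(0, 32, 32))), 0)
  expect_equal(nrow(detect_spots(matrix(100, 32, 32))), 0)
})

test_that("a rendered Gaussian spot is localized to sub-pixel accuracy", {
  img <- spot_image(x_px = 12.3, y_px = 45.7, amplitude = 80, noise_sd = 8)
  det <- detect_spots(img, detection_config(), pixel_size = 0.16)
  expect_gte(nrow(det), 1)
  best <- which.min((det$x_px - 12.3)^2 + (det$y_px - 45.7)^2)
  expect_lt(abs(det$x_px[best] - 12.3), 0.1)
  expect_lt(abs(det$y_px[best] - 45.7), 0.1)
  expect_equal(det$x_um[best], det$x_px[best] * 0.16)
})

test_that("false-positive rate on pure noise respects the stringency", {
  set.seed(11)
  n_det <- 0; n_px <- 0
  for (f in 1:10) {
    img <- matrix(rnorm(1e6, 100, 5), 1000, 1000)
    n_det <- n_det + nrow(detect_spots(img, detection_config(log10_false_positive = -5)))
    n_px <- n_px + length(img)
  }
  expect_gte(n_px, 1e7)
  # the designed per-pixel rate is 1e-5; allow the 3-sigma binomial
  # sampling margin of the Monte-Carlo count
  expect_lte(n_det, 1e-5 * n_px + 3 * sqrt(1e-5 * n_px))
})

test_that("linking joins a single molecule and splits on gating violations", {
  cfg <- link_config(D_max = 5, gaps_allowed = 2, frame_interval = 0.0075)
  rmax <- sqrt(4 * 5 * 0.0075)
  # small jumps: one track
  loc <- data.frame(frame = 0:9, x_um = cumsum(rep(0.05, 10)), y_um = 0)
  tt <- link_tracks(loc, cfg)
  expect_equal(n_tracks(tt), 1)
  expect_equal(nrow(tt), 10)
  # one jump beyond r_max(0): track terminated, new track started
  loc2 <- loc
  loc2$x_um[6:10] <- loc2$x_um[6:10] + 2 * rmax
  expect_equal(n_tracks(link_tracks(loc2, cfg)), 2)
  # empty input
  expect_equal(nrow(link_tracks(data.frame(frame = integer(),
                                           x_um = numeric(),
                                           y_um = numeric()), cfg)), 0)
})

test_that("two missing frames are bridged, three start a new track", {
  cfg <- link_config(D_max = 5, gaps_allowed = 2, frame_interval = 0.0075)
  base <- data.frame(frame = 0:11, x_um = 0.01 * (0:11), y_um = 0)
  gap2 <- base[!(base$frame %in% 5:6), ]
  gap3 <- base[!(base$frame %in% 5:7), ]
  expect_equal(n_tracks(link_tracks(gap2, cfg)), 1)
  expect_equal(n_tracks(link_tracks(gap3, cfg)), 2)
})

test_that("linked localizations are a partition of the input", {
  set.seed(12)
  loc <- data.frame(frame = rep(0:39, each = 6),
                    x_um = runif(240, 0, 10), y_um = runif(240, 0, 10))
  tt <- link_tracks(loc, link_config(D_max = 5, gaps_allowed = 2,
                                     frame_interval = 0.0075))
  expect_equal(nrow(tt), nrow(loc))          # nothing dropped or duplicated
  expect_false(anyDuplicated(tt[, c("track_id", "frame")]) > 0)
  key_in <- sort(paste(loc$frame, round(loc$x_um, 9)))
  key_out <- sort(paste(tt$frame, round(tt$x_um, 9)))
  expect_equal(key_out, key_in)
})

test_that("track count is non-increasing in the allowed gap length", {
  set.seed(13)
  loc <- make_sparse_tracks(n_tracks = 4, n_frames = 50,
                            drop = list(id = 2, frames = c(10, 11, 20)))
  counts <- vapply(0:3, function(g) {
    n_tracks(link_tracks(loc, link_config(D_max = 5, gaps_allowed = g,
                                          frame_interval = 0.0075)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("linking reproduces ground truth on sparse noise-free fields", {
  loc <- make_sparse_tracks(n_tracks = 4, n_frames = 60, step_sd = 0.05,
                            spacing = 6)
  tt <- link_tracks(loc, link_config(D_max = 5, gaps_allowed = 2,
                                     frame_interval = 0.0075))
  expect_equal(n_tracks(tt), 4)
  m <- merge(as.data.frame(tt), loc, by = c("frame", "x_um", "y_um"))
  tab <- table(m$track_id, m$truth_id)
  expect_true(all(rowSums(tab > 0) == 1))    # each track maps to one truth id
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("low-mobility gating keeps bound tracks and shreds free ones", {
  set.seed(14)
  # bound molecule, D = 0.005 um^2/s at 200 ms
  bound <- data.frame(frame = 0:49,
                      x_um = cumsum(rnorm(50, sd = sqrt(2 * 0.005 * 0.2))),
                      y_um = cumsum(rnorm(50, sd = sqrt(2 * 0.005 * 0.2))))
  tb <- track_low_mobility(bound)
  expect_equal(n_tracks(tb), 1)
  expect_equal(nrow(tb), 50)
  # free molecule, D = 1.5 um^2/s: jumps exceed the gate
  free <- data.frame(frame = 0:49,
                     x_um = cumsum(rnorm(50, sd = sqrt(2 * 1.5 * 0.2))),
                     y_um = cumsum(rnorm(50, sd = sqrt(2 * 1.5 * 0.2))))
  tf <- track_low_mobility(free)
  lens <- tapply(tf$frame, tf$track_id, length)
  expect_lte(median(lens), 2)
  expect_equal(nrow(track_low_mobility(free[0, ])), 0)
})
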
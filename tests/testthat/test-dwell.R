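test_that("survival curves follow the counting definition", {
  sc <- survival_curve(c(1, 2, 3))
  expect_equal(sc$time, c(1, 2, 3))
  expect_equal(sc$survival, c(1, 2 / 3, 1 / 3))
  sc2 <- survival_curve(rep(2.5, 10))
  expect_equal(nrow(sc2), 1)
  expect_equal(sc2$survival, 1)
  expect_error(survival_curve(numeric(0)), class = "telospt_parameter_error")
  expect_error(survival_curve(c(1, 0)), class = "telospt_parameter_error")
})

test_that("survival curves are non-increasing on arbitrary inputs", {
  set.seed(20)
  for (i in 1:20) {
    d <- switch(1 + i %% 3,
                rexp(200, 0.5), runif(150, 0.1, 5),
                sample(seq(0.2, 4, by = 0.2), 100, replace = TRUE))
    sc <- survival_curve(d)
    expect_true(all(diff(sc$survival) < 0))
    expect_true(all(sc$survival >= 0 & sc$survival <= 1))
    expect_equal(sc$survival[1], 1)
  }
})

test_that("an exponential survival fit recovers the half-life", {
  set.seed(21)
  d <- floor(rexp(1e4, log(2) / 2.3) / 0.2) * 0.2
  sc <- survival_curve(d[d > 0])
  f <- fit_residence(sc, bleach = NULL, model = "one_exp", n_boot = 50)
  expect_equal(f$t_half, 2.3, tolerance = 0.05)
})

test_that("bleach fitting is exact on exact data and robust to noise", {
  t <- 0:99 * 0.2
  y <- 500 * exp(-0.2 * t)
  b <- fit_bleach(y, 0.2)
  expect_equal(b$k_bleach, 0.2, tolerance = 1e-6)
  expect_equal(fit_bleach(rep(123, 50), 0.2)$k_bleach, 0)
  set.seed(22)
  yn <- y * (1 + rnorm(length(y), sd = 0.05))
  expect_equal(fit_bleach(yn, 0.2)$k_bleach, 0.2, tolerance = 0.05)
  expect_error(fit_bleach(c(y[1:5], NA, y[7:20]), 0.2),
               class = "telospt_parameter_error")
  expect_error(fit_bleach(y[1:5], 0.2), class = "telospt_parameter_error")
})

test_that("bleaching correction subtracts rates and flags degeneracy", {
  set.seed(23)
  # observed decay 0.5/s, of which 0.2/s is bleaching
  d <- floor(rexp(5000, 0.5) / 0.05) * 0.05
  sc <- survival_curve(d[d > 0])
  bl <- structure(list(k_bleach = 0.2, amplitude = 1, baseline = 0,
                       residual = 0), class = "bleach_model")
  f <- fit_residence(sc, bl, model = "one_exp", n_boot = 100)
  expect_equal(f$k_off, f$k_obs - 0.2, tolerance = 1e-12)
  expect_equal(f$t_half, log(2) / 0.3, tolerance = 0.08)
  expect_true(f$ci[1] < f$t_half & f$t_half < f$ci[2])
  # no-correction limit
  f0 <- fit_residence(sc, NULL, model = "one_exp", n_boot = 20)
  expect_equal(f0$t_half, log(2) / f0$k_obs, tolerance = 1e-12)
  # bleaching at least as fast as the observed decay is unresolvable
  bl2 <- structure(list(k_bleach = f0$k_obs, amplitude = 1, baseline = 0,
                        residual = 0), class = "bleach_model")
  expect_error(fit_residence(sc, bl2, model = "one_exp"),
               class = "telospt_degenerate_correction")
  expect_error(fit_residence(survival_curve(d[d > 0][1:20]), NULL),
               class = "telospt_insufficient_data")
})

test_that("group comparison reports the half-life ratio with a CI", {
  set.seed(24)
  mk <- function(thalf, n, seed) {
    d <- floor(rexp(n, log(2) / thalf) / 0.2) * 0.2
    fit_residence(survival_curve(d[d > 0]), NULL, model = "one_exp",
                  n_boot = 200, seed = seed)
  }
  fa <- mk(2.3, 5000, 1)
  expect_equal(compare_groups(fa, fa)$ratio, 1)
  fb <- mk(0.7, 5000, 2)
  cmp <- compare_groups(fa, fb)
  expect_equal(cmp$ratio, 2.3 / 0.7, tolerance = 0.1)
  expect_gt(cmp$ci[1], 1)    # clearly separated groups exclude ratio 1
})

test_that("track durations count spanned frames times the interval", {
  tr <- track_table(data.frame(track_id = c(1, 1, 1, 2, 3, 3),
                               frame = c(0, 1, 4, 2, 5, 6),
                               x_um = 0, y_um = 0),
                    frame_interval = 0.2)
  d <- track_durations(tr)
  expect_equal(sort(d), c(0.2, 0.8))  # single-frame track 2 has no duration
})
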
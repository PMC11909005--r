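#' Spot-detection configuration
#'
#' @param log10_false_positive Detection stringency: the per-pixel
#'   false-positive probability on the Gaussian tail of the background
#'   noise is `10^log10_false_positive` (default -5).
#' @param window_radius Half-width (pixels) of the fitting window around a
#'   candidate maximum.
#' @param min_intensity Minimum fitted amplitude (counts) to keep a spot.
#' @param psf_sigma_px Gaussian PSF sd in pixels used by the localization
#'   fit (default from the default optics: 0.21 * 0.672/1.49 / 0.16 px).
#' @param deflation_loops Carried for configuration compatibility; no
#'   deflation is performed.
#' @return A list of class `detection_config`.
#' @export
detection_config <- function(log10_false_positive = -5,
                             window_radius = 3,
                             min_intensity = 0,
                             psf_sigma_px = 0.21 * 0.672 / 1.49 / 0.16,
                             deflation_loops = 0) {
  if (window_radius < 1) abort_param("`window_radius` must be >= 1")
  structure(list(log10_false_positive = log10_false_positive,
                 window_radius = as.integer(window_radius),
                 min_intensity = min_intensity,
                 psf_sigma_px = psf_sigma_px,
                 deflation_loops = deflation_loops),
            class = "detection_config")
}

#' Track-linking configuration
#'
#' @param D_max Upper bound on the diffusivity of linkable motion
#'   (um^2/s); a link spanning `g` skipped frames is allowed only if the
#'   displacement is at most `sqrt(4 * D_max * (g+1) * frame_interval)`.
#' @param gaps_allowed Maximum number of consecutive missed frames bridged
#'   within one track.
#' @param frame_interval Frame spacing (s).
#' @param pixel_size Pixel size (um), metadata only.
#' @return A list of class `link_config`.
#' @export
link_config <- function(D_max = 5, gaps_allowed = 2, frame_interval = 0.0075,
                        pixel_size = 0.16) {
  check_pos(D_max, "D_max")
  check_count(gaps_allowed, "gaps_allowed")
  check_pos(frame_interval, "frame_interval")
  structure(list(D_max = D_max, gaps_allowed = as.integer(gaps_allowed),
                 frame_interval = frame_interval, pixel_size = pixel_size),
            class = "link_config")
}

#' Detect fluorescent spots in a single movie frame
#'
#' Background level and noise are estimated per frame by median/MAD;
#' candidate local maxima exceeding the Gaussian tail quantile at
#' `10^log10_false_positive` are refined to sub-pixel centroids by
#' least-squares fitting of a 2D Gaussian (fixed PSF width) within the
#' window.
#'
#' @param frame_image Numeric matrix (row = y, column = x).
#' @param config A [detection_config()].
#' @param pixel_size Pixel size in micrometres.
#' @param origin_um Micrometre coordinate of the image edge (default 0; use
#'   `movie$origin_um` for rendered movies).
#' @return Tibble with `x_px`, `y_px` (pixel units, centre of pixel (1,1)
#'   at 0.5 px), `x_um`, `y_um`, `intensity` (fitted amplitude above local
#'   background) and `fit_quality` (R^2 of the Gaussian fit).
#' @export
detect_spots <- function(frame_image, config = detection_config(),
                         pixel_size = 0.16, origin_um = 0) {
  stopifnot(is.matrix(frame_image))
  empty <- tibble::tibble(x_px = numeric(), y_px = numeric(),
                          x_um = numeric(), y_um = numeric(),
                          intensity = numeric(), fit_quality = numeric())
  bg <- stats::median(frame_image)
  noise <- stats::mad(frame_image)
  if (noise == 0) {
    # flat background (e.g. noise-free rendering): any positive excursion
    # is signal; use a tiny floor so rendered test images still work
    noise <- max(1e-12, max(abs(frame_image - bg)) * 1e-6)
    if (all(frame_image == bg)) return(empty)
  }
  thr <- bg + qnorm(1 - 10^config$log10_false_positive) * noise
  cand <- local_maxima(frame_image, thr)
  if (nrow(cand) == 0) return(empty)
  w <- config$window_radius
  out <- vector("list", nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    out[[k]] <- fit_gaussian_spot(frame_image, i, j, w, config$psf_sigma_px, bg)
  }
  out <- do.call(rbind, out)
  out <- out[!is.na(out$x_px) & out$intensity >= config$min_intensity, ,
             drop = FALSE]
  out$x_um <- origin_um + out$x_px * pixel_size
  out$y_um <- origin_um + out$y_px * pixel_size
  tibble::as_tibble(out[, c("x_px", "y_px", "x_um", "y_um", "intensity",
                            "fit_quality")])
}

# 8-neighbour local maxima above a threshold; returns (row, col) matrix
local_maxima <- function(img, thr) {
  nr <- nrow(img); nc <- ncol(img)
  if (nr < 3 || nc < 3) return(matrix(integer(), 0, 2))
  core <- img[2:(nr - 1), 2:(nc - 1)]
  ok <- core > thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ok <- ok & core >= img[2:(nr - 1) + di, 2:(nc - 1) + dj]
  }
  idx <- which(ok, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(integer(), 0, 2))
  idx + 1L  # back to full-image indices
}

# least-squares Gaussian fit with fixed width; falls back to the
# intensity-weighted centroid if the fit fails
fit_gaussian_spot <- function(img, i, j, w, sigma_px, bg0) {
  nr <- nrow(img); nc <- ncol(img)
  i0 <- max(1L, i - w); i1 <- min(nr, i + w)
  j0 <- max(1L, j - w); j1 <- min(nc, j + w)
  sub <- img[i0:i1, j0:j1]
  xs <- (j0:j1) - 0.5  # pixel-centre coordinates
  ys <- (i0:i1) - 0.5
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  v <- as.vector(sub)
  wgt <- pmax(v - bg0, 0)
  cx0 <- if (sum(wgt) > 0) sum(gx * wgt) / sum(wgt) else j - 0.5
  cy0 <- if (sum(wgt) > 0) sum(gy * wgt) / sum(wgt) else i - 0.5
  a0 <- max(v) - bg0
  fit <- tryCatch({
    res_fun <- function(p) {
      mu <- p[4] + p[3] * exp(-((gx - p[1])^2 + (gy - p[2])^2) / (2 * sigma_px^2))
      v - mu
    }
    minpack.lm::nls.lm(par = c(cx0, cy0, a0, bg0), fn = res_fun,
                       control = minpack.lm::nls.lm.control(maxiter = 100))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(data.frame(x_px = cx0, y_px = cy0, intensity = a0,
                      fit_quality = NA_real_))
  }
  p <- fit$par
  rss <- sum(fit$fvec^2); tss <- sum((v - mean(v))^2)
  # reject fits that ran away from the window
  if (p[1] < xs[1] - 1 || p[1] > xs[length(xs)] + 1 ||
      p[2] < ys[1] - 1 || p[2] > ys[length(ys)] + 1) {
    return(data.frame(x_px = NA_real_, y_px = NA_real_,
                      intensity = NA_real_, fit_quality = NA_real_))
  }
  data.frame(x_px = p[1], y_px = p[2], intensity = p[3],
             fit_quality = if (tss > 0) 1 - rss / tss else NA_real_)
}

#' Detect spots in every frame of a movie channel
#'
#' @param movie A `movie_stack`.
#' @param channel 1 or 2.
#' @param config A [detection_config()].
#' @return Tibble of localizations with a `frame` column (0-based).
#' @export
detect_movie <- function(movie, channel = 2, config = detection_config()) {
  arr <- movie[[paste0("channel", channel)]]
  nf <- dim(arr)[3]
  out <- vector("list", nf)
  for (f in seq_len(nf)) {
    d <- detect_spots(arr[, , f], config, pixel_size = movie$pixel_size,
                      origin_um = movie$origin_um)
    if (nrow(d)) d$frame <- f - 1L
    out[[f]] <- d
  }
  out <- do.call(rbind, out[vapply(out, nrow, 1L) > 0])
  if (is.null(out))
    return(tibble::tibble(frame = integer(), x_um = numeric(), y_um = numeric(),
                          x_px = numeric(), y_px = numeric(),
                          intensity = numeric(), fit_quality = numeric()))
  tibble::as_tibble(out)
}

#' Link localizations into trajectories with gap closing
#'
#' Frame-to-frame assignment by greedy selection on the gated cost matrix:
#' candidate links between an active track end and a new detection are
#' admitted when the displacement over `g` skipped frames is at most
#' `r_max(g) = sqrt(4 * D_max * (g+1) * frame_interval)`; candidates are
#' accepted in order of increasing cost (squared displacement divided by
#' `g+1`), with ties broken by the earlier track-end frame, then by lower
#' localization index, and conflicts resolved globally per frame.
#' Unlinked detections start new tracks.
#'
#' @param localizations Data frame with `frame`, `x_um`, `y_um` (optionally
#'   `intensity`), sorted by frame.
#' @param config A [link_config()].
#' @return A `track_table`.
#' @export
link_tracks <- function(localizations, config = link_config()) {
  stopifnot(inherits(config, "link_config"))
  loc <- as.data.frame(localizations)
  if (nrow(loc) == 0) {
    return(new_track_table(
      tibble::tibble(track_id = integer(), frame = integer(),
                     x_um = numeric(), y_um = numeric()),
      frame_interval = config$frame_interval,
      pixel_size = config$pixel_size, source = "linker"))
  }
  loc <- loc[order(loc$frame), , drop = FALSE]
  loc$.row <- seq_len(nrow(loc))
  frames <- sort(unique(loc$frame))
  gmax <- config$gaps_allowed
  dtv <- config$frame_interval

  # active track ends
  end_x <- numeric(0); end_y <- numeric(0); end_f <- integer(0)
  end_id <- integer(0)
  assign_id <- integer(nrow(loc))
  next_id <- 1L

  for (f in frames) {
    rows <- which(loc$frame == f)
    px <- loc$x_um[rows]; py <- loc$y_um[rows]
    live <- which(f - end_f >= 1L & f - end_f <= gmax + 1L)
    taken_det <- rep(FALSE, length(rows))
    if (length(live) && length(rows)) {
      g <- f - end_f[live] - 1L                 # skipped frames per track
      rmax <- sqrt(4 * config$D_max * (g + 1) * dtv)
      d2 <- outer(end_x[live], px, `-`)^2 + outer(end_y[live], py, `-`)^2
      cost <- d2 / (g + 1)
      ok <- d2 <= rmax^2
      if (any(ok)) {
        cand <- which(ok, arr.ind = TRUE)
        cc <- cost[ok]
        ord <- order(cc, end_f[live][cand[, 1]], rows[cand[, 2]])
        used_tr <- rep(FALSE, length(live))
        for (q in ord) {
          ti <- cand[q, 1]; di <- cand[q, 2]
          if (used_tr[ti] || taken_det[di]) next
          used_tr[ti] <- TRUE; taken_det[di] <- TRUE
          k <- live[ti]
          assign_id[rows[di]] <- end_id[k]
          end_x[k] <- px[di]; end_y[k] <- py[di]; end_f[k] <- f
        }
      }
    }
    # new tracks for unmatched detections
    for (di in which(!taken_det)) {
      assign_id[rows[di]] <- next_id
      end_x <- c(end_x, px[di]); end_y <- c(end_y, py[di])
      end_f <- c(end_f, f); end_id <- c(end_id, next_id)
      next_id <- next_id + 1L
    }
    # prune expired track ends
    keep <- f - end_f <= gmax
    end_x <- end_x[keep]; end_y <- end_y[keep]
    end_f <- end_f[keep]; end_id <- end_id[keep]
  }
  out <- tibble::tibble(track_id = assign_id, frame = loc$frame,
                        x_um = loc$x_um, y_um = loc$y_um)
  if (!is.null(loc$intensity)) out$intensity <- loc$intensity
  out <- out[order(out$track_id, out$frame), ]
  new_track_table(out, frame_interval = config$frame_interval,
                  pixel_size = config$pixel_size, source = "linker")
}

#' Link only low-mobility molecules
#'
#' [link_tracks()] with the low-mobility gate (`D_max = 0.5` um^2/s, two
#' gap frames) used for residence-time analysis of 200 ms-interval movies:
#' freely diffusing molecules jump farther than the gate between frames and
#' fragment into 1-2 frame stubs, so only chromatin-bound molecules form
#' extended tracks.
#'
#' @param localizations Data frame with `frame`, `x_um`, `y_um`.
#' @param frame_interval Frame spacing (s), default 0.2.
#' @param D_max Mobility gate (um^2/s), default 0.5.
#' @param gaps_allowed Gap frames bridged, default 2.
#' @param pixel_size Pixel size (um), metadata.
#' @return A `track_table`.
#' @export
track_low_mobility <- function(localizations, frame_interval = 0.2,
                               D_max = 0.5, gaps_allowed = 2,
                               pixel_size = 0.16) {
  link_tracks(localizations,
              link_config(D_max = D_max, gaps_allowed = gaps_allowed,
                          frame_interval = frame_interval,
                          pixel_size = pixel_size))
}
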
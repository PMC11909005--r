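#' Render a two-channel fluorescence movie from ground truth
#'
#' Channel 1 carries the telomere marker foci, channel 2 the detected
#' molecules. Each emitter is drawn as a 2D Gaussian of sd
#' `0.21 * lambda / NA` whose per-pixel mass is integrated exactly over the
#' pixel area (photon conserving), Poisson shot noise is applied to signal
#' plus background, and the linear camera model (`offset + gain * counts`)
#' is applied.
#'
#' @param truth Ground-truth table from [simulate_tracks()].
#' @param foci A `foci_set`.
#' @param config The [simulation_config()] used for the simulation.
#' @param fov_um Field of view (um, square). Default covers the nucleus
#'   plus a 1 um margin; a field smaller than the nucleus is an error.
#' @param noise Apply Poisson shot noise (default `TRUE`).
#' @param foci_photons Photons per focus per frame (default 5x the
#'   per-molecule photon yield; marker foci carry many fluorophores).
#' @return A list of class `movie_stack`: `channel1`, `channel2` (numeric
#'   arrays `ny x nx x n_frames` in camera counts), `pixel_size`,
#'   `frame_interval`, `fov_um`, `origin_um`.
#' @export
render_movie <- function(truth, foci, config, fov_um = NULL, noise = TRUE,
                         foci_photons = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  opt <- config$optics
  fov_um <- fov_um %||% (2 * (config$nucleus_radius + 1))
  if (fov_um < 2 * config$nucleus_radius)
    abort_param("field of view is smaller than the nucleus diameter")
  px <- config$pixel_size
  npix <- as.integer(ceiling(fov_um / px))
  half <- npix * px / 2
  nf <- config$n_frames
  sig <- psf_sigma(opt)
  foci_photons <- foci_photons %||% (5 * opt$photons_per_molecule_per_frame)

  ch1 <- array(0, dim = c(npix, npix, nf))
  ch2 <- array(0, dim = c(npix, npix, nf))

  static_foci <- isTRUE(attr(foci, "static")) || is.null(foci) ||
    nrow(foci) == 0 || all(is.na(foci$frame))
  det <- truth[truth$detected, c("frame", "x_um", "y_um"), drop = FALSE]

  for (f in seq_len(nf)) {
    fr <- f - 1L
    img1 <- matrix(0, npix, npix)
    if (!is.null(foci) && nrow(foci) > 0) {
      fo <- if (static_foci) foci else foci[!is.na(foci$frame) & foci$frame == fr, ]
      if (nrow(fo) > 0)
        img1 <- add_gaussians(img1, fo$x_um, fo$y_um, foci_photons, sig, px, half)
    }
    img2 <- matrix(0, npix, npix)
    d <- det[det$frame == fr, , drop = FALSE]
    if (nrow(d) > 0)
      img2 <- add_gaussians(img2, d$x_um, d$y_um,
                            opt$photons_per_molecule_per_frame, sig, px, half)
    img1 <- img1 + opt$background_rate
    img2 <- img2 + opt$background_rate
    if (noise) {
      img1 <- matrix(stats::rpois(npix * npix, img1), npix, npix)
      img2 <- matrix(stats::rpois(npix * npix, img2), npix, npix)
    }
    ch1[, , f] <- opt$camera_offset + opt$camera_gain * img1
    ch2[, , f] <- opt$camera_offset + opt$camera_gain * img2
  }
  structure(list(channel1 = ch1, channel2 = ch2, pixel_size = px,
                 frame_interval = config$frame_interval, fov_um = npix * px,
                 origin_um = -half, dZ = config$dZ),
            class = "movie_stack")
}

# add photon-conserving Gaussian spots to an image; coordinates are in um
# with the image centred at the origin. Pixel (row i, col j) covers
# x in [origin + (j-1) px, origin + j px), y likewise with rows.
add_gaussians <- function(img, x, y, photons, sigma, px, half) {
  npix <- nrow(img)
  w <- ceiling(4 * sigma / px)
  for (k in seq_along(x)) {
    cx <- (x[k] + half) / px  # in pixel units from image edge
    cy <- (y[k] + half) / px
    j0 <- max(1L, floor(cx) - w); j1 <- min(npix, floor(cx) + w + 1L)
    i0 <- max(1L, floor(cy) - w); i1 <- min(npix, floor(cy) + w + 1L)
    if (j0 > j1 || i0 > i1) next
    jj <- j0:j1; ii <- i0:i1
    fx <- pnorm((jj - cx) * px, sd = sigma) - pnorm((jj - 1 - cx) * px, sd = sigma)
    fy <- pnorm((ii - cy) * px, sd = sigma) - pnorm((ii - 1 - cy) * px, sd = sigma)
    img[ii, jj] <- img[ii, jj] + photons * outer(fy, fx)
  }
  img
}

#' Convert between pixel and micrometre coordinates of a movie
#'
#' @param movie A `movie_stack`.
#' @param x_px,y_px Pixel-centre coordinates (1-based; the centre of pixel
#'   (1,1) is at 0.5 px).
#' @return `px_to_um` returns a two-column matrix of micrometre coordinates.
#' @export
px_to_um <- function(movie, x_px, y_px) {
  cbind(x_um = movie$origin_um + x_px * movie$pixel_size,
        y_um = movie$origin_um + y_px * movie$pixel_size)
}

#' Write a movie stack to multi-page 16-bit TIFF files
#'
#' One TIFF per channel plus a YAML metadata sidecar carrying
#' `frame_interval`, `pixel_size` and `dZ`.
#'
#' @param movie A `movie_stack`.
#' @param basename Output path prefix; writes `<basename>_ch1.tif`,
#'   `<basename>_ch2.tif`, `<basename>.yaml`.
#' @return Invisibly, the paths written.
#' @export
write_movie <- function(movie, basename) {
  paths <- c(ch1 = paste0(basename, "_ch1.tif"),
             ch2 = paste0(basename, "_ch2.tif"),
             meta = paste0(basename, ".yaml"))
  for (ch in 1:2) {
    arr <- movie[[paste0("channel", ch)]]
    frames <- lapply(seq_len(dim(arr)[3]), function(f) {
      m <- arr[, , f]
      m[m < 0] <- 0; m[m > 65535] <- 65535
      m / 65535  # tiff package stores [0,1]; 16-bit quantization on write
    })
    tiff::writeTIFF(frames, paths[[ch]], bits.per.sample = 16L)
  }
  yaml::write_yaml(list(frame_interval = movie$frame_interval,
                        pixel_size = movie$pixel_size, dZ = movie$dZ,
                        fov_um = movie$fov_um, origin_um = movie$origin_um),
                   paths[["meta"]])
  invisible(paths)
}

#' Read a movie written by [write_movie()]
#'
#' @param basename Path prefix used at write time.
#' @return A `movie_stack` (counts rescaled to the original 16-bit range).
#' @export
read_movie <- function(basename) {
  meta <- yaml::read_yaml(paste0(basename, ".yaml"))
  rd <- function(p) {
    fr <- tiff::readTIFF(p, all = TRUE)
    arr <- array(0, dim = c(nrow(fr[[1]]), ncol(fr[[1]]), length(fr)))
    for (f in seq_along(fr)) arr[, , f] <- fr[[f]] * 65535
    arr
  }
  structure(list(channel1 = rd(paste0(basename, "_ch1.tif")),
                 channel2 = rd(paste0(basename, "_ch2.tif")),
                 pixel_size = meta$pixel_size,
                 frame_interval = meta$frame_interval,
                 fov_um = meta$fov_um, origin_um = meta$origin_um,
                 dZ = meta$dZ),
            class = "movie_stack")
}
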
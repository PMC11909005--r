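#' Convert a pixel distance threshold to micrometres
#'
#' @param pixels Number of pixels (>= 0).
#' @param pixel_size Pixel size (um).
#' @return Distance in micrometres (`pixels * pixel_size`).
#' @export
pixel_threshold <- function(pixels, pixel_size) {
  if (pixels < 0) abort_param("`pixels` must be >= 0")
  check_pos(pixel_size, "pixel_size")
  pixels * pixel_size
}

#' Detect telomere marker foci in the marker channel
#'
#' Frames of a short stack are temporally averaged, pixels above the
#' threshold form connected regions (8-connectivity), and each region is
#' reduced to its intensity-weighted centroid. Centroids closer than
#' `merge_radius` are merged into their intensity-weighted midpoint.
#'
#' @param marker Numeric matrix, 3D array (`ny x nx x frames`) or a
#'   `movie_stack` (channel 1 used).
#' @param min_intensity Absolute intensity threshold; `NULL` uses
#'   median + 5 * MAD of the averaged image.
#' @param merge_radius Merge distance in micrometres.
#' @param pixel_size Pixel size (um); taken from a `movie_stack` input.
#' @param origin_um Micrometre coordinate of the image edge.
#' @return A static `foci_set`.
#' @export
detect_foci <- function(marker, min_intensity = NULL, merge_radius = 0.3,
                        pixel_size = 0.16, origin_um = 0) {
  if (inherits(marker, "movie_stack")) {
    pixel_size <- marker$pixel_size
    origin_um <- marker$origin_um
    marker <- marker$channel1
  }
  img <- if (length(dim(marker)) == 3) apply(marker, c(1, 2), mean) else marker
  stopifnot(is.matrix(img))
  empty <- new_foci_set(tibble::tibble(focus_id = integer(),
                                       frame = integer(), x_um = numeric(),
                                       y_um = numeric()), static = TRUE)
  bg <- stats::median(img)
  thr <- min_intensity %||% (bg + 5 * stats::mad(img))
  mask <- img > thr
  if (!any(mask)) return(empty)
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  lab <- EBImage::imageData(lab)
  ids <- sort(unique(lab[lab > 0]))
  wimg <- pmax(img - bg, 0)
  cx <- cy <- wt <- numeric(length(ids))
  for (k in seq_along(ids)) {
    idx <- which(lab == ids[k], arr.ind = TRUE)
    ww <- wimg[idx]
    wt[k] <- sum(ww)
    cy[k] <- sum((idx[, 1] - 0.5) * ww) / wt[k]   # rows -> y (pixel units)
    cx[k] <- sum((idx[, 2] - 0.5) * ww) / wt[k]   # cols -> x
  }
  x <- origin_um + cx * pixel_size
  y <- origin_um + cy * pixel_size
  # merge near-coincident regions
  if (length(x) > 1 && merge_radius > 0) {
    hc <- stats::hclust(stats::dist(cbind(x, y)), method = "single")
    grp <- stats::cutree(hc, h = merge_radius)
    x <- tapply(x * wt, grp, sum) / tapply(wt, grp, sum)
    y <- tapply(y * wt, grp, sum) / tapply(wt, grp, sum)
    x <- as.numeric(x); y <- as.numeric(y)
  }
  new_foci_set(tibble::tibble(focus_id = seq_along(x), frame = NA_integer_,
                              x_um = x, y_um = y), static = TRUE)
}

#' Classify tracks as telomere-vicinity or non-telomere
#'
#' A track is `telomeric` when its distance to the nearest focus centroid
#' is at most `threshold` (boundary inclusive; the classical rule is 3
#' pixels = 0.48 um). By default the distance uses the track's
#' time-averaged position against static focus centroids (time-averaged
#' for slowly moving foci); `method = "any_frame"` instead labels a track
#' telomeric if any localization comes within the threshold of a
#' (frame-matched, when available) focus position.
#'
#' @param tracks A `track_table`.
#' @param foci A `foci_set`.
#' @param threshold Distance threshold in micrometres (default 0.48).
#' @param method `"mean_position"` (default) or `"any_frame"`.
#' @return A tibble of class `track_classification` with `track_id`,
#'   `distance_um` (distance used for the rule) and `label`.
#' @export
classify_tracks <- function(tracks, foci, threshold = 0.48,
                            method = c("mean_position", "any_frame")) {
  method <- match.arg(method)
  check_nonneg(threshold, "threshold")
  ps_t <- attr(tracks, "pixel_size"); ps_f <- attr(foci, "pixel_size")
  if (!is.null(ps_f) && !is.na(ps_f) && !is.na(ps_t) && ps_t != ps_f)
    abort_param("tracks and foci carry different pixel-size metadata")
  ids <- unique(tracks$track_id)
  if (length(ids) == 0)
    return(structure(tibble::tibble(track_id = integer(),
                                    distance_um = numeric(),
                                    label = character()),
                     class = c("track_classification", class(tibble::tibble()))))
  no_foci <- is.null(foci) || nrow(foci) == 0
  per_frame_foci <- !no_foci && !isTRUE(attr(foci, "static")) &&
    any(!is.na(foci$frame))

  if (method == "mean_position") {
    mx <- tapply(tracks$x_um, tracks$track_id, mean)
    my <- tapply(tracks$y_um, tracks$track_id, mean)
    ids <- as.numeric(names(mx))
    if (no_foci) {
      dmin <- rep(Inf, length(ids))
    } else {
      fp <- foci_positions(foci)
      d2 <- outer(as.numeric(mx), fp[, 1], `-`)^2 +
        outer(as.numeric(my), fp[, 2], `-`)^2
      dmin <- sqrt(apply(d2, 1, min))
    }
  } else {
    ids <- sort(ids)
    dmin <- rep(Inf, length(ids))
    if (!no_foci) {
      if (per_frame_foci) {
        for (k in seq_along(ids)) {
          tr <- tracks[tracks$track_id == ids[k], ]
          fo <- foci[foci$frame %in% tr$frame, ]
          if (nrow(fo) == 0) next
          m <- merge(as.data.frame(tr[, c("frame", "x_um", "y_um")]),
                     as.data.frame(fo[, c("frame", "x_um", "y_um")]),
                     by = "frame", suffixes = c("", ".f"))
          if (nrow(m)) dmin[k] <- sqrt(min((m$x_um - m$x_um.f)^2 +
                                           (m$y_um - m$y_um.f)^2))
        }
      } else {
        fp <- foci_positions(foci)
        d2 <- outer(tracks$x_um, fp[, 1], `-`)^2 +
          outer(tracks$y_um, fp[, 2], `-`)^2
        dloc <- sqrt(apply(d2, 1, min))
        dmin <- as.numeric(tapply(dloc, tracks$track_id, min))
        ids <- as.numeric(names(tapply(dloc, tracks$track_id, min)))
      }
    }
  }
  out <- tibble::tibble(track_id = ids, distance_um = as.numeric(dmin),
                        label = ifelse(dmin <= threshold, "telomeric",
                                       "non_telomeric"))
  class(out) <- c("track_classification", class(out))
  attr(out, "threshold") <- threshold
  attr(out, "method") <- method
  out
}

#' Split a track table by telomere classification
#'
#' @param tracks A `track_table`.
#' @param classification Output of [classify_tracks()].
#' @return List with elements `telomeric` and `non_telomeric`, both
#'   `track_table`s.
#' @export
split_by_classification <- function(tracks, classification) {
  telo_ids <- classification$track_id[classification$label == "telomeric"]
  mk <- function(df) new_track_table(df,
                                     frame_interval = attr(tracks, "frame_interval"),
                                     pixel_size = attr(tracks, "pixel_size"),
                                     source = attr(tracks, "source"))
  list(telomeric = mk(tracks[tracks$track_id %in% telo_ids, ]),
       non_telomeric = mk(tracks[!tracks$track_id %in% telo_ids, ]))
}

#' Telomere-bound share of all bound molecules
#'
#' Combines the per-group two-state fits: the bound-jump mass of each group
#' is its jump count times its bound fraction, and the share is the
#' telomeric group's bound mass over the total bound mass,
#' `(n_telo * F_telo) / (n_telo * F_telo + n_non * F_non)`.
#'
#' @param fit_telo,fit_non `two_state_fit`s (or lists with `F_bound`) for
#'   the telomere-vicinity and non-telomere groups.
#' @param n_telo,n_non Jump counts of the two groups.
#' @return Share in `[0, 1]`; 0 when the total bound mass is 0.
#' @export
telomere_bound_share <- function(fit_telo, n_telo, fit_non, n_non) {
  if (n_telo < 0 || n_non < 0) abort_param("jump counts must be >= 0")
  conv <- c(fit_telo$converged %||% TRUE, fit_non$converged %||% TRUE)
  if (!all(conv))
    warning("a per-group two-state fit did not report convergence")
  num <- n_telo * fit_telo$F_bound
  den <- num + n_non * fit_non$F_bound
  if (den <= 0) return(0)
  num / den
}

#' Chance-colocalization probability of the focus pattern
#'
#' Probability that a point placed uniformly in the nuclear projection
#' falls within `threshold` of at least one focus centroid. With 160 foci
#' and the 0.48 um rule this is large in a realistic nucleus, so the raw
#' telomere-bound share is dominated by chance colocalization of
#' non-telomeric binding sites with foci; this estimate feeds the
#' randomization-corrected share (see [corrected_share()]).
#'
#' @param foci A `foci_set`.
#' @param nucleus_radius Radius of the nuclear projection (um).
#' @param threshold Colocalization distance (um).
#' @param n_points Monte-Carlo sample size.
#' @param seed Seed (local to the call).
#' @return Probability in `[0, 1]`.
#' @export
chance_colocalization <- function(foci, nucleus_radius, threshold = 0.48,
                                  n_points = 2e5, seed = 99) {
  if (is.null(foci) || nrow(foci) == 0) return(0)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  pts <- runif_disk(n_points, nucleus_radius)
  fp <- foci_positions(foci)
  hit <- rep(FALSE, n_points)
  for (k in seq_len(nrow(fp))) {
    hit <- hit | ((pts[, 1] - fp[k, 1])^2 + (pts[, 2] - fp[k, 2])^2 <=
                    threshold^2)
  }
  mean(hit)
}

#' Rotate focus centroids about the nuclear centre
#'
#' Used to build a randomization null for colocalization: rotation keeps
#' the focus pattern and the nuclear geometry but destroys any true
#' correspondence between binding sites and foci.
#'
#' @param foci A `foci_set` (coordinates centred on the nucleus).
#' @param angle Rotation angle in radians.
#' @return A rotated `foci_set`.
#' @export
rotate_foci <- function(foci, angle) {
  x <- foci$x_um * cos(angle) - foci$y_um * sin(angle)
  y <- foci$x_um * sin(angle) + foci$y_um * cos(angle)
  out <- foci
  out$x_um <- x
  out$y_um <- y
  out
}

#' Chance-corrected telomere-bound share
#'
#' Inverts the mixing relation `share_raw = s + (1 - s) * c`, where `c` is
#' the chance-colocalization probability of a uniformly placed binding
#' site with the focus pattern, to recover the specific telomere-bound
#' share `s = (share_raw - c) / (1 - c)` (clamped to `[0, 1]`). This is
#' the randomization control customary in colocalization analysis.
#'
#' @param share_raw Raw share from [telomere_bound_share()].
#' @param chance Chance-colocalization probability, e.g. from
#'   [chance_colocalization()].
#' @return Corrected share in `[0, 1]`.
#' @export
corrected_share <- function(share_raw, chance) {
  check_prob(share_raw, "share_raw"); check_prob(chance, "chance")
  if (chance >= 1) return(0)
  min(1, max(0, (share_raw - chance) / (1 - chance)))
}
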
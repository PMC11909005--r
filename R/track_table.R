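#' Track tables
#'
#' A `track_table` is a tibble of time-ordered sub-pixel localizations, one
#' row per (track, frame), with columns `track_id`, `frame`, `x_um`,
#' `y_um` and optionally `intensity`, `molecule` and ground-truth `state`.
#' Frame-interval and pixel-size metadata travel as attributes.
#'
#' @param df Data frame with at least `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval Frame spacing in seconds.
#' @param pixel_size Pixel size in micrometres.
#' @param source Free-text provenance tag.
#' @return A tibble of class `track_table`.
#' @export
track_table <- function(df, frame_interval, pixel_size = NA_real_,
                        source = "unknown") {
  need <- c("track_id", "frame", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_param(paste("track table lacks columns:", paste(miss, collapse = ", ")))
  check_pos(frame_interval, "frame_interval")
  df <- tibble::as_tibble(df)
  df <- df[order(df$track_id, df$frame), ]
  if (anyDuplicated(df[, c("track_id", "frame")]))
    abort_param("duplicate (track_id, frame) rows: frames must be strictly increasing within a track")
  new_track_table(df, frame_interval = frame_interval,
                  pixel_size = pixel_size, source = source)
}

new_track_table <- function(df, frame_interval, pixel_size, source) {
  df <- tibble::as_tibble(df)
  class(df) <- c("track_table", class(df))
  attr(df, "frame_interval") <- frame_interval
  attr(df, "pixel_size") <- pixel_size
  attr(df, "source") <- source
  df
}

#' @export
print.track_table <- function(x, ...) {
  cat(sprintf("<track_table> %d localizations in %d tracks (frame interval %g s)\n",
              nrow(x), length(unique(x$track_id)),
              attr(x, "frame_interval")))
  NextMethod()
}

#' Frame interval of a track table
#' @param tracks A `track_table`.
#' @return Frame spacing in seconds.
#' @export
frame_interval <- function(tracks) attr(tracks, "frame_interval")

#' Number of tracks
#' @param tracks A `track_table`.
#' @return Count of distinct track ids.
#' @export
n_tracks <- function(tracks) length(unique(tracks$track_id))

#' Read / write track tables as CSV
#'
#' CSV columns: `track_id, frame, x_um, y_um` plus any extras present.
#' Metadata (`frame_interval`, `pixel_size`) is not stored in the CSV and
#' must be supplied on read.
#'
#' @param path File path.
#' @param frame_interval,pixel_size Metadata for the returned table.
#' @return [read_track_csv()] returns a `track_table`.
#' @export
read_track_csv <- function(path, frame_interval, pixel_size = NA_real_) {
  df <- utils::read.csv(path)
  track_table(df, frame_interval = frame_interval, pixel_size = pixel_size,
              source = path)
}

#' @param tracks A `track_table`.
#' @rdname read_track_csv
#' @export
write_track_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' Read / write focus centroid tables as CSV
#'
#' CSV columns: `focus_id, frame, x_um, y_um` (`frame` empty for static
#' foci).
#' @param path File path.
#' @return [read_foci_csv()] returns a `foci_set`.
#' @export
read_foci_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("focus_id", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_param(paste("foci table lacks columns:", paste(miss, collapse = ", ")))
  if (is.null(df$frame)) df$frame <- NA_integer_
  new_foci_set(tibble::as_tibble(df[, c("focus_id", "frame", "x_um", "y_um")]),
               static = all(is.na(df$frame)))
}

#' @param foci A `foci_set`.
#' @rdname read_foci_csv
#' @export
write_foci_csv <- function(foci, path) {
  utils::write.csv(as.data.frame(foci), path, row.names = FALSE)
  invisible(path)
}
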
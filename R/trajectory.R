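#' Trajectory set
#'
#' A `trajectory_set` holds particle trajectories as a long-format data frame
#' with one row per localization, plus the camera frame interval. All positions
#' are in micrometres and times in seconds; pixel units are converted at I/O
#' boundaries only.
#'
#' @param points data frame with columns `track_id`, `frame`, `x_um`, `y_um`
#'   (and optionally `state` for ground-truth tracks). Frames are non-negative
#'   integers, strictly increasing within a track.
#' @param frame_interval camera frame interval in seconds.
#' @return An object of class `trajectory_set`: the points data frame with a
#'   `frame_interval` attribute.
#' @export
trajectory_set <- function(points, frame_interval) {
  required <- c("track_id", "frame", "x_um", "y_um")
  missing_cols <- setdiff(required, names(points))
  if (length(missing_cols) > 0L) {
    stop("trajectory points lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      !is.finite(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be a single positive number (seconds)")
  }
  points <- as.data.frame(points)
  if (nrow(points) > 0L) {
    if (any(!is.finite(points$x_um)) || any(!is.finite(points$y_um))) {
      stop("non-finite coordinates in trajectory points")
    }
    if (any(points$frame < 0) || any(points$frame != round(points$frame))) {
      stop("frames must be non-negative integers")
    }
    points <- points[order(points$track_id, points$frame), , drop = FALSE]
    rownames(points) <- NULL
    d <- unlist(tapply(points$frame, points$track_id, diff, simplify = FALSE),
                use.names = FALSE)
    if (length(d) > 0L && any(d <= 0)) {
      stop("frames must be strictly increasing within a track")
    }
  }
  structure(points, frame_interval = frame_interval,
            class = c("trajectory_set", "data.frame"))
}

#' @export
print.trajectory_set <- function(x, ...) {
  n_tracks <- length(unique(x$track_id))
  cat(sprintf("trajectory_set: %d tracks, %d localizations, frame interval %g s\n",
              n_tracks, nrow(x), attr(x, "frame_interval")))
  if (n_tracks > 0L) {
    len <- table(x$track_id)
    cat(sprintf("  track length: median %g, range %d-%d; frames %d-%d\n",
                stats::median(len), min(len), max(len),
                min(x$frame), max(x$frame)))
  }
  invisible(x)
}

#' Frame interval of a trajectory set
#' @param tracks a `trajectory_set`.
#' @return Frame interval in seconds.
#' @export
frame_interval <- function(tracks) {
  fi <- attr(tracks, "frame_interval")
  if (is.null(fi)) stop("object has no frame_interval attribute")
  fi
}

#' Number of tracks
#' @param tracks a `trajectory_set`.
#' @return Integer count of distinct tracks.
#' @export
n_tracks <- function(tracks) length(unique(tracks$track_id))

#' Read tracks from CSV
#'
#' Reads a track table with columns `track_id, frame, x_um, y_um[, state]`
#' (the schema written by [write_tracks_csv()] and the simulator).
#'
#' @param file path to a CSV file.
#' @param frame_interval frame interval in seconds.
#' @return A [trajectory_set()].
#' @export
read_tracks_csv <- function(file, frame_interval = 0.02) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  trajectory_set(df, frame_interval = frame_interval)
}

#' Write tracks to CSV
#' @param tracks a `trajectory_set`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_tracks_csv <- function(tracks, file) {
  utils::write.csv(as.data.frame(tracks), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Import a TrackMate spots export
#'
#' Reads the spots CSV exported by TrackMate (columns `TRACK_ID`, `FRAME`,
#' `POSITION_X`, `POSITION_Y`; recent versions prepend extra header rows,
#' which are dropped). Positions are multiplied by `pixel_size_um` so that
#' exports in pixel units can be converted; exports already calibrated in
#' micrometres use the default of 1.
#'
#' @param file path to the TrackMate spots CSV.
#' @param pixel_size_um length of one pixel in micrometres (default 1,
#'   i.e. positions already in um).
#' @param frame_interval frame interval in seconds.
#' @return A [trajectory_set()].
#' @export
read_trackmate_csv <- function(file, pixel_size_um = 1, frame_interval = 0.02) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")
  if (!all(need %in% names(raw))) {
    stop("not a TrackMate spots export; need columns: ", paste(need, collapse = ", "))
  }
  # extra header rows contain non-numeric FRAME entries
  fr <- suppressWarnings(as.numeric(raw$FRAME))
  raw <- raw[!is.na(fr), , drop = FALSE]
  df <- data.frame(
    track_id = as.integer(as.numeric(raw$TRACK_ID)),
    frame = as.integer(as.numeric(raw$FRAME)),
    x_um = as.numeric(raw$POSITION_X) * pixel_size_um,
    y_um = as.numeric(raw$POSITION_Y) * pixel_size_um
  )
  df <- df[!is.na(df$track_id), , drop = FALSE]
  trajectory_set(df, frame_interval = frame_interval)
}
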
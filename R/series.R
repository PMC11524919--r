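# Core recording containers shared by the generator and the IO layer.
#
# Coordinate conventions (owned here and by the IO module):
#   * image: origin top-left, x rightward, y downward (screen), pixels;
#   * sensor: origin at mat centre, X mediolateral (rightward as seen by the
#     camera), Y anteroposterior, cm; grid row 0 is the far (positive-Y) edge;
#   * timestamps in seconds from trial start.

#' Pressure frame series
#'
#' Sparse per-frame plantar pressure on the sensor grid.
#'
#' @param timestamps Strictly increasing frame times, seconds.
#' @param cells Tibble/data frame with columns `frame` (1-based frame index),
#'   `row`, `col` (0-based grid indices) and `value` (pressure, arbitrary
#'   units, non-negative).
#' @param grid_cells Grid dimensions (rows, cols).
#' @param cell_pitch Cell side length, cm.
#'
#' @return An object of class `olst_pressure`.
#' @export
pressure_series <- function(timestamps, cells, grid_cells, cell_pitch) {
  cells <- as_tibble(cells)
  stopifnot(all(c("frame", "row", "col", "value") %in% names(cells)))
  n <- length(timestamps)
  if (n == 0L) {
    stop_olst("a pressure series needs at least one frame", "olst_format_error")
  }
  if (n > 1L && any(diff(timestamps) <= 0)) {
    stop_olst("pressure timestamps must be strictly increasing",
              "olst_format_error")
  }
  bad <- which(cells$value < 0)
  if (length(bad)) {
    stop_olst(sprintf("negative pressure at cell record %d", bad[[1]]),
              "olst_format_error")
  }
  if (any(cells$row < 0 | cells$row >= grid_cells[[1]] |
          cells$col < 0 | cells$col >= grid_cells[[2]])) {
    stop_olst("pressure cell indices outside the grid", "olst_format_error")
  }
  if (any(cells$frame < 1 | cells$frame > n)) {
    stop_olst("pressure cell frame index out of range", "olst_format_error")
  }
  structure(
    list(timestamps = as.numeric(timestamps), cells = cells,
         grid_cells = as.integer(grid_cells), cell_pitch = cell_pitch),
    class = "olst_pressure"
  )
}

#' Keypoint series
#'
#' Named 2-D skeletal landmarks with confidences for one trial.
#'
#' @param timestamps Frame times, seconds.
#' @param coords Numeric array `[frame, landmark, (x, y, confidence)]` with
#'   the 15 landmark names of `olst_landmarks()` on the second dimension;
#'   image coordinates in pixels, confidences in \[0, 1\].
#' @param image_size Camera frame size (width, height), pixels.
#' @param px_per_cm Image calibration scale, pixels per cm.
#'
#' @return An object of class `olst_keypoints`.
#' @export
keypoint_series <- function(timestamps, coords, image_size, px_per_cm) {
  if (length(dim(coords)) != 3L || dim(coords)[[3]] != 3L) {
    stop_olst("`coords` must be a [frame, landmark, 3] array",
              "olst_format_error")
  }
  if (dim(coords)[[1]] != length(timestamps)) {
    stop_olst("keypoint frames do not match the timestamp vector",
              "olst_format_error")
  }
  lm <- dimnames(coords)[[2]]
  if (is.null(lm) || !all(lm %in% LANDMARKS) || !all(LANDMARKS %in% lm)) {
    stop_olst("keypoint landmarks must be exactly the 15-name vocabulary",
              "olst_format_error")
  }
  conf <- coords[, , 3, drop = FALSE]
  if (any(conf < 0 | conf > 1, na.rm = TRUE)) {
    stop_olst("keypoint confidences must lie in [0, 1]", "olst_format_error")
  }
  structure(
    list(timestamps = as.numeric(timestamps),
         coords = coords[, LANDMARKS, , drop = FALSE],
         image_size = as.integer(image_size), px_per_cm = px_per_cm),
    class = "olst_keypoints"
  )
}

#' Trial recording
#'
#' One one-legged standing trial: the stance leg, the realized duration, and
#' the two synchronized recording streams.
#'
#' @param leg `"right"` or `"left"`.
#' @param duration Trial duration, seconds.
#' @param pressure A [pressure_series()].
#' @param keypoints A [keypoint_series()].
#'
#' @return An object of class `olst_trial`.
#' @export
trial_recording <- function(leg, duration, pressure, keypoints) {
  leg <- match.arg(leg, c("right", "left"))
  stopifnot(inherits(pressure, "olst_pressure"),
            inherits(keypoints, "olst_keypoints"))
  if (length(pressure$timestamps) != length(keypoints$timestamps) ||
      max(abs(pressure$timestamps - keypoints$timestamps)) > 1e-9) {
    stop_olst("pressure and keypoint streams are not synchronous",
              "olst_format_error")
  }
  if (duration <= 0) {
    stop_olst("trial duration must be positive", "olst_format_error")
  }
  structure(list(leg = leg, duration = duration, pressure = pressure,
                 keypoints = keypoints),
            class = "olst_trial")
}

#' Landmark and angle vocabularies
#'
#' @return Character vectors: the 15 landmark names, or the 10 joint-angle
#'   names used throughout the package.
#' @export
olst_landmarks <- function() LANDMARKS

#' @rdname olst_landmarks
#' @export
olst_angles <- function() ANGLE_NAMES

# cell-centre coordinates (cm, sensor frame) for 0-based row/col indices
cell_centers <- function(row, col, grid_cells, cell_pitch, sensor_size) {
  list(
    x = (col + 0.5) * cell_pitch - sensor_size / 2,
    y = sensor_size / 2 - (row + 0.5) * cell_pitch
  )
}
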
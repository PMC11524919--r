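# COP trajectory and the COP-sway / overall-balance explanatory variables.

# Dempster segment mass fractions used for the 2-D COM estimate
SEGMENT_MASS <- list(
  list(w = 0.081, a = "nose", b = "neck"),            # head + neck
  list(w = 0.497, a = "neck", b = "mid_hip"),         # trunk
  list(w = 0.028, a = "right_shoulder", b = "right_elbow"),
  list(w = 0.028, a = "left_shoulder", b = "left_elbow"),
  list(w = 0.022, a = "right_elbow", b = "right_wrist"),
  list(w = 0.022, a = "left_elbow", b = "left_wrist"),
  list(w = 0.100, a = "right_hip", b = "right_knee"),
  list(w = 0.100, a = "left_hip", b = "left_knee"),
  list(w = 0.061, a = "right_knee", b = "right_ankle"),
  list(w = 0.061, a = "left_knee", b = "left_ankle")
)

#' Compute the COP trajectory from a pressure frame series
#'
#' Per frame the COP is the pressure-weighted centroid of the active cells
#' (cell-centre coordinates, cm, sensor frame). The foot region is summarized
#' by the pressure-weighted second-moment ellipse pooled over all valid
#' frames, and the trajectory is rotated about the ellipse centre so that the
#' major axis becomes the Y (anteroposterior) axis and the minor axis the X
#' (mediolateral) axis.
#'
#' @param series A [pressure_series()].
#' @param active_frac A cell is active when its pressure exceeds this
#'   fraction of the frame maximum.
#' @param pressure_frac A frame is valid when its total pressure exceeds this
#'   fraction of the trial median total.
#' @param min_active Minimum number of active cells for a valid frame.
#'
#' @return An object of class `olst_cop`: timestamps, rotated `x`/`y`
#'   coordinates (cm), a `valid` flag per frame, and the foot `ellipse`
#'   (centre, semi-axis lengths, orientation in radians).
#' @export
compute_cop_trajectory <- function(series, active_frac = 0.05,
                                   pressure_frac = 0.1, min_active = 3L) {
  stopifnot(inherits(series, "olst_pressure"))
  n <- length(series$timestamps)
  cells <- series$cells
  ctr <- cell_centers(cells$row, cells$col, series$grid_cells,
                      series$cell_pitch, series$grid_cells[[1L]] *
                        series$cell_pitch)
  fmax <- tapply(cells$value, cells$frame, max)
  active <- cells$value > active_frac * fmax[as.character(cells$frame)]
  ac <- cells[active, ]
  ax <- ctr$x[active]
  ay <- ctr$y[active]

  tot <- rep(0, n)
  cx <- rep(NA_real_, n)
  cy <- rep(NA_real_, n)
  nact <- rep(0L, n)
  sums <- rowsum(cbind(ac$value, ac$value * ax, ac$value * ay, 1),
                 ac$frame)
  fr <- as.integer(rownames(sums))
  tot[fr] <- sums[, 1L]
  cx[fr] <- sums[, 2L] / sums[, 1L]
  cy[fr] <- sums[, 3L] / sums[, 1L]
  nact[fr] <- as.integer(sums[, 4L])

  valid <- tot > pressure_frac * stats::median(tot) & nact >= min_active &
    is.finite(cx)
  if (!any(valid)) {
    stop_olst("no valid frames: cannot form a COP trajectory",
              "olst_empty_trajectory_error")
  }

  # pooled second-moment ellipse over active cells of valid frames
  vsel <- active & valid[cells$frame]
  w <- cells$value[vsel]
  ex <- ctr$x[vsel]
  ey <- ctr$y[vsel]
  wsum <- sum(w)
  mx <- sum(w * ex) / wsum
  my <- sum(w * ey) / wsum
  cxx <- sum(w * (ex - mx)^2) / wsum
  cyy <- sum(w * (ey - my)^2) / wsum
  cxy <- sum(w * (ex - mx) * (ey - my)) / wsum
  cov <- matrix(c(cxx, cxy, cxy, cyy), 2L)
  if (all(abs(cov) < 1e-12)) {
    major <- c(0, 1)
    axes <- c(1e-6, 1e-6)
  } else {
    eg <- eigen(cov, symmetric = TRUE)
    major <- eg$vectors[, 1L]
    axes <- 2 * sqrt(pmax(eg$values, 1e-12))
  }
  if (major[[2L]] < 0 || (major[[2L]] == 0 && major[[1L]] < 0)) {
    major <- -major
  }
  theta <- pi / 2 - atan2(major[[2L]], major[[1L]]) # rotate major onto +Y
  rx <- cos(theta) * (cx - mx) - sin(theta) * (cy - my) + mx
  ry <- sin(theta) * (cx - mx) + cos(theta) * (cy - my) + my

  structure(
    list(
      timestamps = series$timestamps, x = rx, y = ry, valid = valid,
      ellipse = list(center = c(mx, my),
                     axes = c(major = max(axes), minor = min(axes)),
                     orientation = atan2(major[[2L]], major[[1L]])),
      rotation = theta
    ),
    class = "olst_cop"
  )
}

# valid points of a trajectory restricted to [window[1], window[2])
window_points <- function(traj, window = NULL) {
  keep <- traj$valid
  if (!is.null(window)) {
    keep <- keep & traj$timestamps >= window[[1L]] &
      traj$timestamps < window[[2L]]
  }
  tibble(t = traj$timestamps[keep], x = traj$x[keep], y = traj$y[keep])
}

#' Sway path length and mean COP speed
#'
#' Total length of the COP sway path (sum of consecutive Euclidean distances
#' between valid points) and its mean speed (path length over the elapsed
#' time between the first and last valid point of the window).
#'
#' @param traj An `olst_cop` trajectory.
#' @param window Time interval `c(from, to)` in seconds (right-open), or
#'   `NULL` for the full trial.
#'
#' @return A tibble with columns `len_total_path` (cm) and `m_cop_speed`
#'   (cm/s).
#' @export
sway_path_metrics <- function(traj, window = NULL) {
  pts <- window_points(traj, window)
  if (nrow(pts) < 2L) {
    stop_olst("need at least 2 valid COP points in the window",
              "olst_insufficient_data_error")
  }
  len <- sum(sqrt(diff(pts$x)^2 + diff(pts$y)^2))
  elapsed <- pts$t[[nrow(pts)]] - pts$t[[1L]]
  tibble(len_total_path = len, m_cop_speed = len / elapsed)
}

#' Approximate entropy (Pincus ApEn)
#'
#' Classical approximate entropy `Phi^m - Phi^(m+1)` with self-matches
#' counted and Chebyshev (maximum) distance between templates. Lower values
#' indicate a more regular, repetitive signal.
#'
#' @param x Numeric series.
#' @param m Embedding (template) length.
#' @param r Tolerance, in the units of `x`. The posturography convention is
#'   `0.2 * sd(x)`. A non-positive `r` (e.g. from a constant series under a
#'   relative tolerance) returns 0 by convention, with a warning.
#'
#' @return A single non-negative number (dimensionless).
#' @export
approximate_entropy <- function(x, m = 2L, r = 0.2 * sd(x)) {
  n <- length(x)
  if (n < m + 2L) {
    stop_olst("series too short for approximate entropy",
              "olst_insufficient_data_error")
  }
  if (is.na(r) || r <= 0) {
    rlang::warn("non-positive ApEn tolerance; returning 0 by convention")
    return(0)
  }
  phi <- function(mm) {
    nt <- n - mm + 1L
    emb <- sapply(seq_len(mm), function(k) x[k:(k + nt - 1L)])
    emb <- matrix(emb, nrow = nt)
    cnt <- vapply(seq_len(nt), function(i) {
      d <- abs(emb - matrix(emb[i, ], nt, mm, byrow = TRUE))
      sum(apply(d, 1L, max) <= r)
    }, integer(1))
    mean(log(cnt / nt))
  }
  phi(m) - phi(m + 1L)
}

#' Convex hull area of a 2-D point set
#'
#' Area (cm^2) of the smallest convex polygon containing all points. Fewer
#' than three distinct points, or a collinear set, has area 0.
#'
#' @param points Two-column matrix or data frame of (x, y) coordinates.
#'
#' @return A single non-negative number.
#' @export
convex_hull_area <- function(points) {
  pts <- as.matrix(points)
  if (nrow(pts) == 0L) {
    stop_olst("empty point set", "olst_insufficient_data_error")
  }
  pts <- unique(pts)
  if (nrow(pts) < 3L) return(0)
  h <- grDevices::chull(pts[, 1L], pts[, 2L])
  if (length(h) < 3L) return(0)
  hx <- pts[h, 1L]
  hy <- pts[h, 2L]
  abs(sum(hx * c(hy[-1L], hy[[1L]]) - c(hx[-1L], hx[[1L]]) * hy)) / 2
}

#' Mediolateral COM-COP distance
#'
#' Estimates the body centre of mass per frame as the anthropometric
#' (Dempster) weighted mean of segment mid-points from the 2-D keypoints,
#' converts the mediolateral component to cm, aligns its mean to the COP
#' mediolateral coordinate over the window (the image-to-mat offset is not
#' observable from a frontal camera), and returns the mean absolute
#' deviation between the two series.
#'
#' @param keypoints A [keypoint_series()].
#' @param traj The matching `olst_cop` trajectory.
#' @param window Time interval `c(from, to)` (right-open) or `NULL`.
#' @param min_conf Landmark confidence below which a frame is invalid.
#' @param min_valid_frac Minimum fraction of window frames that must be
#'   valid.
#'
#' @return Mean absolute COM-COP mediolateral distance, cm.
#' @export
com_cop_distance <- function(keypoints, traj, window = NULL,
                             min_conf = 0.1, min_valid_frac = 0.5) {
  stopifnot(inherits(keypoints, "olst_keypoints"))
  tt <- keypoints$timestamps
  keep <- rep(TRUE, length(tt))
  if (!is.null(window)) keep <- tt >= window[[1L]] & tt < window[[2L]]
  conf_ok <- apply(keypoints$coords[, , 3, drop = FALSE] >= min_conf, 1L, all)
  valid <- keep & conf_ok & traj$valid
  if (sum(valid) < max(2L, ceiling(min_valid_frac * sum(keep)))) {
    stop_olst("too few frames with complete landmarks for the COM estimate",
              "olst_insufficient_data_error")
  }
  com_px <- rep(0, length(tt))
  for (seg in SEGMENT_MASS) {
    com_px <- com_px + seg$w *
      (keypoints$coords[, seg$a, 1] + keypoints$coords[, seg$b, 1]) / 2
  }
  com_cm <- com_px / keypoints$px_per_cm
  d <- com_cm[valid] - traj$x[valid]
  mean(abs(d - mean(d)))
}

#' Longest one-leg standing time
#'
#' @param trials List of [trial_recording()] objects (one participant).
#'
#' @return Maximum trial duration, seconds.
#' @export
max_trial_duration <- function(trials) {
  if (length(trials) == 0L) {
    stop_olst("no trials", "olst_insufficient_data_error")
  }
  max(vapply(trials, function(tr) tr$duration, numeric(1)))
}
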
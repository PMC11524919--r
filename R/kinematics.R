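# Joint-angle series from keypoints and the COP-joint coupling correlations.

# interior angle (degrees) at vertex v between segments v->a and v->b,
# all inputs n x 2 matrices in y-up coordinates
interior_angle <- function(v, a, b) {
  u1 <- a - v
  u2 <- b - v
  dot <- rowSums(u1 * u2)
  n1 <- sqrt(rowSums(u1^2))
  n2 <- sqrt(rowSums(u2^2))
  cosang <- pmin(pmax(dot / (n1 * n2), -1), 1)
  acos(cosang) * 180 / pi
}

# inclination (degrees, in (-90, 90]) of the a->b line to the horizontal
inclination_angle <- function(a, b) {
  d <- b - a
  wrap_inclination(atan2(d[, 2L], d[, 1L]) * 180 / pi)
}

#' Compute the 10 joint-angle series from a keypoint series
#'
#' Image coordinates are converted to y-up before any angle computation.
#' Definitions: `neck` and `shoulder` are inclinations of the neck-to-nose
#' and right-to-left-shoulder lines to the horizontal (degrees, in
#' (-90, 90\]); `right_elbow`/`left_elbow` are interior angles at the elbow
#' between the upper arm and forearm; `right_trunk`/`left_trunk` are
#' interior angles at the mid-hip between the trunk midline (mid-hip to
#' neck) and the mid-hip-to-hip segment; `right_hip`/`left_hip` at the hip
#' between the hip-to-shoulder and hip-to-knee segments; and
#' `right_knee`/`left_knee` at the knee between the thigh and shank.
#' A frame's angle is invalid when any required landmark has confidence
#' below `min_conf`.
#'
#' @param kp A [keypoint_series()].
#' @param min_conf Landmark confidence gate.
#'
#' @return An object of class `olst_angles`: timestamps, an
#'   `n x 10` matrix `angles` (degrees) and a matching logical `valid`
#'   matrix, with columns named by `olst_angles()`.
#' @export
compute_joint_angles <- function(kp, min_conf = 0.1) {
  stopifnot(inherits(kp, "olst_keypoints"))
  n <- length(kp$timestamps)
  # y-up coordinates
  pt <- function(name) {
    cbind(kp$coords[, name, 1], -kp$coords[, name, 2])
  }
  conf <- function(...) {
    nm <- c(...)
    ok <- rep(TRUE, n)
    for (l in nm) ok <- ok & kp$coords[, l, 3] >= min_conf
    ok
  }
  angles <- matrix(NA_real_, n, length(ANGLE_NAMES),
                   dimnames = list(NULL, ANGLE_NAMES))
  valid <- matrix(FALSE, n, length(ANGLE_NAMES),
                  dimnames = list(NULL, ANGLE_NAMES))

  angles[, "neck"] <- inclination_angle(pt("neck"), pt("nose"))
  valid[, "neck"] <- conf("neck", "nose")
  angles[, "shoulder"] <- inclination_angle(pt("right_shoulder"),
                                            pt("left_shoulder"))
  valid[, "shoulder"] <- conf("right_shoulder", "left_shoulder")
  for (s in c("right", "left")) {
    sh <- paste0(s, "_shoulder")
    el <- paste0(s, "_elbow")
    wr <- paste0(s, "_wrist")
    hp <- paste0(s, "_hip")
    kn <- paste0(s, "_knee")
    an <- paste0(s, "_ankle")
    angles[, el] <- interior_angle(pt(el), pt(sh), pt(wr))
    valid[, el] <- conf(el, sh, wr)
    angles[, paste0(s, "_trunk")] <-
      interior_angle(pt("mid_hip"), pt("neck"), pt(hp))
    valid[, paste0(s, "_trunk")] <- conf("mid_hip", "neck", hp)
    angles[, hp] <- interior_angle(pt(hp), pt(sh), pt(kn))
    valid[, hp] <- conf(hp, sh, kn)
    angles[, kn] <- interior_angle(pt(kn), pt(hp), pt(an))
    valid[, kn] <- conf(kn, hp, an)
  }
  structure(list(timestamps = kp$timestamps, angles = angles, valid = valid),
            class = "olst_angles")
}

#' Correlation between the first differences of two series
#'
#' Pearson correlation between the frame-to-frame changes of `a` and `b`,
#' computed over pairs where both differences are available.
#'
#' @param a,b Numeric series of equal length; `NA` marks invalid frames.
#' @param method `"pearson"` (default) or `"spearman"`.
#'
#' @return A list with `r` (in \[-1, 1\], or `NA` when either difference
#'   series has zero variance) and `n_pairs`.
#' @export
diff_correlation <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b)) {
    stop_olst("series lengths differ", "olst_format_error")
  }
  da <- diff(a)
  db <- diff(b)
  ok <- is.finite(da) & is.finite(db)
  if (sum(ok) < 3L) {
    stop_olst("fewer than 3 paired first differences",
              "olst_insufficient_data_error")
  }
  da <- da[ok]
  db <- db[ok]
  if (sd(da) == 0 || sd(db) == 0) {
    rlang::warn("zero variance in a difference series; correlation undefined")
    return(list(r = NA_real_, n_pairs = sum(ok)))
  }
  list(r = cor(da, db, method = method), n_pairs = sum(ok))
}

#' COP-joint coupling correlations
#'
#' For each of the 10 joint angles, the correlation between the change in
#' the COP mediolateral coordinate and the change in the angle, within the
#' analysis window. An undefined correlation (zero variance, too few valid
#' frames) propagates as `NA`.
#'
#' @param angles An `olst_angles` object.
#' @param traj The matching `olst_cop` trajectory.
#' @param window Time interval `c(from, to)` (right-open) or `NULL`.
#' @param cop_change Which COP scalar the coupling is measured against:
#'   mediolateral `"x"` (default), anteroposterior `"y"`, or the step
#'   `"magnitude"`.
#' @param method Correlation type passed to [diff_correlation()].
#'
#' @return A tibble with columns `angle`, `r`, `n_pairs` (10 rows, in the
#'   order of `olst_angles()`).
#' @export
cop_joint_correlations <- function(angles, traj, window = NULL,
                                   cop_change = c("x", "y", "magnitude"),
                                   method = "pearson") {
  cop_change <- match.arg(cop_change)
  stopifnot(inherits(angles, "olst_angles"))
  tt <- traj$timestamps
  keep <- rep(TRUE, length(tt))
  if (!is.null(window)) keep <- tt >= window[[1L]] & tt < window[[2L]]
  cop <- switch(cop_change,
    x = traj$x,
    y = traj$y,
    magnitude = sqrt(traj$x^2 + traj$y^2)
  )
  cop[!traj$valid] <- NA_real_
  cop <- cop[keep]
  out <- purrr::map(ANGLE_NAMES, function(nm) {
    ang <- angles$angles[keep, nm]
    ang[!angles$valid[keep, nm]] <- NA_real_
    res <- tryCatch(diff_correlation(cop, ang, method = method),
                    olst_insufficient_data_error = function(e) {
                      list(r = NA_real_, n_pairs = 0L)
                    })
    tibble(angle = nm, r = res$r, n_pairs = res$n_pairs)
  })
  dplyr::bind_rows(out)
}
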
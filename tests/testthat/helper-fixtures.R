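# Shared fixtures, built in code and cached for the test run.

small_cfg <- function(...) {
  olst_config(n_boys = 4, n_girls = 4, trial_cap = 6, ...)
}

.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(small_cfg(), seed = 101)
  }
  .fixture_env$cohort
}

fixture_features <- function() {
  if (is.null(.fixture_env$features)) {
    .fixture_env$features <- suppressMessages(
      build_feature_table(fixture_cohort())
    )
  }
  .fixture_env$features
}

# small cohort with boosted high-trait fractions so both classes always
# have enough members to cross-validate
fixture_features_balanced <- function() {
  if (is.null(.fixture_env$features_balanced)) {
    co <- generate_cohort(
      olst_config(n_boys = 6, n_girls = 6, trial_cap = 6,
                  high_frac = c(male = 0.5, female = 0.5)),
      seed = 101
    )
    .fixture_env$features_balanced <- suppressMessages(build_feature_table(co))
  }
  .fixture_env$features_balanced
}

# a feature table where one column separates the classes perfectly and the
# rest are noise; used by the search tests
separable_table <- function(n_high = 6, n_low = 14, seed = 5,
                            signal_col = "cop_convex_hull") {
  withr::with_seed(seed, {
    n <- n_high + n_low
    group <- factor(c(rep("High", n_high), rep("Low", n_low)),
                    levels = c("Low", "High"))
    tab <- tibble::tibble(
      participant_id = sprintf("S%02d", seq_len(n)),
      sex = rep(c("male", "female"), length.out = n),
      srs_total = ifelse(group == "High", 70, 30) + rnorm(n),
      group = group
    )
    for (v in category_columns("combined")) tab[[v]] <- rnorm(n)
    tab[[signal_col]] <- ifelse(group == "High", 3, -3) + 0.1 * rnorm(n)
    tab
  })
}

# hand-built keypoint frame: every landmark at the given (x, y) offsets
make_kp_series <- function(xy_list, image_size = c(640L, 480L),
                           px_per_cm = 1, conf = 1, sample_rate = 20) {
  n <- length(xy_list)
  lms <- olst_landmarks()
  coords <- array(NA_real_, dim = c(n, length(lms), 3),
                  dimnames = list(NULL, lms, c("x", "y", "confidence")))
  for (i in seq_len(n)) {
    for (l in lms) {
      coords[i, l, ] <- c(xy_list[[i]][[l]], conf)
    }
  }
  keypoint_series((seq_len(n) - 1) / sample_rate, coords, image_size,
                  px_per_cm)
}

# a static template pose (image coordinates, y down) for kinematics tests
template_pose <- function() {
  list(
    nose = c(320, 120), neck = c(320, 160),
    right_shoulder = c(280, 170), left_shoulder = c(360, 170),
    right_elbow = c(270, 220), left_elbow = c(370, 220),
    right_wrist = c(265, 270), left_wrist = c(375, 270),
    mid_hip = c(320, 260), right_hip = c(295, 262), left_hip = c(345, 262),
    right_knee = c(293, 330), left_knee = c(347, 330),
    right_ankle = c(291, 400), left_ankle = c(349, 400)
  )
}

# pressure series with an explicit list of per-frame sparse cells
make_pressure <- function(frames, grid = c(48L, 48L), pitch = 1,
                          sample_rate = 20) {
  cells <- dplyr::bind_rows(lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    tibble::tibble(frame = i, row = f$row, col = f$col, value = f$value)
  }))
  pressure_series((seq_along(frames) - 1) / sample_rate, cells, grid, pitch)
}

# sensor-frame cell-centre coordinate for a 0-based (row, col)
cell_xy <- function(row, col, grid = c(48L, 48L), pitch = 1) {
  size <- grid[[1]] * pitch
  c((col + 0.5) * pitch - size / 2, size / 2 - (row + 0.5) * pitch)
}

# bare COP trajectory object for direct unit tests of window statistics
make_traj <- function(t, x, y, valid = rep(TRUE, length(t))) {
  structure(
    list(timestamps = t, x = x, y = y, valid = valid,
         ellipse = list(center = c(0, 0), axes = c(major = 1, minor = 1),
                        orientation = pi / 2),
         rotation = 0),
    class = "olst_cop"
  )
}
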
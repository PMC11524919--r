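# Assembly of the 16-variable feature table and the grouping rule.

COP_SWAY_VARS <- c("len_total_path", "m_cop_speed", "cop_entropy",
                   "cop_convex_hull")
BALANCE_VARS <- c("len_max_trial", "com_cop_dist")
CORR_VARS <- paste0("corr_", ANGLE_NAMES)
ALL_FEATURE_VARS <- c(COP_SWAY_VARS, BALANCE_VARS, CORR_VARS)

#' Explanatory-variable categories
#'
#' The 16 explanatory variables fall into three modelling categories:
#' `conventional` (COP sway + overall balance, 6 variables), `proposed`
#' (the 10 COP-joint coupling correlations), and `combined` (all 16).
#'
#' @param category One of `"conventional"`, `"proposed"`, `"combined"`.
#'
#' @return Character vector of feature column names.
#' @export
category_columns <- function(category) {
  if (length(category) != 1L ||
      !category %in% c("conventional", "proposed", "combined")) {
    stop_olst("unknown variable category", "olst_domain_error")
  }
  switch(category,
    conventional = c(COP_SWAY_VARS, BALANCE_VARS),
    proposed = CORR_VARS,
    combined = ALL_FEATURE_VARS
  )
}

#' Assign the High/Low autistic-trait group
#'
#' A participant is in the High group iff their SRS-2 total strictly exceeds
#' the sex-specific screening cutoff (boys 53.5, girls 52.5 by default; the
#' half-point cutoffs make ties impossible for integer scores).
#'
#' @param sex Character vector of `"male"`/`"female"`.
#' @param srs_total Non-negative SRS-2 total scores.
#' @param cutoff_male,cutoff_female Screening cutoffs.
#'
#' @return Factor with levels `Low`, `High`.
#' @export
assign_group <- function(sex, srs_total, cutoff_male = 53.5,
                         cutoff_female = 52.5) {
  if (!all(sex %in% c("male", "female"))) {
    stop_olst("`sex` must be 'male' or 'female'", "olst_domain_error")
  }
  if (any(srs_total < 0)) {
    stop_olst("`srs_total` must be non-negative", "olst_domain_error")
  }
  cut <- ifelse(sex == "male", cutoff_male, cutoff_female)
  factor(ifelse(srs_total > cut, "High", "Low"), levels = c("Low", "High"))
}

#' Extract the 16 explanatory variables for one participant
#'
#' All variables except `len_max_trial` are computed on the initial
#' `window_s` seconds (default 2 s, covering the two-to-one-leg weight-shift
#' transition) of the participant's first trial; `len_max_trial` is the
#' longest stand across all trials. Components that cannot be computed
#' (insufficient valid frames, zero-variance correlations) are returned as
#' `NA`, never imputed.
#'
#' @param participant One row of an `olst_cohort` tibble, or any list with a
#'   `trials` element.
#' @param window_s Length of the analysis window, seconds.
#' @param apen_m,apen_r_frac Approximate-entropy embedding length and
#'   relative tolerance (fraction of the per-axis SD).
#' @param cop_change,corr_method Passed to [cop_joint_correlations()].
#' @param min_valid_frames Minimum number of valid COP frames in the window;
#'   below this all window features are `NA`.
#'
#' @return A one-row tibble with the 16 feature columns.
#' @export
extract_features <- function(participant, window_s = 2,
                             apen_m = 2L, apen_r_frac = 0.2,
                             cop_change = "x", corr_method = "pearson",
                             min_valid_frames = 10L) {
  trials <- if (is.data.frame(participant)) {
    participant$trials[[1L]]
  } else {
    participant$trials
  }
  if (is.null(trials) || length(trials) == 0L) {
    stop_olst("participant has no trials", "olst_insufficient_data_error")
  }
  out <- as.list(setNames(rep(NA_real_, length(ALL_FEATURE_VARS)),
                          ALL_FEATURE_VARS))
  out$len_max_trial <- max_trial_duration(trials)

  tr1 <- trials[[1L]]
  win <- c(0, min(window_s, tr1$duration))
  traj <- tryCatch(
    compute_cop_trajectory(subset_pressure(tr1$pressure, win)),
    olst_empty_trajectory_error = function(e) NULL
  )
  kp <- subset_keypoints(tr1$keypoints, win)
  if (is.null(traj) || sum(traj$valid) < min_valid_frames) {
    rlang::warn("first trial unusable: window features set to missing")
    return(as_tibble(out))
  }

  pm <- sway_path_metrics(traj)
  out$len_total_path <- pm$len_total_path
  out$m_cop_speed <- pm$m_cop_speed
  pts <- window_points(traj)
  out$cop_convex_hull <- convex_hull_area(cbind(pts$x, pts$y))
  apen_axis <- function(v) {
    suppressWarnings(
      approximate_entropy(v, m = apen_m, r = apen_r_frac * sd(v))
    )
  }
  out$cop_entropy <- mean(c(apen_axis(pts$x), apen_axis(pts$y)))
  out$com_cop_dist <- tryCatch(
    com_cop_distance(kp, traj),
    olst_insufficient_data_error = function(e) NA_real_
  )
  ang <- compute_joint_angles(kp)
  cj <- suppressWarnings(
    cop_joint_correlations(ang, traj, cop_change = cop_change,
                           method = corr_method)
  )
  for (i in seq_len(nrow(cj))) {
    out[[paste0("corr_", cj$angle[[i]])]] <- cj$r[[i]]
  }
  as_tibble(out)
}

subset_pressure <- function(series, window) {
  keep <- series$timestamps >= window[[1L]] & series$timestamps < window[[2L]]
  frames <- which(keep)
  cells <- series$cells[series$cells$frame %in% frames, ]
  cells$frame <- match(cells$frame, frames)
  pressure_series(series$timestamps[keep], cells, series$grid_cells,
                  series$cell_pitch)
}

subset_keypoints <- function(kp, window) {
  keep <- kp$timestamps >= window[[1L]] & kp$timestamps < window[[2L]]
  keypoint_series(kp$timestamps[keep], kp$coords[keep, , , drop = FALSE],
                  kp$image_size, kp$px_per_cm)
}

#' Build the feature table for a cohort
#'
#' One row per participant: identifiers, the High/Low group label recomputed
#' from sex and SRS-2 total, and the 16 explanatory variables.
#'
#' @param cohort An `olst_cohort` tibble from [generate_cohort()] or loaded
#'   via [load_cohort()].
#' @param cutoff_male,cutoff_female Screening cutoffs for [assign_group()].
#' @param ... Passed to [extract_features()].
#'
#' @return A tibble of class `olst_features` with columns `participant_id`,
#'   `sex`, `srs_total`, `group`, then the 16 feature columns in their
#'   canonical order.
#' @export
build_feature_table <- function(cohort, cutoff_male = 53.5,
                                cutoff_female = 52.5, ...) {
  if (!is.data.frame(cohort) || nrow(cohort) == 0L) {
    stop_olst("`cohort` must be a non-empty cohort tibble",
              "olst_domain_error")
  }
  feats <- purrr::map(seq_len(nrow(cohort)), function(i) {
    extract_features(list(trials = cohort$trials[[i]]), ...)
  })
  out <- dplyr::bind_cols(
    tibble(
      participant_id = cohort$id,
      sex = cohort$sex,
      srs_total = cohort$srs_total,
      group = assign_group(cohort$sex, cohort$srs_total,
                           cutoff_male, cutoff_female)
    ),
    dplyr::bind_rows(feats)
  )
  class(out) <- c("olst_features", class(out))
  out
}

# rows of a feature table usable for a category; logs the exclusion count
complete_rows <- function(table, columns) {
  ok <- stats::complete.cases(table[, columns, drop = FALSE])
  if (any(!ok)) {
    rlang::inform(sprintf(
      "%d of %d rows excluded for missing values in this category",
      sum(!ok), length(ok)
    ))
  }
  table[ok, , drop = FALSE]
}
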
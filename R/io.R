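# On-disk formats. All text: sparse long CSV for pressure frames, JSON for
# keypoints, CSV for manifests and feature tables, JSON for model reports.
# Pressure rows/cols are 0-based; timestamps are seconds from trial start.

#' Write one trial to disk
#'
#' Emits `<prefix>_pressure.csv` (header `t,row,col,value`, one row per
#' active cell per frame) and `<prefix>_keypoints.json` (an object with
#' `image_size`, `px_per_cm` and a `frames` array of
#' `{"t": s, "people": [{"keypoints": {name: [x, y, c]}}]}`).
#'
#' @param trial A [trial_recording()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#'
#' @return Named character vector with the `pressure` and `keypoints` paths.
#' @export
write_trial <- function(trial, dir, prefix = "trial") {
  stopifnot(inherits(trial, "olst_trial"))
  if (length(trial$pressure$timestamps) == 0L) {
    stop_olst("refusing to write an empty trial", "olst_format_error")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ppath <- file.path(dir, paste0(prefix, "_pressure.csv"))
  kpath <- file.path(dir, paste0(prefix, "_keypoints.json"))

  cells <- trial$pressure$cells
  readr::write_csv(
    tibble(
      t = trial$pressure$timestamps[cells$frame],
      row = cells$row, col = cells$col, value = cells$value
    ),
    ppath
  )

  kp <- trial$keypoints
  frames <- purrr::map(seq_along(kp$timestamps), function(i) {
    pts <- purrr::map(LANDMARKS, function(l) unname(kp$coords[i, l, ]))
    names(pts) <- LANDMARKS
    list(t = kp$timestamps[[i]], people = list(list(keypoints = pts)))
  })
  jsonlite::write_json(
    list(image_size = kp$image_size, px_per_cm = kp$px_per_cm,
         leg = trial$leg, duration = trial$duration, frames = frames),
    kpath, auto_unbox = TRUE, digits = NA
  )
  c(pressure = ppath, keypoints = kpath)
}

read_pressure_csv <- function(path, grid_cells = c(48L, 48L),
                              cell_pitch = 1) {
  if (!file.exists(path)) {
    stop_olst(sprintf("pressure file not found: %s", path), "olst_io_error")
  }
  df <- readr::read_csv(path, col_types = "dddd", progress = FALSE)
  if (!identical(names(df), c("t", "row", "col", "value"))) {
    stop_olst(sprintf("%s: expected header t,row,col,value", path),
              "olst_format_error")
  }
  bad <- which(df$value < 0)
  if (length(bad)) {
    stop_olst(sprintf("%s: negative pressure on data line %d", path,
                      bad[[1L]]),
              "olst_format_error")
  }
  tt <- sort(unique(df$t))
  pressure_series(
    tt,
    tibble(frame = match(df$t, tt), row = as.integer(df$row),
           col = as.integer(df$col), value = df$value),
    grid_cells, cell_pitch
  )
}

read_keypoints_json <- function(path, sample_rate = 20,
                                image_size = c(640L, 480L), px_per_cm = 3) {
  if (!file.exists(path)) {
    stop_olst(sprintf("keypoint file not found: %s", path), "olst_io_error")
  }
  js <- jsonlite::read_json(path)
  if (is.null(names(js))) { # bare array of frames
    frames <- js
  } else {
    frames <- js$frames
    image_size <- unlist(js$image_size) %||% image_size
    px_per_cm <- js$px_per_cm %||% px_per_cm
  }
  n <- length(frames)
  if (n == 0L) {
    stop_olst(sprintf("%s: no frames", path), "olst_format_error")
  }
  tt <- vapply(seq_len(n), function(i) {
    frames[[i]]$t %||% ((i - 1) / sample_rate)
  }, numeric(1))
  coords <- array(NA_real_, dim = c(n, length(LANDMARKS), 3),
                  dimnames = list(NULL, LANDMARKS, c("x", "y", "confidence")))
  for (i in seq_len(n)) {
    pts <- frames[[i]]$people[[1L]]$keypoints
    missing <- setdiff(LANDMARKS, names(pts))
    if (length(missing)) {
      stop_olst(sprintf("%s: frame %d lacks landmark '%s'", path, i,
                        missing[[1L]]),
                "olst_format_error")
    }
    for (l in LANDMARKS) coords[i, l, ] <- unlist(pts[[l]])[1:3]
  }
  keypoint_series(tt, coords, image_size, px_per_cm)
}

#' Load one trial from disk
#'
#' Reads and cross-validates the two recording streams; they must have the
#' same number of frames and matching timestamps.
#'
#' @param pressure_path Path to the sparse pressure CSV.
#' @param keypoints_path Path to the keypoint JSON.
#' @param grid_cells,cell_pitch Sensor geometry of the pressure grid.
#' @param leg Stance leg label (read from the keypoint file when present).
#'
#' @return A [trial_recording()].
#' @export
load_trial <- function(pressure_path, keypoints_path,
                       grid_cells = c(48L, 48L), cell_pitch = 1,
                       leg = NULL) {
  pres <- read_pressure_csv(pressure_path, grid_cells, cell_pitch)
  js <- jsonlite::read_json(keypoints_path)
  kp <- read_keypoints_json(keypoints_path)
  if (length(pres$timestamps) != length(kp$timestamps) ||
      max(abs(pres$timestamps - kp$timestamps)) > 1e-6) {
    stop_olst(sprintf(
      "timestamp mismatch between %s (%d frames) and %s (%d frames)",
      pressure_path, length(pres$timestamps),
      keypoints_path, length(kp$timestamps)
    ), "olst_format_error")
  }
  leg <- leg %||% (if (!is.null(names(js))) js$leg else NULL) %||% "right"
  duration <- (if (!is.null(names(js))) js$duration else NULL) %||%
    (length(pres$timestamps) /
       max(1, round(1 / stats::median(diff(pres$timestamps)))))
  trial_recording(leg, duration, pres, kp)
}

#' Read a directory of OpenPose BODY_25 per-frame JSON files
#'
#' Read-only shim for raw pose-estimator output: one JSON file per frame
#' with `people[[1]]$pose_keypoints_2d` as a flat `[x, y, c]` triplet list.
#' Only the 15 landmarks used by this package are mapped; frame times are
#' the file order divided by `sample_rate`.
#'
#' @param dir Directory of `*_keypoints.json` files.
#' @param sample_rate Frames per second.
#' @param image_size,px_per_cm Calibration metadata.
#'
#' @return A [keypoint_series()].
#' @export
read_openpose_dir <- function(dir, sample_rate = 20,
                              image_size = c(640L, 480L), px_per_cm = 3) {
  body25 <- c(
    nose = 0L, neck = 1L, right_shoulder = 2L, right_elbow = 3L,
    right_wrist = 4L, left_shoulder = 5L, left_elbow = 6L, left_wrist = 7L,
    mid_hip = 8L, right_hip = 9L, right_knee = 10L, right_ankle = 11L,
    left_hip = 12L, left_knee = 13L, left_ankle = 14L
  )
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  if (length(files) == 0L) {
    stop_olst(sprintf("no JSON files in %s", dir), "olst_io_error")
  }
  n <- length(files)
  coords <- array(NA_real_, dim = c(n, length(LANDMARKS), 3),
                  dimnames = list(NULL, LANDMARKS, c("x", "y", "confidence")))
  for (i in seq_len(n)) {
    js <- jsonlite::read_json(files[[i]])
    flat <- unlist(js$people[[1L]]$pose_keypoints_2d)
    for (l in names(body25)) {
      k <- body25[[l]]
      coords[i, l, ] <- flat[(3L * k + 1L):(3L * k + 3L)]
    }
  }
  keypoint_series((seq_len(n) - 1L) / sample_rate, coords, image_size,
                  px_per_cm)
}

manifest_cols <- function(n_trials = 4L) {
  c("participant_id", "sex", "age", "srs_total",
    as.vector(t(outer(paste0("trial", seq_len(n_trials)),
                      c("_pressure", "_keypoints", "_leg"), paste0))))
}

#' Write a cohort to disk
#'
#' Writes one pressure CSV and one keypoint JSON per trial plus a manifest
#' CSV (`participant_id,sex,age,srs_total,trial1_pressure,trial1_keypoints,
#' trial1_leg,...`), with paths relative to the manifest.
#'
#' @param cohort An `olst_cohort` tibble.
#' @param dir Output directory.
#'
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    trials <- cohort$trials[[i]]
    row <- list(participant_id = cohort$id[[i]], sex = cohort$sex[[i]],
                age = cohort$age[[i]], srs_total = cohort$srs_total[[i]])
    for (k in seq_along(trials)) {
      paths <- write_trial(trials[[k]], dir,
                           sprintf("%s_t%d", cohort$id[[i]], k))
      row[[sprintf("trial%d_pressure", k)]] <- basename(paths[["pressure"]])
      row[[sprintf("trial%d_keypoints", k)]] <- basename(paths[["keypoints"]])
      row[[sprintf("trial%d_leg", k)]] <- trials[[k]]$leg
    }
    as_tibble(row)
  })
  manifest <- dplyr::bind_rows(rows)
  mpath <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, mpath)
  invisible(mpath)
}

#' Load and validate a cohort manifest
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every referenced trial file exists.
#'
#' @return A tibble with normalized sex values and one row per participant.
#' @export
load_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) {
    stop_olst(sprintf("manifest not found: %s", path), "olst_io_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  want <- manifest_cols()
  if (!all(want %in% names(df))) {
    stop_olst(sprintf("manifest %s lacks columns: %s", path,
                      paste(setdiff(want, names(df)), collapse = ", ")),
              "olst_format_error")
  }
  if (nrow(df) == 0L) return(as_tibble(df[, want]))
  if (anyDuplicated(df$participant_id)) {
    stop_olst("duplicate participant_id in manifest", "olst_format_error")
  }
  sex <- tolower(as.character(df$sex))
  sex[sex %in% c("m", "boy")] <- "male"
  sex[sex %in% c("f", "girl")] <- "female"
  if (!all(sex %in% c("male", "female"))) {
    stop_olst("manifest sex values outside {male, female}",
              "olst_format_error")
  }
  df$sex <- sex
  if (check_files) {
    base <- dirname(path)
    for (k in 1:4) {
      for (suffix in c("_pressure", "_keypoints")) {
        p <- file.path(base, df[[paste0("trial", k, suffix)]])
        missing <- p[!file.exists(p)]
        if (length(missing)) {
          stop_olst(sprintf("manifest references missing file: %s",
                            missing[[1L]]),
                    "olst_io_error")
        }
      }
    }
  }
  as_tibble(df[, want])
}

#' Load a full cohort from a manifest
#'
#' @param path Manifest CSV path.
#' @param grid_cells,cell_pitch Sensor geometry of the pressure grids.
#'
#' @return An `olst_cohort` tibble (with `severity = NA`, which is latent
#'   and unobservable for real recordings).
#' @export
load_cohort <- function(path, grid_cells = c(48L, 48L), cell_pitch = 1) {
  mf <- load_manifest(path)
  base <- dirname(path)
  trials <- purrr::map(seq_len(nrow(mf)), function(i) {
    purrr::map(1:4, function(k) {
      load_trial(
        file.path(base, mf[[paste0("trial", k, "_pressure")]][[i]]),
        file.path(base, mf[[paste0("trial", k, "_keypoints")]][[i]]),
        grid_cells, cell_pitch,
        leg = mf[[paste0("trial", k, "_leg")]][[i]]
      )
    })
  })
  out <- tibble(
    id = mf$participant_id, sex = mf$sex, age = mf$age,
    srs_total = mf$srs_total, severity = NA_real_, trials = trials
  )
  class(out) <- c("olst_cohort", class(out))
  out
}

#' Write and read the feature-table CSV
#'
#' Fixed column order: identifiers, group, then the 16 explanatory
#' variables.
#'
#' @param table An `olst_features` table.
#' @param path CSV path.
#'
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns an `olst_features` tibble.
#' @export
write_feature_table <- function(table, path) {
  cols <- c("participant_id", "sex", "srs_total", "group", ALL_FEATURE_VARS)
  readr::write_csv(table[, cols], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  df$group <- factor(df$group, levels = c("Low", "High"))
  class(df) <- c("olst_features", class(df))
  df
}

#' Write a model report as JSON
#'
#' Selected variables, cost, per-participant out-of-fold predictions and
#' probabilities, confusion counts, and metrics.
#'
#' @param model An `olst_model`.
#' @param path Output JSON path.
#'
#' @return `path`, invisibly.
#' @export
write_model_report <- function(model, path) {
  jsonlite::write_json(
    list(
      category = model$category, mode = model$mode,
      strategy = model$strategy,
      selected_variables = model$subset, cost = model$cost,
      platt = model$platt,
      predictions = model$predictions,
      confusion = as.list(model$confusion[, c("tp", "fn", "tn", "fp")]),
      metrics = as.list(model$confusion[, c("accuracy", "sensitivity",
                                            "specificity")])
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
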
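# Synthetic OLST cohort generator.
#
# The dynamical model is deliberately the simplest mechanism that realizes
# every group contrast the screening analysis relies on:
#   * COP sway: discretized Ornstein-Uhlenbeck process per axis, mixed with a
#     periodic component whose weight grows with severity (smaller and more
#     regular sway at high severity);
#   * stance failure: exponential fall time with severity-proportional
#     hazard, right-censored at the trial cap;
#   * body motion: a 15-landmark template skeleton whose joint angles respond
#     linearly to mediolateral COP displacement, with gain proportional to
#     severity (the coupling the proposed Corr_* variables measure).

#' Simulate one one-legged standing trial
#'
#' Draws a trial duration, simulates the COP path, renders elliptical
#' footprint pressure frames whose pressure-weighted centroid tracks the
#' simulated COP, and synthesizes skeletal keypoints whose joint angles are
#' linearly coupled to the mediolateral COP coordinate. Uses the current RNG
#' state; [generate_cohort()] provides the seeded entry point.
#'
#' @param severity Latent severity in \[0, 1\].
#' @param leg Stance leg, `"right"` or `"left"`.
#' @param cfg An [olst_config()].
#'
#' @return An [trial_recording()] object.
#' @export
simulate_trial <- function(severity, leg, cfg = olst_config()) {
  if (!is.numeric(severity) || length(severity) != 1L ||
      is.na(severity) || severity < 0 || severity > 1) {
    stop_olst("`severity` must be a single value in [0, 1]",
              "olst_domain_error")
  }
  leg <- match.arg(leg, c("right", "left"))
  eff <- cfg$effect
  rate <- cfg$sample_rate
  dt <- 1 / rate

  # trial duration: exponential fall time after the stance transition,
  # right-censored at the cap
  hazard <- eff$fall_hazard * severity
  t_stand <- if (hazard > 0) cfg$min_stand + rexp(1L, hazard) else Inf
  duration <- min(t_stand, cfg$trial_cap)
  n <- max(round(duration * rate), round(cfg$min_stand * rate), 2L)
  duration <- n / rate
  tt <- (seq_len(n) - 1L) * dt

  # COP sway: OU + periodic mixture with severity-dependent amplitude and
  # regularity, clamped to stay inside the footprint
  sig <- max(eff$sway_sigma_base + eff$sway_sigma * severity, 0.15)
  rho <- min(eff$regularity_gain * severity, 0.95)
  decay <- exp(-eff$ou_theta * dt)
  ou_path <- function(sigma) {
    z <- rnorm(n)
    x <- numeric(n)
    x[1L] <- sigma * z[1L]
    innov <- sigma * sqrt(1 - decay^2)
    for (k in seq_len(n - 1L)) x[k + 1L] <- decay * x[k] + innov * z[k + 1L]
    x
  }
  per <- function(sigma) {
    sqrt(2) * sigma * sin(2 * pi * eff$sway_freq * tt + runif(1L, 0, 2 * pi))
  }
  ax <- eff$footprint_axes[[1L]]
  ay <- eff$footprint_axes[[2L]]
  sway_x <- sqrt(1 - rho^2) * ou_path(sig) + rho * per(sig)
  sway_y <- sqrt(1 - rho^2) * ou_path(sig * eff$ap_scale) +
    rho * per(sig * eff$ap_scale)
  sway_x <- pmin(pmax(sway_x, -0.45 * ax), 0.45 * ax)
  sway_y <- pmin(pmax(sway_y, -0.30 * ay), 0.30 * ay)

  # feet 8 cm apart around the mat centre; weight shifts onto the stance
  # foot over the ramp
  side <- if (leg == "right") 1 else -1
  foot_stance <- c(4 * side, 0)
  foot_lift <- c(-4 * side, 0)
  lam <- if (cfg$ramp > 0) pmax(1 - tt / cfg$ramp, 0) else rep(0, n)
  m_lift <- 0.5 * lam
  m_stance <- 1 - m_lift
  cs_x <- foot_stance[[1L]] + sway_x
  cs_y <- foot_stance[[2L]] + sway_y
  cop_x <- m_stance * cs_x + m_lift * foot_lift[[1L]]
  cop_y <- m_stance * cs_y + m_lift * foot_lift[[2L]]

  cells <- render_pressure(cs_x, cs_y, m_stance, foot_lift, m_lift, cfg)
  pres <- pressure_series(tt, cells, cfg$grid_cells, cfg$cell_pitch)
  kp <- synth_keypoints(cop_x, tt, severity, leg, cfg)
  trial_recording(leg, duration, pres, kp)
}

# Rasterize the two footprint blobs on the sensor grid. Each blob is an
# Epanechnikov-tapered ellipse, so its continuous centroid is its centre;
# per-frame blob masses are normalized so the frame centroid equals the
# analytic COP up to discretization.
render_pressure <- function(cs_x, cs_y, m_stance, foot_lift, m_lift, cfg) {
  eff <- cfg$effect
  ax <- eff$footprint_axes[[1L]]
  ay <- eff$footprint_axes[[2L]]
  pitch <- cfg$cell_pitch
  half <- cfg$sensor_size / 2
  n <- length(cs_x)
  scale_units <- 500 # arbitrary pressure units per unit body weight

  blob_cells <- function(cx_range, cy_range) {
    cols <- seq(floor((cx_range[1] - ax + half) / pitch),
                ceiling((cx_range[2] + ax + half) / pitch - 1))
    rows <- seq(floor((half - (cy_range[2] + ay)) / pitch),
                ceiling((half - (cy_range[1] - ay)) / pitch - 1))
    cols <- cols[cols >= 0 & cols < cfg$grid_cells[[2L]]]
    rows <- rows[rows >= 0 & rows < cfg$grid_cells[[1L]]]
    grid <- expand.grid(row = rows, col = cols)
    ctr <- cell_centers(grid$row, grid$col, cfg$grid_cells, pitch,
                        cfg$sensor_size)
    list(row = grid$row, col = grid$col, x = ctr$x, y = ctr$y)
  }

  # stance blob: K cells x n frames density matrix
  st <- blob_cells(range(cs_x), range(cs_y))
  K <- length(st$x)
  dxr <- outer(st$x, cs_x, "-") / ax
  dyr <- outer(st$y, cs_y, "-") / ay
  dens <- pmax(1 - dxr^2 - dyr^2, 0)
  tot <- colSums(dens)
  tot[tot == 0] <- 1
  dens <- dens * rep(m_stance * scale_units / tot, each = K)
  idx <- which(dens > 0)
  cell <- (idx - 1L) %% K + 1L
  frame <- (idx - 1L) %/% K + 1L
  row <- st$row[cell]
  col <- st$col[cell]
  value <- dens[idx]

  ramp_frames <- which(m_lift > 0)
  if (length(ramp_frames)) {
    lf <- blob_cells(rep(foot_lift[[1L]], 2), rep(foot_lift[[2L]], 2))
    d <- pmax(1 - ((lf$x - foot_lift[[1L]]) / ax)^2 -
                ((lf$y - foot_lift[[2L]]) / ay)^2, 0)
    keep <- d > 0
    d <- d[keep] / sum(d[keep])
    nk <- sum(keep)
    frame <- c(frame, rep(ramp_frames, each = nk))
    row <- c(row, rep(lf$row[keep], length(ramp_frames)))
    col <- c(col, rep(lf$col[keep], length(ramp_frames)))
    value <- c(value, as.numeric(outer(d, m_lift[ramp_frames] *
                                         scale_units)))
  }
  ord <- order(frame, row, col)
  tibble::new_tibble(
    list(frame = frame[ord], row = row[ord], col = col[ord],
         value = value[ord]),
    nrow = length(ord)
  )
}

# AR(1) noise path with innovation SD `s`
ar1 <- function(n, s, phi = 0.9) {
  if (s <= 0) return(numeric(n))
  e <- numeric(n)
  z <- rnorm(n, sd = s)
  e[1L] <- z[1L] / sqrt(1 - phi^2)
  for (k in seq_len(n - 1L)) e[k + 1L] <- phi * e[k] + z[k + 1L]
  e
}

# Template skeleton (cm, y up from the ground) driven by the mediolateral COP
# coordinate. Per-joint gains emphasize proximal joints (shoulder, trunk,
# hip), consistent with the feed-forward weight-shift strategy the coupling
# features are meant to capture.
synth_keypoints <- function(cop_x, tt, severity, leg, cfg) {
  eff <- cfg$effect
  n <- length(tt)
  drive <- eff$coupling_beta * severity * (cop_x - mean(cop_x)) # degrees
  ns <- eff$angle_noise
  d2r <- pi / 180

  phi_t <- (2 + 1.0 * drive + ar1(n, ns)) * d2r    # trunk tilt from vertical
  phi_p <- (0 + 0.7 * drive + ar1(n, ns)) * d2r    # pelvis tilt
  # 8-degree habitual head tilt keeps the neck line clear of the vertical
  # inclination fold, so its coupling stays identifiable
  phi_n <- (8 + 0.6 * drive + ar1(n, ns)) * d2r    # neck, relative to trunk
  psi_s <- (0 + 1.2 * drive + ar1(n, ns)) * d2r    # shoulder-line tilt
  a_relb <- pmin(pmax(160 + 0.4 * drive + ar1(n, ns), 30), 179) * d2r
  a_lelb <- pmin(pmax(160 - 0.4 * drive + ar1(n, ns), 30), 179) * d2r
  tau_st <- (0 + 1.0 * drive + ar1(n, ns)) * d2r   # stance thigh tilt
  kap_st <- pmin(pmax(175 + 0.8 * drive + ar1(n, ns), 90), 179.5) * d2r
  tau_lf <- (20 + 1.0 * drive + ar1(n, ns)) * d2r  # lifted thigh tilt
  kap_lf <- pmin(pmax(120 + 0.8 * drive + ar1(n, ns), 30), 179) * d2r

  rot <- function(vx, vy, a) {
    list(x = cos(a) * vx - sin(a) * vy, y = sin(a) * vx + cos(a) * vy)
  }
  P <- array(NA_real_, dim = c(n, length(LANDMARKS), 2),
             dimnames = list(NULL, LANDMARKS, c("x", "y")))
  set_lm <- function(name, x, y) {
    P[, name, 1] <<- x
    P[, name, 2] <<- y
  }

  hip_y <- 55
  mh_x <- 0.8 * cop_x
  set_lm("mid_hip", mh_x, rep(hip_y, n))
  set_lm("right_hip", mh_x + 8 * cos(phi_p), hip_y + 8 * sin(phi_p))
  set_lm("left_hip", mh_x - 8 * cos(phi_p), hip_y - 8 * sin(phi_p))
  neck_x <- mh_x + 33 * sin(phi_t)
  neck_y <- hip_y + 33 * cos(phi_t)
  set_lm("neck", neck_x, neck_y)
  set_lm("nose", neck_x + 12 * sin(phi_t + phi_n),
         neck_y + 12 * cos(phi_t + phi_n))
  shc_x <- mh_x + 29 * sin(phi_t)
  shc_y <- hip_y + 29 * cos(phi_t)
  set_lm("right_shoulder", shc_x + 15 * cos(psi_s), shc_y + 15 * sin(psi_s))
  set_lm("left_shoulder", shc_x - 15 * cos(psi_s), shc_y - 15 * sin(psi_s))

  for (s in c("right", "left")) {
    sgn <- if (s == "right") 1 else -1
    sh_x <- P[, paste0(s, "_shoulder"), 1]
    sh_y <- P[, paste0(s, "_shoulder"), 2]
    delta <- sgn * 12 * d2r
    el_x <- sh_x + 17 * sin(delta)
    el_y <- sh_y - 17 * cos(delta)
    set_lm(paste0(s, "_elbow"), el_x, el_y)
    ux <- (sh_x - el_x) / 17
    uy <- (sh_y - el_y) / 17
    alpha <- if (s == "right") a_relb else a_lelb
    fa <- rot(ux, uy, -sgn * alpha)
    set_lm(paste0(s, "_wrist"), el_x + 15 * fa$x, el_y + 15 * fa$y)

    stance <- s == leg
    tau <- if (stance) tau_st else -sgn * tau_lf
    kap <- if (stance) kap_st else kap_lf
    hx <- P[, paste0(s, "_hip"), 1]
    hy <- P[, paste0(s, "_hip"), 2]
    kn_x <- hx + 25 * sin(tau)
    kn_y <- hy - 25 * cos(tau)
    set_lm(paste0(s, "_knee"), kn_x, kn_y)
    ux <- (hx - kn_x) / 25
    uy <- (hy - kn_y) / 25
    sh_rot <- rot(ux, uy, sgn * kap)
    set_lm(paste0(s, "_ankle"), kn_x + 25 * sh_rot$x, kn_y + 25 * sh_rot$y)
  }

  # cm (y up) -> image px (y down), plus measurement jitter
  ppc <- cfg$px_per_cm
  x_px <- cfg$image_size[[1L]] / 2 + P[, , 1] * ppc
  y_px <- (cfg$image_size[[2L]] - 30) - P[, , 2] * ppc
  if (eff$jitter_px > 0) {
    x_px <- x_px + rnorm(length(x_px), sd = eff$jitter_px)
    y_px <- y_px + rnorm(length(y_px), sd = eff$jitter_px)
  }
  coords <- array(NA_real_, dim = c(n, length(LANDMARKS), 3),
                  dimnames = list(NULL, LANDMARKS, c("x", "y", "confidence")))
  coords[, , 1] <- x_px
  coords[, , 2] <- y_px
  coords[, , 3] <- runif(n * length(LANDMARKS), 0.6, 1)
  keypoint_series(tt, coords, cfg$image_size, cfg$px_per_cm)
}

# truncated-normal SRS draw by rejection, rounded to integer scores
draw_srs <- function(n, mean, sd, cutoff, side) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (tries in 1:10000) {
      x <- rnorm(1L, mean, sd)
      keep <- if (side == "high") x > cutoff else (x >= 0 && x < cutoff)
      if (keep) break
    }
    out[i] <- round(x)
  }
  out
}

#' Generate a synthetic OLST cohort
#'
#' Deterministically (for a fixed config and seed) generates a cohort of
#' participants: sex-specific high/low group assignment, SRS-2 totals drawn
#' from group-wise normals truncated at the sex cutoff, latent severity equal
#' to the within-cohort SRS percentile, and `n_trials` recordings per child
#' with legs alternating right/left starting on the right.
#'
#' @param cfg An [olst_config()].
#' @param seed Integer seed; defaults to `cfg$seed`.
#'
#' @return A tibble of class `olst_cohort` with columns `id`, `sex`, `age`,
#'   `srs_total`, `severity` and a `trials` list-column of
#'   [trial_recording()] lists.
#' @export
#' @examples
#' cfg <- olst_config(n_boys = 2, n_girls = 2, trial_cap = 4)
#' cohort <- generate_cohort(cfg, seed = 1)
#' cohort$trials[[1]][[1]]$leg
generate_cohort <- function(cfg = olst_config(), seed = cfg$seed) {
  if (!inherits(cfg, "olst_config")) {
    stop_olst("`cfg` must be an olst_config()", "olst_config_error")
  }
  withr::with_seed(seed, {
    n <- cfg$n_boys + cfg$n_girls
    sex <- c(rep("male", cfg$n_boys), rep("female", cfg$n_girls))
    cutoff <- ifelse(sex == "male", cfg$cutoff_male, cfg$cutoff_female)
    high <- runif(n) < cfg$high_frac[ifelse(sex == "male", "male", "female")]
    srs <- numeric(n)
    for (i in seq_len(n)) {
      srs[i] <- if (high[i]) {
        draw_srs(1L, cfg$srs_mean_high, cfg$srs_sd_high, cutoff[i], "high")
      } else {
        draw_srs(1L, cfg$srs_mean_low, cfg$srs_sd_low, cutoff[i], "low")
      }
    }
    age_mean <- ifelse(high, 5.13, 5.06)
    age_sd <- ifelse(high, 0.16, 0.13)
    age <- pmin(pmax(rnorm(n, age_mean, age_sd), 4.5), 6)
    severity <- (rank(srs, ties.method = "average") - 0.5) / n
    legs <- rep(c("right", "left"), length.out = cfg$n_trials)
    trials <- lapply(seq_len(n), function(i) {
      lapply(legs, function(l) simulate_trial(severity[i], l, cfg))
    })
    out <- tibble(
      id = sprintf("P%03d", seq_len(n)),
      sex = sex,
      age = round(age, 2),
      srs_total = srs,
      severity = severity,
      trials = trials
    )
    class(out) <- c("olst_cohort", class(out))
    out
  })
}
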
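#' Severity-effect parameters of the synthetic cohort generator
#'
#' Collects the dials through which latent autistic-trait severity (a value in
#' \[0, 1\], the within-cohort SRS-2 percentile) shapes the simulated balance
#' dynamics. The defaults are the documented "strong effect" study conditions:
#' higher severity produces smaller, more periodic (lower-entropy) sway, a
#' stronger linear coupling between joint angles and mediolateral COP motion,
#' and a shorter time to failure of the one-legged stance.
#'
#' @param sway_sigma_base Stationary mediolateral sway SD at severity 0, in cm.
#' @param sway_sigma Change in sway SD per unit severity, in cm. Negative:
#'   higher severity gives smaller centre-of-pressure excursions.
#' @param regularity_gain Dimensionless mixing weight of a periodic sway
#'   component; at severity `s` the COP path is
#'   `sqrt(1 - rho^2) * OU + rho * sine` with
#'   `rho = min(regularity_gain * s, 0.95)`, so higher severity means more
#'   repetitive, lower-entropy sway.
#' @param coupling_beta Joint-angle response to mediolateral COP displacement,
#'   in degrees per cm per unit severity.
#' @param fall_hazard Exponential fall hazard per unit severity, in 1/s; trial
#'   durations are right-censored at the trial cap.
#' @param ou_theta Mean-reversion rate of the Ornstein-Uhlenbeck sway process,
#'   in 1/s.
#' @param footprint_axes Semi-axes (mediolateral, anteroposterior) of the
#'   elliptical footprint, in cm.
#' @param sway_freq Frequency of the periodic sway component, in Hz.
#' @param ap_scale Anteroposterior-to-mediolateral sway SD ratio.
#' @param angle_noise Innovation SD of the AR(1) joint-angle noise, degrees.
#' @param jitter_px Isotropic keypoint position jitter SD, in pixels.
#'
#' @return A list of class `olst_effect`.
#' @seealso [olst_config()], [severity_effect_null()]
#' @export
severity_effect <- function(sway_sigma_base = 1.1,
                            sway_sigma = -0.7,
                            regularity_gain = 0.9,
                            coupling_beta = 8,
                            fall_hazard = 0.12,
                            ou_theta = 1,
                            footprint_axes = c(3, 8.5),
                            sway_freq = 0.9,
                            ap_scale = 1.3,
                            angle_noise = 0.4,
                            jitter_px = 0.3) {
  check_number(sway_sigma_base, "sway_sigma_base", lower = 0, strict_lower = TRUE)
  check_number(fall_hazard, "fall_hazard", lower = 0)
  check_number(ou_theta, "ou_theta", lower = 0, strict_lower = TRUE)
  check_number(regularity_gain, "regularity_gain", lower = 0)
  check_number(sway_freq, "sway_freq", lower = 0, strict_lower = TRUE)
  check_number(angle_noise, "angle_noise", lower = 0)
  check_number(jitter_px, "jitter_px", lower = 0)
  if (length(footprint_axes) != 2L || any(footprint_axes <= 0)) {
    stop_olst("`footprint_axes` must be two positive semi-axis lengths (cm)",
              "olst_config_error")
  }
  structure(
    list(
      sway_sigma_base = sway_sigma_base, sway_sigma = sway_sigma,
      regularity_gain = regularity_gain, coupling_beta = coupling_beta,
      fall_hazard = fall_hazard, ou_theta = ou_theta,
      footprint_axes = as.numeric(footprint_axes), sway_freq = sway_freq,
      ap_scale = ap_scale, angle_noise = angle_noise, jitter_px = jitter_px
    ),
    class = "olst_effect"
  )
}

#' Null severity effect
#'
#' Severity-effect settings with every severity-dependent dial zeroed, so the
#' generated features carry no class signal. Used for calibration checks of
#' the model-selection machinery on null data.
#'
#' @return A list of class `olst_effect`.
#' @export
severity_effect_null <- function() {
  severity_effect(sway_sigma = 0, regularity_gain = 0,
                  coupling_beta = 0, fall_hazard = 0)
}

#' Configuration of the synthetic OLST cohort
#'
#' The defaults reproduce the study protocol: 64 boys and 62 girls, four
#' one-legged standing trials per child alternating right/left starting on the
#' right, trials capped at 20 s, pressure and keypoints synchronously sampled
#' at 20 Hz on a 48-cm square mat, SRS-2 totals drawn per group from truncated
#' normals (high: mean 69.79, SD 23.66; low: mean 31.24, SD 11.48) split at
#' sex-specific screening cutoffs (boys 53.5, girls 52.5), and high-group
#' fractions of 9/64 (boys) and 10/62 (girls).
#'
#' @param n_boys,n_girls Number of participants per sex.
#' @param high_frac Named probabilities (`male`, `female`) of belonging to the
#'   high autistic trait group.
#' @param srs_mean_high,srs_sd_high,srs_mean_low,srs_sd_low Group-wise SRS-2
#'   total score distribution parameters before truncation at the cutoff.
#' @param cutoff_male,cutoff_female Sex-specific SRS-2 screening cutoffs; a
#'   child is in the high group iff their total strictly exceeds the cutoff.
#' @param sample_rate Sampling rate of both recording streams, Hz.
#' @param trial_cap Maximum trial duration, seconds.
#' @param n_trials Trials per participant.
#' @param grid_cells Pressure-grid dimensions (rows, cols); at least 8 x 8.
#' @param sensor_size Side length of the square pressure mat, cm.
#' @param ramp Duration of the two-foot to one-foot weight-shift ramp at the
#'   start of each trial, seconds.
#' @param min_stand Minimum stand duration, seconds: falls cannot occur before
#'   the stance transition completes, so the 2-s feature window always exists.
#' @param image_size Camera frame size (width, height), pixels.
#' @param px_per_cm Image calibration scale, pixels per cm.
#' @param effect A [severity_effect()] object.
#' @param seed Default integer seed used by [generate_cohort()].
#'
#' @return A list of class `olst_config`.
#' @export
olst_config <- function(n_boys = 64, n_girls = 62,
                        high_frac = c(male = 9 / 64, female = 10 / 62),
                        srs_mean_high = 69.79, srs_sd_high = 23.66,
                        srs_mean_low = 31.24, srs_sd_low = 11.48,
                        cutoff_male = 53.5, cutoff_female = 52.5,
                        sample_rate = 20, trial_cap = 20, n_trials = 4,
                        grid_cells = c(48, 48), sensor_size = 48,
                        ramp = 0.5, min_stand = 2,
                        image_size = c(640, 480), px_per_cm = 3,
                        effect = severity_effect(), seed = 1L) {
  check_number(n_boys, "n_boys", lower = 1)
  check_number(n_girls, "n_girls", lower = 1)
  check_number(sample_rate, "sample_rate", lower = 0, strict_lower = TRUE)
  check_number(trial_cap, "trial_cap", lower = 0, strict_lower = TRUE)
  check_number(n_trials, "n_trials", lower = 1)
  check_number(sensor_size, "sensor_size", lower = 0, strict_lower = TRUE)
  check_number(ramp, "ramp", lower = 0)
  check_number(min_stand, "min_stand", lower = 0)
  if (length(grid_cells) != 2L || any(grid_cells < 8)) {
    stop_olst("`grid_cells` must give at least an 8 x 8 grid",
              "olst_config_error")
  }
  if (!all(c("male", "female") %in% names(high_frac)) ||
      any(high_frac < 0) || any(high_frac > 1)) {
    stop_olst("`high_frac` must be probabilities named 'male' and 'female'",
              "olst_config_error")
  }
  if (!inherits(effect, "olst_effect")) {
    stop_olst("`effect` must be created by severity_effect()",
              "olst_config_error")
  }
  pitch <- sensor_size / max(grid_cells)
  if (any(2 * effect$footprint_axes > sensor_size)) {
    stop_olst("footprint does not fit within the sensor", "olst_config_error")
  }
  if (min_stand > trial_cap) {
    stop_olst("`min_stand` cannot exceed `trial_cap`", "olst_config_error")
  }
  structure(
    list(
      n_boys = as.integer(n_boys), n_girls = as.integer(n_girls),
      high_frac = high_frac,
      srs_mean_high = srs_mean_high, srs_sd_high = srs_sd_high,
      srs_mean_low = srs_mean_low, srs_sd_low = srs_sd_low,
      cutoff_male = cutoff_male, cutoff_female = cutoff_female,
      sample_rate = sample_rate, trial_cap = trial_cap,
      n_trials = as.integer(n_trials),
      grid_cells = as.integer(grid_cells), sensor_size = sensor_size,
      cell_pitch = pitch, ramp = ramp, min_stand = min_stand,
      image_size = as.integer(image_size), px_per_cm = px_per_cm,
      effect = effect, seed = as.integer(seed)
    ),
    class = "olst_config"
  )
}

#' Default study-protocol configuration
#'
#' Convenience wrapper returning [olst_config()] with all defaults (the study
#' protocol and the documented strong severity effects).
#'
#' @return A list of class `olst_config`.
#' @export
default_config <- function() olst_config()
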
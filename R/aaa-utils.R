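# internal helpers shared across modules

LANDMARKS <- c(
  "nose", "neck", "right_shoulder", "left_shoulder",
  "right_elbow", "left_elbow", "right_wrist", "left_wrist",
  "mid_hip", "right_hip", "left_hip",
  "right_knee", "left_knee", "right_ankle", "left_ankle"
)

ANGLE_NAMES <- c(
  "neck", "shoulder", "right_elbow", "left_elbow",
  "right_trunk", "left_trunk", "right_hip", "left_hip",
  "right_knee", "left_knee"
)

stop_olst <- function(msg, class) {
  rlang::abort(msg, class = c(class, "olst_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_olst(sprintf("`%s` must be a single finite number", name),
              "olst_config_error")
  }
  bad <- if (strict_lower) x <= lower else x < lower
  if (bad || x > upper) {
    stop_olst(sprintf("`%s` = %g is outside its allowed range", name, x),
              "olst_config_error")
  }
  invisible(x)
}

# wrap a line-direction angle (degrees) into (-90, 90]
wrap_inclination <- function(a) {
  a <- a %% 180
  ifelse(a > 90, a - 180, a)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
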
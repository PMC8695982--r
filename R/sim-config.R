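#' Simulator configuration
#'
#' Builds the configuration object for the virtual wave-surfing simulator.
#' The defaults reproduce the task constants of the study environment: an
#' acceleration gain of 0.17 m.u./(s^2 deg) capped at 20 m.u./s^2, a
#' joystick-to-torque gain of 0.27 N m.u./deg with mechanical joystick limits
#' of +/-15 deg, wave directions drawn from 60 to 120 deg in 5 deg steps,
#' 36 incoming waves per session, and kinematics sampled at 50 Hz.
#'
#' Quantities whose values the rendered game engine supplied implicitly
#' (wave slope envelope, drag) are explicit parameters here: the boat pitch
#' follows a raised-cosine wave-slope envelope scaled by alignment, and both
#' translation and rotation are damped by first-order linear drag.
#'
#' @param accel_gain_cs Acceleration gain, m.u./(s^2 deg). Default 0.17.
#' @param accel_cap Acceleration cap, m.u./s^2. Default 20.
#' @param torque_gain_cR Joystick-to-torque gain, N m.u./deg. Default 0.27.
#' @param joystick_limit Symmetric mechanical joystick bound, deg. Default 15.
#' @param wave_dir_min,wave_dir_max,wave_dir_step Admissible wave directions
#'   (deg w.r.t. the global x axis): the set `seq(min, max, by = step)`.
#' @param trials_per_session Incoming waves per session. Default 36.
#' @param sample_rate Kinematics sampling rate, Hz. Default 50.
#' @param pitch_peak Pitch reached by a perfectly aligned boat at the wave
#'   crest, deg. Default 60.
#' @param wave_envelope_duration Duration of the raised-cosine wave-slope
#'   envelope, s. Default 8.
#' @param translational_drag First-order translational drag, 1/s. Default 0.35.
#' @param rotational_drag First-order rotational drag on yaw rate, 1/s.
#'   Default 2.
#' @param decel_mode How the out-of-range pitch branch of the acceleration
#'   update is evaluated: `"literal"` (the printed form
#'   `a - 5*cs*phi + 2`, default) or `"monotone"` (`a - (5*cs*phi + 2)`,
#'   a strictly decelerating reading). Outputs are clamped to
#'   `[0, accel_cap]` in both modes.
#' @param turn_gain Yaw angular acceleration per unit steering torque,
#'   deg/s^2 per N m.u. Default 30.
#' @param initial_speed Boat speed at trial start, m.u./s. Default 5.
#' @param trial_lead_in Seconds simulated before the wave envelope starts.
#'   Default 1.
#' @param trial_duration Total simulated trial length, s. Default 11 (lead-in
#'   plus envelope plus tail, enough to cover the obstacle-task window).
#' @param seed Optional integer seed recorded in the config.
#'
#' @return A list of class `surf_config`.
#' @export
#' @examples
#' cfg <- sim_config()
#' cfg$accel_gain_cs
sim_config <- function(accel_gain_cs = 0.17,
                       accel_cap = 20,
                       torque_gain_cR = 0.27,
                       joystick_limit = 15,
                       wave_dir_min = 60,
                       wave_dir_max = 120,
                       wave_dir_step = 5,
                       trials_per_session = 36,
                       sample_rate = 50,
                       pitch_peak = 60,
                       wave_envelope_duration = 8,
                       translational_drag = 0.35,
                       rotational_drag = 2,
                       decel_mode = c("literal", "monotone"),
                       turn_gain = 30,
                       initial_speed = 5,
                       trial_lead_in = 1,
                       trial_duration = 11,
                       seed = NULL) {
  decel_mode <- match.arg(decel_mode)
  cfg <- list(
    accel_gain_cs = accel_gain_cs, accel_cap = accel_cap,
    torque_gain_cR = torque_gain_cR, joystick_limit = joystick_limit,
    wave_dir_min = wave_dir_min, wave_dir_max = wave_dir_max,
    wave_dir_step = wave_dir_step, trials_per_session = trials_per_session,
    sample_rate = sample_rate, pitch_peak = pitch_peak,
    wave_envelope_duration = wave_envelope_duration,
    translational_drag = translational_drag,
    rotational_drag = rotational_drag, decel_mode = decel_mode,
    turn_gain = turn_gain, initial_speed = initial_speed,
    trial_lead_in = trial_lead_in, trial_duration = trial_duration,
    seed = seed
  )
  class(cfg) <- "surf_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "surf_config"))
  num_pos <- c(
    "accel_gain_cs", "accel_cap", "wave_dir_step", "sample_rate",
    "pitch_peak", "wave_envelope_duration", "turn_gain", "trial_duration"
  )
  for (f in num_pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(paste0("`", f, "` must be a single positive number."),
        class = "alphasurf_config_error"
      )
    }
  }
  if (cfg$wave_dir_min >= cfg$wave_dir_max) {
    abort("`wave_dir_min` must be below `wave_dir_max`.",
      class = "alphasurf_config_error"
    )
  }
  if (cfg$translational_drag < 0 || cfg$rotational_drag < 0) {
    abort("drag coefficients must be non-negative.",
      class = "alphasurf_config_error"
    )
  }
  if (cfg$trials_per_session < 1) {
    abort("`trials_per_session` must be at least 1.",
      class = "alphasurf_config_error"
    )
  }
  cfg
}

#' @export
print.surf_config <- function(x, ...) {
  cat("<surf_config>\n")
  cat(sprintf(
    "  accel: gain %.3g, cap %.3g (decel_mode: %s)\n",
    x$accel_gain_cs, x$accel_cap, x$decel_mode
  ))
  cat(sprintf(
    "  steering: torque gain %.3g, joystick limit +/-%g deg\n",
    x$torque_gain_cR, x$joystick_limit
  ))
  cat(sprintf(
    "  waves: directions %g..%g by %g deg, %d per session\n",
    x$wave_dir_min, x$wave_dir_max, x$wave_dir_step, x$trials_per_session
  ))
  cat(sprintf(
    "  sampling: %g Hz, trial %g s (lead-in %g s, envelope %g s)\n",
    x$sample_rate, x$trial_duration, x$trial_lead_in,
    x$wave_envelope_duration
  ))
  invisible(x)
}

# wrap an angle difference to (-180, 180]
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

# absolute alignment error folded to [0, 180]
fold_beta <- function(beta) {
  abs(wrap180(beta))
}
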
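# shared fixtures: all built in code at test time

default_cfg <- sim_config()

# a wave event tibble row with full control
wave_row <- function(omega = 90, onset_time = 1, duration = 8, peak = 1,
                     trial = 1L) {
  tibble::tibble(
    trial = trial, onset_time = onset_time, direction_omega = omega,
    env_peak = peak, env_duration = duration
  )
}

# uniform single-trial log with constant channels, onset at sample 1
constant_log <- function(n = 400, rate = 50, vel_x = 0, vel_y = 0,
                         pos_y_rate = NULL, gamma = 0, omega = 90,
                         heading = 90) {
  time <- (seq_len(n) - 1) / rate
  vy <- if (is.null(pos_y_rate)) vel_y else pos_y_rate
  tibble::tibble(
    trial = 1L,
    time = time,
    pos_x = 0,
    pos_y = cumsum(rep(vy / rate, n)) - vy / rate,
    vel_x = vel_x,
    vel_y = vy,
    heading_alpha = heading,
    pitch_phi = 0,
    accel_aw = 0,
    joystick_gamma = gamma,
    wave_dir_omega = omega
  )
}

onset_event <- function(sample = 1L, trial = 1L) {
  tibble::tibble(trial = trial, sample = sample, label = "onset")
}

# small EEG configuration used across the EEG-side tests
small_eeg_cfg <- function(...) {
  args <- utils::modifyList(
    list(
      subjects_per_group = 2, trials_per_cell = 4,
      n_electrodes = 16, fs = 100
    ),
    list(...)
  )
  do.call(synth_eeg_config, args)
}

# independent brute-force evaluator of the four-branch acceleration update
accel_oracle <- function(a_prev, phi, cs = 0.17, cap = 20,
                         mode = "literal") {
  out <- numeric(length(a_prev))
  for (i in seq_along(a_prev)) {
    a <- a_prev[i]
    p <- phi[i]
    val <- if (p >= 15 && p <= 90) {
      if (a < cap) a + cs * p + 0.1 else cap
    } else {
      if (a > 0) {
        if (mode == "literal") a - 5 * cs * p + 2 else a - (5 * cs * p + 2)
      } else {
        0
      }
    }
    out[i] <- min(max(val, 0), cap)
  }
  out
}
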
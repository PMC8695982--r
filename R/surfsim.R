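#' Per-step boat acceleration update
#'
#' Applies the four-branch per-iteration update of the boat forward
#' acceleration as a function of the current pitch angle. With gain
#' `cs = accel_gain_cs` and pitch `phi`:
#'
#' * `phi` in \[15, 90\] deg and `a_prev` below the cap: `a_prev + cs*phi + 0.1`
#' * `phi` in \[15, 90\] deg and `a_prev` at or above the cap: the cap
#' * `phi` outside \[15, 90\] deg and `a_prev > 0`: `a_prev - 5*cs*phi + 2`
#'   (`decel_mode = "literal"`) or `a_prev - (5*cs*phi + 2)`
#'   (`decel_mode = "monotone"`)
#' * `phi` outside \[15, 90\] deg and `a_prev <= 0`: 0
#'
#' The result is clamped to `[0, accel_cap]`. Vectorized over `a_prev` and
#' `phi` (recycled to a common length).
#'
#' @param a_prev Previous acceleration, m.u./s^2.
#' @param phi Boat pitch angle, deg.
#' @param cfg A [sim_config()].
#' @return Updated acceleration, m.u./s^2, same length as the inputs.
#' @export
#' @examples
#' accel_update(5, 30, sim_config()) # 5 + 0.17*30 + 0.1
accel_update <- function(a_prev, phi, cfg = sim_config()) {
  if (!is.numeric(a_prev) || !is.numeric(phi) ||
    any(!is.finite(a_prev)) || any(!is.finite(phi))) {
    abort("`a_prev` and `phi` must be finite numerics.",
      class = "alphasurf_input_error"
    )
  }
  n <- max(length(a_prev), length(phi))
  a_prev <- rep_len(a_prev, n)
  phi <- rep_len(phi, n)
  cs <- cfg$accel_gain_cs
  cap <- cfg$accel_cap
  in_range <- phi >= 15 & phi <= 90
  out <- numeric(n)
  b1 <- in_range & a_prev < cap
  b2 <- in_range & a_prev >= cap
  b3 <- !in_range & a_prev > 0
  out[b1] <- a_prev[b1] + cs * phi[b1] + 0.1
  out[b2] <- cap
  if (identical(cfg$decel_mode, "literal")) {
    out[b3] <- a_prev[b3] - 5 * cs * phi[b3] + 2
  } else {
    out[b3] <- a_prev[b3] - (5 * cs * phi[b3] + 2)
  }
  pmin(pmax(out, 0), cap)
}

#' Joystick angle to steering torque
#'
#' Maps the joystick rotation about its vertical axis to a signed steering
#' torque about the boat yaw axis, `torque = gamma_z * cR`. Joystick angles
#' beyond the mechanical limit are clamped with a warning.
#'
#' @param gamma_z Joystick angle, deg (signed).
#' @param cfg A [sim_config()].
#' @return Signed torque, N m.u.; vectorized.
#' @export
#' @examples
#' steering_torque(15, sim_config()) # 4.05
steering_torque <- function(gamma_z, cfg = sim_config()) {
  if (!is.numeric(gamma_z) || any(!is.finite(gamma_z))) {
    abort("`gamma_z` must be finite numeric.", class = "alphasurf_input_error")
  }
  lim <- cfg$joystick_limit
  if (any(abs(gamma_z) > lim)) {
    warn(sprintf("joystick angle clamped to +/-%g deg", lim))
    gamma_z <- pmin(pmax(gamma_z, -lim), lim)
  }
  gamma_z * cfg$torque_gain_cR
}

#' Wave slope envelope
#'
#' Raised-cosine envelope of the wave slope, 0 outside the event and peaking
#' midway through `duration`.
#'
#' @param t Time, s.
#' @param onset_time Envelope start, s.
#' @param duration Envelope duration, s.
#' @param peak Peak envelope value (unitless slope scale). Default 1.
#' @return Envelope values in `[0, peak]`.
#' @export
wave_envelope <- function(t, onset_time, duration, peak = 1) {
  u <- (t - onset_time) / duration
  e <- ifelse(u >= 0 & u < 1, peak * 0.5 * (1 - cos(2 * pi * u)), 0)
  e
}

# pitch from alignment error and envelope value
pitch_from_alignment <- function(beta, env, cfg) {
  b <- fold_beta(beta)
  cfg$pitch_peak * env * pmax(0, 1 - b / 90)
}

#' Open-loop pitch trajectory
#'
#' Computes the boat pitch time series implied by an alignment-error series
#' and a wave event: `phi(t) = pitch_peak * E(t) * max(0, 1 - |beta|/90)`,
#' with `E(t)` the raised-cosine slope envelope of the event. The incoming
#' wave onset is the first sample at which the pitch crosses 15 deg upward.
#'
#' @param beta_series Alignment error series, deg, sampled on the trial grid
#'   (one value per sample at `cfg$sample_rate` starting at time 0).
#' @param wave A one-row wave event (see [make_wave_schedule()]) or a list
#'   with `onset_time`, `env_duration`, `env_peak`.
#' @param cfg A [sim_config()].
#' @return A list with `phi` (deg, same length as `beta_series`), `time`
#'   (s), and `onset_sample` (1-based index of the first upward 15 deg
#'   crossing, `NA` if the pitch never reaches 15 deg).
#' @export
pitch_trajectory <- function(beta_series, wave, cfg = sim_config()) {
  time <- (seq_along(beta_series) - 1) / cfg$sample_rate
  env <- wave_envelope(
    time, wave$onset_time,
    wave$env_duration %||% cfg$wave_envelope_duration,
    wave$env_peak %||% 1
  )
  phi <- pitch_from_alignment(beta_series, env, cfg)
  onset <- detect_onset(phi)
  list(phi = phi, time = time, onset_sample = onset)
}

# first upward crossing of 15 deg; NA when never reached
detect_onset <- function(phi, threshold = 15) {
  above <- phi >= threshold
  if (!any(above)) {
    return(NA_integer_)
  }
  idx <- which(above & !c(FALSE, above[-length(above)]))
  idx[1]
}

#' Wave schedule for one session
#'
#' Draws the per-trial incoming wave events of a session: directions sampled
#' uniformly from the admissible direction set, one raised-cosine slope
#' envelope per trial starting after the trial lead-in.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @return A tibble with one row per trial: `trial`, `onset_time` (s, the
#'   envelope start), `direction_omega` (deg), `env_peak`, `env_duration`
#'   (s).
#' @export
#' @examples
#' make_wave_schedule(sim_config(), seed = 1)
make_wave_schedule <- function(cfg = sim_config(), seed = NULL) {
  dirs <- seq(cfg$wave_dir_min, cfg$wave_dir_max, by = cfg$wave_dir_step)
  if (length(dirs) == 0) {
    abort("empty admissible wave-direction set.",
      class = "alphasurf_config_error"
    )
  }
  n <- cfg$trials_per_session
  omega <- with_seed_(seed, sample(dirs, n, replace = TRUE))
  tibble(
    trial = seq_len(n),
    onset_time = cfg$trial_lead_in,
    direction_omega = omega,
    env_peak = 1,
    env_duration = cfg$wave_envelope_duration
  )
}

#' Agent skill profile
#'
#' Parameterizes the simulated participant steering the boat: a systematic
#' alignment bias, white command noise on the joystick, a reaction delay for
#' obstacle avoidance, and additive per-phase learning changes applied at
#' Retention.
#'
#' @param alignment_bias Systematic heading bias, deg.
#' @param motor_noise_sd SD of white joystick command noise, deg.
#' @param reaction_delay Delay before responding to an obstacle, s.
#' @param learning_bias_delta,learning_noise_delta Additive changes to the
#'   bias and noise SD from Baseline to Retention.
#' @param steer_gain Proportional steering gain, joystick deg per deg of
#'   heading error. Default 1.
#' @param group Instruction group label ("IMP", "E" or "E-IMP").
#' @return A list of class `surf_agent`.
#' @export
agent_profile <- function(alignment_bias = 0,
                          motor_noise_sd = 0,
                          reaction_delay = 0.3,
                          learning_bias_delta = 0,
                          learning_noise_delta = 0,
                          steer_gain = 1,
                          group = "IMP") {
  if (motor_noise_sd < 0 || reaction_delay < 0) {
    abort("`motor_noise_sd` and `reaction_delay` must be non-negative.",
      class = "alphasurf_input_error"
    )
  }
  structure(
    list(
      alignment_bias = alignment_bias, motor_noise_sd = motor_noise_sd,
      reaction_delay = reaction_delay,
      learning_bias_delta = learning_bias_delta,
      learning_noise_delta = learning_noise_delta,
      steer_gain = steer_gain, group = group
    ),
    class = "surf_agent"
  )
}

#' Trial specification
#'
#' @param task Task type: `"HT"` (free surfing), `"OT"` (obstacle task), or
#'   a training task (`"TRAIN_IMP"`, `"TRAIN_E"`, `"TRAIN_EIMP"`).
#' @param obstacle_present For OT trials, whether an obstacle appears at
#'   incoming wave onset.
#' @param buoy_offset Training-task buoy angular offset w.r.t. the wave
#'   direction, deg (buoys on the 25 m.u. semi-circle for IMP/E, on the wave
#'   direction for E-IMP).
#' @param buoy_colour `"green"` (go) or `"red"` (no-go) for E-IMP training.
#' @return A list of class `surf_trialspec`.
#' @export
trial_spec <- function(task = c("HT", "OT", "TRAIN_IMP", "TRAIN_E", "TRAIN_EIMP"),
                       obstacle_present = FALSE,
                       buoy_offset = NA_real_,
                       buoy_colour = NA_character_) {
  task <- match.arg(task)
  structure(
    list(
      task = task, obstacle_present = obstacle_present,
      buoy_offset = buoy_offset, buoy_colour = buoy_colour
    ),
    class = "surf_trialspec"
  )
}

# Core vectorized integrator: simulates many trials on a common time grid.
# `trials` is a tibble with one row per trial and columns:
#   omega, onset_time, env_duration, env_peak,
#   bias, noise_sd, reaction_delay, steer_gain,
#   obstacle_present (logical), avoid_sign (+1/-1), target_offset (deg)
# Returns list(log = long tibble, events = tibble(trial, sample, label)).
simulate_trials_core <- function(trials, cfg, seed = NULL) {
  n_tr <- nrow(trials)
  dt <- 1 / cfg$sample_rate
  n_t <- floor(cfg$trial_duration * cfg$sample_rate)
  time <- (seq_len(n_t) - 1) * dt
  avoid_offset <- 35 # deg steered away from the wave on obstacle response

  noise <- with_seed_(
    seed,
    matrix(rnorm(n_t * n_tr), nrow = n_t, ncol = n_tr)
  )
  noise <- sweep(noise, 2, trials$noise_sd, `*`)

  # state vectors (one entry per trial)
  alpha <- rep(90, n_tr) # start heading toward the finish line (+y)
  yaw_rate <- rep(0, n_tr)
  a_w <- rep(0, n_tr)
  v <- rep(cfg$initial_speed, n_tr)
  px <- rep(0, n_tr)
  py <- rep(0, n_tr)
  onset_sample <- rep(NA_integer_, n_tr)

  ch <- function() matrix(0, nrow = n_t, ncol = n_tr)
  out <- list(
    pos_x = ch(), pos_y = ch(), vel_x = ch(), vel_y = ch(),
    heading_alpha = ch(), pitch_phi = ch(), accel_aw = ch(),
    joystick_gamma = ch()
  )

  deg2rad <- pi / 180
  base_target <- trials$omega + trials$bias +
    ifelse(is.na(trials$target_offset), 0, trials$target_offset)
  avoid_target <- trials$omega + trials$avoid_sign * avoid_offset +
    trials$bias
  obstacle <- as.logical(trials$obstacle_present)

  for (i in seq_len(n_t)) {
    t_i <- time[i]
    # obstacle avoidance engages reaction_delay after the detected onset
    avoiding <- obstacle & !is.na(onset_sample) &
      (t_i >= (onset_sample - 1) * dt + trials$reaction_delay)
    target <- ifelse(avoiding, avoid_target, base_target)

    err <- wrap180(target - alpha)
    gamma <- trials$steer_gain * err + noise[i, ]
    gamma <- pmin(pmax(gamma, -cfg$joystick_limit), cfg$joystick_limit)
    tau <- gamma * cfg$torque_gain_cR

    beta <- fold_beta(trials$omega - alpha)
    env <- wave_envelope(t_i, trials$onset_time, trials$env_duration,
      peak = trials$env_peak
    )
    phi <- pitch_from_alignment(beta, env, cfg)
    a_w <- accel_update(a_w, phi, cfg)

    newly_on <- is.na(onset_sample) & phi >= 15
    onset_sample[newly_on] <- i

    out$pos_x[i, ] <- px
    out$pos_y[i, ] <- py
    out$vel_x[i, ] <- v * cos(alpha * deg2rad)
    out$vel_y[i, ] <- v * sin(alpha * deg2rad)
    out$heading_alpha[i, ] <- alpha
    out$pitch_phi[i, ] <- phi
    out$accel_aw[i, ] <- a_w
    out$joystick_gamma[i, ] <- gamma

    # integrate state to the next sample
    yaw_rate <- yaw_rate + dt * (cfg$turn_gain * tau -
      cfg$rotational_drag * yaw_rate)
    alpha <- alpha + dt * yaw_rate
    v <- pmax(v + dt * (a_w - cfg$translational_drag * v), 0)
    px <- px + dt * v * cos(alpha * deg2rad)
    py <- py + dt * v * sin(alpha * deg2rad)
  }

  # nominal onset fallback: time at which a perfectly aligned boat would
  # cross 15 deg (envelope alone); keeps badly misaligned trials analyzable
  need <- is.na(onset_sample)
  if (any(need)) {
    for (j in which(need)) {
      env_j <- wave_envelope(
        time, trials$onset_time[j],
        trials$env_duration[j], trials$env_peak[j]
      )
      onset_sample[j] <- detect_onset(cfg$pitch_peak * env_j)
    }
  }

  log <- tibble(
    trial = rep(trials$trial, each = n_t),
    time = rep(time, times = n_tr),
    pos_x = as.vector(out$pos_x), pos_y = as.vector(out$pos_y),
    vel_x = as.vector(out$vel_x), vel_y = as.vector(out$vel_y),
    heading_alpha = as.vector(out$heading_alpha),
    pitch_phi = as.vector(out$pitch_phi),
    accel_aw = as.vector(out$accel_aw),
    joystick_gamma = as.vector(out$joystick_gamma),
    wave_dir_omega = rep(trials$omega, each = n_t)
  )
  events <- tibble(
    trial = trials$trial,
    sample = onset_sample,
    label = "onset"
  )
  list(log = log, events = events)
}

#' Simulate a single trial
#'
#' Runs the closed-loop simulation of one trial: the agent steers a
#' proportional controller (with bias and white command noise) toward the
#' wave direction (or an avoidance heading for obstacle trials), the
#' joystick maps to yaw torque with first-order rotational drag, pitch
#' follows the wave-slope envelope scaled by alignment, acceleration follows
#' the per-step pitch update, and speed integrates acceleration against
#' first-order translational drag.
#'
#' @param agent An [agent_profile()].
#' @param wave A one-row wave event from [make_wave_schedule()].
#' @param spec A [trial_spec()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed; the log is bit-identical for a fixed seed.
#' @return A list with `log` (tibble: `time`, `pos_x`, `pos_y`, `vel_x`,
#'   `vel_y`, `heading_alpha`, `pitch_phi`, `accel_aw`, `joystick_gamma`,
#'   `wave_dir_omega`) and `events` (tibble: `trial`, `sample`, `label`,
#'   with the incoming wave onset marker).
#' @export
#' @examples
#' w <- make_wave_schedule(sim_config(), seed = 1)[1, ]
#' sim <- simulate_trial(agent_profile(), w, trial_spec("HT"),
#'   sim_config(),
#'   seed = 1
#' )
#' head(sim$log)
simulate_trial <- function(agent, wave, spec = trial_spec("HT"),
                           cfg = sim_config(), seed = NULL) {
  stopifnot(inherits(agent, "surf_agent"), inherits(spec, "surf_trialspec"))
  target_offset <- NA_real_
  if (spec$task %in% c("TRAIN_IMP", "TRAIN_E") && !is.na(spec$buoy_offset)) {
    target_offset <- spec$buoy_offset
  }
  if (spec$task == "TRAIN_EIMP" && identical(spec$buoy_colour, "red")) {
    target_offset <- 90 # no-go buoy: misalign orthogonally to shed speed
  }
  trials <- tibble(
    trial = wave$trial %||% 1L,
    omega = wave$direction_omega,
    onset_time = wave$onset_time,
    env_duration = wave$env_duration %||% cfg$wave_envelope_duration,
    env_peak = wave$env_peak %||% 1,
    bias = agent$alignment_bias,
    noise_sd = agent$motor_noise_sd,
    reaction_delay = agent$reaction_delay,
    steer_gain = agent$steer_gain,
    obstacle_present = isTRUE(spec$obstacle_present),
    avoid_sign = 1,
    target_offset = target_offset
  )
  simulate_trials_core(trials, cfg, seed = seed)
}

#' Default cohort design
#'
#' Group sizes and agent-profile distributions for a simulated cohort: three
#' instruction groups of 12 participants. Learning deltas plant a larger
#' joystick-variability reduction in the E and E-IMP groups than in IMP.
#' The default motor-noise parameters are calibrated so that the measured
#' per-group median joystick-variability changes land on the study-scale
#' values (-2.27, -8.4, -8.69 deg for IMP, E, E-IMP): the joystick's
#' mechanical +/-15 deg limit truncates the command noise, so the raw
#' noise-SD deltas are larger than the measured changes they produce.
#'
#' @param subjects_per_group Participants per instruction group. Default 12.
#' @param noise_delta Named per-group additive change in motor noise SD
#'   (deg) from Baseline to Retention.
#' @param bias_delta Named per-group additive change in alignment bias (deg).
#' @param baseline_noise_sd Mean Baseline motor noise SD, deg.
#' @param baseline_bias Mean Baseline alignment bias magnitude, deg.
#' @param subject_sd Between-subject SD applied to both baseline parameters.
#' @param delta_sd Between-subject SD of the individual learning deltas
#'   (deg); sets the spread of the change scores around the group
#'   medians. Default 4.
#' @param lapse_prob Per-trial probability of an attentional lapse in
#'   which the agent steers far off the wave (producing Missed waves).
#'   Default 0.15.
#' @return A list of class `surf_design`.
#' @export
cohort_design <- function(subjects_per_group = 12,
                          noise_delta = c(
                            "IMP" = -4.15, "E" = -10.75, "E-IMP" = -11.05
                          ),
                          bias_delta = c(
                            "IMP" = 0, "E" = -4, "E-IMP" = -5
                          ),
                          baseline_noise_sd = 12,
                          baseline_bias = 15,
                          subject_sd = 1,
                          delta_sd = 4,
                          lapse_prob = 0.15) {
  if (subjects_per_group < 2) {
    abort("`subjects_per_group` must be at least 2.",
      class = "alphasurf_config_error"
    )
  }
  structure(
    list(
      subjects_per_group = subjects_per_group,
      groups = names(noise_delta),
      noise_delta = noise_delta, bias_delta = bias_delta,
      baseline_noise_sd = baseline_noise_sd,
      baseline_bias = baseline_bias, subject_sd = subject_sd,
      delta_sd = delta_sd, lapse_prob = lapse_prob
    ),
    class = "surf_design"
  )
}

#' Simulate a full behavioural cohort
#'
#' Emits Baseline and Retention sessions of the requested tasks for every
#' participant of a three-group cohort. Each participant receives an agent
#' profile drawn around the design's group parameters; Retention applies the
#' group's learning deltas. All randomness derives from `seed`.
#'
#' @param design A [cohort_design()].
#' @param cfg A [sim_config()].
#' @param seed Integer master seed.
#' @param tasks Character subset of `c("HT", "OT")`.
#' @return A list of class `surf_cohort` with `log` (long kinematics tibble
#'   keyed by `subject`, `group`, `phase`, `task`, `trial`), `events`
#'   (onset markers with the same keys), `trials` (per-trial design,
#'   including `obstacle_present`), and `agents` (per-subject profiles).
#' @export
simulate_cohort <- function(design = cohort_design(), cfg = sim_config(),
                            seed = 1, tasks = c("HT", "OT")) {
  tasks <- match.arg(tasks, several.ok = TRUE)
  stopifnot(inherits(design, "surf_design"))
  groups <- design$groups
  nsub <- design$subjects_per_group

  agents <- with_seed_(derive_seed(seed, "agent"), {
    n_all <- nsub * length(groups)
    grp <- rep(groups, each = nsub)
    tibble(
      subject = sprintf("S%02d", seq_len(n_all)),
      group = grp,
      baseline_bias = pmax(
        0, rnorm(n_all, design$baseline_bias, design$subject_sd)
      ),
      baseline_noise_sd = pmax(
        0.5, rnorm(n_all, design$baseline_noise_sd, design$subject_sd)
      ),
      noise_delta = design$noise_delta[grp] +
        rnorm(n_all, 0, design$delta_sd),
      bias_delta = design$bias_delta[grp] +
        rnorm(n_all, 0, design$delta_sd / 2),
      reaction_delay = 0.3,
      steer_gain = 1
    )
  })

  sessions <- tidyr::expand_grid(
    subject = agents$subject,
    phase = c("Baseline", "Retention"),
    task = tasks
  ) |>
    dplyr::left_join(agents, by = "subject")

  sched_seed <- derive_seed(seed, "schedule")
  all_trials <- purrr::pmap(
    list(
      sessions$subject, sessions$phase, sessions$task,
      seq_len(nrow(sessions))
    ),
    function(subject, phase, task, k) {
      sch <- make_wave_schedule(cfg, seed = sched_seed + k)
      ag <- sessions[k, ]
      retained <- phase == "Retention"
      obstacle <- if (task == "OT") {
        with_seed_(
          sched_seed + 7L * k,
          sample(rep(c(TRUE, FALSE), length.out = nrow(sch)))
        )
      } else {
        rep(FALSE, nrow(sch))
      }
      # attentional lapses: the agent steers far off the wave and misses it
      lapse_off <- with_seed_(sched_seed + 13L * k, {
        lapse <- runif(nrow(sch)) < design$lapse_prob
        ifelse(lapse, sample(c(-90, 90), nrow(sch), replace = TRUE),
          NA_real_
        )
      })
      tibble(
        subject = subject, group = ag$group, phase = phase, task = task,
        trial = sch$trial,
        omega = sch$direction_omega,
        onset_time = sch$onset_time,
        env_duration = sch$env_duration,
        env_peak = sch$env_peak,
        bias = if (retained) {
          pmax(0, ag$baseline_bias + ag$bias_delta)
        } else {
          ag$baseline_bias
        },
        noise_sd = if (retained) {
          pmax(0.5, ag$baseline_noise_sd + ag$noise_delta)
        } else {
          ag$baseline_noise_sd
        },
        reaction_delay = ag$reaction_delay,
        steer_gain = ag$steer_gain,
        obstacle_present = obstacle,
        avoid_sign = 1,
        target_offset = lapse_off
      )
    }
  ) |>
    dplyr::bind_rows()
  all_trials$row_id <- seq_len(nrow(all_trials))

  core_in <- all_trials
  core_in$trial <- core_in$row_id
  sim <- simulate_trials_core(core_in, cfg,
    seed = derive_seed(seed, "behaviour")
  )

  keys <- all_trials[, c("subject", "group", "phase", "task", "trial", "row_id")]
  log <- sim$log |>
    dplyr::rename(row_id = "trial") |>
    dplyr::left_join(keys, by = "row_id") |>
    dplyr::select(
      "subject", "group", "phase", "task", "trial",
      dplyr::everything(), -"row_id"
    )
  events <- sim$events |>
    dplyr::rename(row_id = "trial") |>
    dplyr::left_join(keys, by = "row_id") |>
    dplyr::select("subject", "group", "phase", "task", "trial", "sample", "label")

  structure(
    list(
      log = log, events = events,
      trials = dplyr::select(all_trials, -"row_id"), agents = agents,
      cfg = cfg, seed = seed
    ),
    class = "surf_cohort"
  )
}

#' @export
print.surf_cohort <- function(x, ...) {
  cat("<surf_cohort>\n")
  cat(sprintf(
    "  %d subjects (%s), phases: %s, tasks: %s\n",
    dplyr::n_distinct(x$trials$subject),
    paste(unique(x$trials$group), collapse = "/"),
    paste(unique(x$trials$phase), collapse = "/"),
    paste(unique(x$trials$task), collapse = "/")
  ))
  cat(sprintf(
    "  %d trials, %d log samples\n",
    nrow(x$trials), nrow(x$log)
  ))
  invisible(x)
}
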
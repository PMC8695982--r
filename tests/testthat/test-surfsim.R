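test_that("acceleration update reproduces the four printed branches", {
  cfg <- default_cfg
  # in-range gain branch: 5 + 0.17*30 + 0.1
  expect_equal(accel_update(5, 30, cfg), 10.2)
  # cap branch
  expect_equal(accel_update(20, 45, cfg), 20)
  expect_equal(accel_update(25, 45, cfg), 20)
  # out-of-range, literal print: 10 - 5*0.17*5 + 2
  expect_equal(accel_update(10, 5, cfg), 7.75)
  # out-of-range monotone reading: 10 - (5*0.17*5 + 2)
  cfg_m <- sim_config(decel_mode = "monotone")
  expect_equal(accel_update(10, 5, cfg_m), 3.75)
  # rest stays at rest off the wave
  expect_equal(accel_update(0, 0, cfg), 0)
  expect_error(accel_update(NA, 10, cfg), class = "alphasurf_input_error")
  expect_error(accel_update(1, Inf, cfg), class = "alphasurf_input_error")
})

test_that("acceleration update agrees with a brute-force branch evaluator", {
  withr::with_seed(11, {
    a <- runif(20000, -5, 30)
    a <- pmin(pmax(a, 0), 20)
    phi <- runif(20000, -30, 120)
  })
  for (mode in c("literal", "monotone")) {
    cfg <- sim_config(decel_mode = mode)
    expect_equal(
      accel_update(a, phi, cfg),
      accel_oracle(a, phi, mode = mode),
      tolerance = 1e-12
    )
  }
})

test_that("sustained in-range pitch drives acceleration monotonically to the cap", {
  cfg <- default_cfg
  a <- 0
  trace <- numeric(30)
  for (i in seq_len(30)) {
    a <- accel_update(a, 45, cfg)
    trace[i] <- a
  }
  expect_true(all(diff(trace) >= 0))
  expect_equal(trace[30], cfg$accel_cap)
  # reaches the cap in finitely many steps for any in-range pitch
  for (phi in c(15, 50, 90)) {
    a <- 0
    for (i in seq_len(1000)) a <- accel_update(a, phi, cfg)
    expect_equal(a, cfg$accel_cap)
  }
})

test_that("steering torque is the signed joystick-angle product", {
  cfg <- default_cfg
  expect_equal(steering_torque(0, cfg), 0)
  expect_equal(steering_torque(15, cfg), 4.05)
  expect_equal(steering_torque(-10, cfg), -2.7)
  expect_warning(out <- steering_torque(20, cfg), "clamped")
  expect_equal(out, 15 * 0.27)
})

test_that("pitch trajectory scales with alignment and marks the onset", {
  cfg <- default_cfg
  w <- wave_row(onset_time = 0, duration = 8)
  n <- 8 * cfg$sample_rate
  # orthogonal boat receives no push
  pt <- pitch_trajectory(rep(90, n), w, cfg)
  expect_true(all(pt$phi == 0))
  expect_true(is.na(pt$onset_sample))
  # aligned boat reaches pitch_peak at the envelope crest
  pt0 <- pitch_trajectory(rep(0, n), w, cfg)
  expect_equal(max(pt0$phi), cfg$pitch_peak, tolerance = 1e-3)
  # half misalignment halves the headroom: 60 * (1 - 45/90) = 30
  pt45 <- pitch_trajectory(rep(45, n), w, cfg)
  expect_equal(max(pt45$phi), 30, tolerance = 1e-3)
  # onset is the first upward 15-degree crossing
  expect_equal(pt0$onset_sample, min(which(pt0$phi >= 15)))
  # alignment error is folded, not signed
  expect_equal(
    pitch_trajectory(rep(-45, n), w, cfg)$phi,
    pt45$phi
  )
})

test_that("wave schedules draw from the admissible direction set", {
  cfg <- default_cfg
  s <- make_wave_schedule(cfg, seed = 5)
  expect_equal(nrow(s), 36)
  expect_true(all(s$direction_omega %in% seq(60, 120, by = 5)))
  expect_identical(s, make_wave_schedule(cfg, seed = 5))
  expect_false(identical(
    s$direction_omega,
    make_wave_schedule(cfg, seed = 6)$direction_omega
  ))
  expect_error(
    make_wave_schedule(sim_config(wave_dir_min = 60, wave_dir_max = 61, wave_dir_step = 5)),
    NA
  )
})

test_that("closed-loop trials behave as the task intends", {
  cfg <- default_cfg
  w <- wave_row(omega = 90)
  # a perfect agent catches the wave: speed increases over the ToI
  sim <- simulate_trial(agent_profile(), w, trial_spec("HT"), cfg, seed = 3)
  m <- trial_metrics(sim$log, sim$events)
  expect_true(m$hit)
  expect_gt(m$mean_speed, m$v0)
  # a frozen orthogonal agent never pitches up and misses
  w_orth <- wave_row(omega = 180) # heading starts at 90 deg
  sim2 <- simulate_trial(
    agent_profile(steer_gain = 0), w_orth, trial_spec("HT"), cfg,
    seed = 3
  )
  expect_true(all(sim2$log$pitch_phi == 0))
  speeds <- sqrt(sim2$log$vel_x^2 + sim2$log$vel_y^2)
  expect_true(all(diff(speeds) <= 1e-12))
  m2 <- trial_metrics(sim2$log, sim2$events)
  expect_false(m2$hit)
  # determinism: same seed gives a bit-identical log
  expect_identical(
    simulate_trial(agent_profile(motor_noise_sd = 5), w, cfg = cfg, seed = 9)$log,
    simulate_trial(agent_profile(motor_noise_sd = 5), w, cfg = cfg, seed = 9)$log
  )
})

test_that("peak speed falls between onset and envelope end (monotone decel)", {
  cfg <- sim_config(decel_mode = "monotone")
  w <- wave_row(omega = 90)
  sim <- simulate_trial(agent_profile(), w, trial_spec("HT"), cfg, seed = 4)
  speeds <- sqrt(sim$log$vel_x^2 + sim$log$vel_y^2)
  peak_t <- sim$log$time[which.max(speeds)]
  onset_t <- sim$log$time[sim$events$sample]
  expect_gt(peak_t, onset_t)
  expect_lt(peak_t, w$onset_time + w$env_duration)
})

test_that("better alignment never yields lower mean ToI speed", {
  cfg <- default_cfg
  w <- wave_row(omega = 90)
  means <- vapply(c(0, 15, 30, 45, 60, 75), function(b) {
    sim <- simulate_trial(
      agent_profile(alignment_bias = b), w, trial_spec("HT"), cfg,
      seed = 7
    )
    trial_metrics(sim$log, sim$events)$mean_speed
  }, numeric(1))
  expect_true(all(diff(means) <= 1e-9))
})

test_that("cohort simulation emits the full design and plants the learning effects", {
  d <- cohort_design()
  expect_equal(d$subjects_per_group, 12)
  expect_equal(d$groups, c("IMP", "E", "E-IMP"))
  small <- cohort_design(subjects_per_group = 2, lapse_prob = 0)
  coh <- simulate_cohort(small, default_cfg, seed = 2, tasks = "HT")
  expect_equal(nrow(coh$agents), 6)
  expect_setequal(unique(coh$trials$phase), c("Baseline", "Retention"))
  expect_equal(nrow(coh$trials), 6 * 2 * 36)
  # all logs satisfy the joystick and acceleration bounds
  expect_true(all(abs(coh$log$joystick_gamma) <= default_cfg$joystick_limit))
  expect_true(all(coh$log$accel_aw >= 0 &
    coh$log$accel_aw <= default_cfg$accel_cap))
  # determinism of the full cohort
  coh2 <- simulate_cohort(small, default_cfg, seed = 2, tasks = "HT")
  expect_identical(coh$log, coh2$log)
  expect_error(cohort_design(subjects_per_group = 1),
    class = "alphasurf_config_error"
  )
})

test_that("a null cohort (zero learning deltas) has near-zero change medians", {
  null_design <- cohort_design(
    subjects_per_group = 4,
    noise_delta = c("IMP" = 0, "E" = 0, "E-IMP" = 0),
    bias_delta = c("IMP" = 0, "E" = 0, "E-IMP" = 0),
    delta_sd = 0, lapse_prob = 0
  )
  coh <- simulate_cohort(null_design, default_cfg, seed = 8, tasks = "HT")
  mm <- trial_metrics(coh$log, coh$events)
  sumt <- summarize_participants(mm)
  meds <- sumt |>
    dplyr::filter(metric == "joystick_sd") |>
    dplyr::group_by(group) |>
    dplyr::summarise(md = median(change))
  expect_true(all(abs(meds$md) < 0.5))
})
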
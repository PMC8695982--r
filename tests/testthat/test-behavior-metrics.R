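test_that("resampling linearly interpolates onto the target grid", {
  # already-uniform input is unchanged on the grid
  raw <- tibble::tibble(time = (0:99) / 50, v = sin((0:99) / 10))
  out <- resample_log(raw, rate = 50)
  expect_equal(out$v[1:99], raw$v[1:99], tolerance = 1e-12)
  # an affine signal is reproduced exactly from irregular samples
  withr::with_seed(2, {
    t_irr <- sort(runif(80, 0, 10))
  })
  t_irr <- c(0, t_irr, 10)
  raw2 <- tibble::tibble(time = t_irr, v = 3 * t_irr - 1)
  out2 <- resample_log(raw2, rate = 50)
  expect_equal(out2$v, 3 * out2$time - 1, tolerance = 1e-9)
  # a 10 s span at 50 Hz gives 500 half-open grid points
  expect_equal(nrow(out2), 500)
  # duplicate timestamps are rejected
  raw3 <- tibble::tibble(time = c(0, 1, 1, 2), v = 1:4)
  expect_error(resample_log(raw3, 50), class = "alphasurf_input_error")
})

test_that("speed smoothing is a zero-phase low-pass with unit DC gain", {
  expect_equal(smooth_speed(rep(3.2, 200), rate = 50), rep(3.2, 200),
    tolerance = 1e-9
  )
  # a 20 Hz ripple at 50 Hz sampling is attenuated below 5 %
  t <- (0:499) / 50
  x <- sin(2 * pi * 20 * t)
  y <- smooth_speed(x, rate = 50)
  expect_lt(max(abs(y[100:400])), 0.05)
  # the peak of a smooth unimodal trace does not move
  tr <- 10 * exp(-(t - 5)^2 / 2)
  expect_equal(which.max(smooth_speed(tr, rate = 50)), which.max(tr))
  expect_error(smooth_speed(x, rate = 8, cutoff = 5),
    class = "alphasurf_config_error"
  )
})

test_that("time-of-interest diagnostics report the peak-time distribution", {
  rate <- 50
  mk <- function(peak_s, trial) {
    t <- (0:449) / rate
    sp <- 5 + 10 * exp(-(t - peak_s)^2 / 0.5)
    tibble::tibble(
      trial = trial, time = t, vel_x = sp, vel_y = 0,
      pos_y = cumsum(sp) / rate
    )
  }
  log <- dplyr::bind_rows(mk(3, 1L), mk(5, 2L), mk(7, 3L))
  ev <- dplyr::bind_rows(lapply(1:3, function(k) onset_event(1L, k)))
  fit <- compute_toi(log, ev, task = "HT", rate = rate)
  expect_equal(fit$median, 5, tolerance = 0.05)
  expect_equal(fit$window$lower, 0.15)
  expect_equal(fit$window$upper, 6.4)
  # single trial: interval degenerates to its own peak time
  fit1 <- compute_toi(mk(4, 1L), onset_event(1L), task = "HT", rate = rate)
  expect_equal(unname(fit1$ci), rep(fit1$median, 2))
  # OT default window
  expect_equal(toi_window("OT")$lower, 0)
  expect_equal(toi_window("OT")$upper, 7)
})

test_that("trial metrics recover closed-form values on constant logs", {
  # constant velocity (3, 4): Pythagorean speed 5
  log <- constant_log(n = 400, vel_x = 3, vel_y = 4)
  m <- trial_metrics(log, onset_event())
  expect_equal(m$mean_speed, 5, tolerance = 1e-9)
  expect_equal(m$v0, 5, tolerance = 1e-9)
  # constant v_y = 2 over the HT ToI: distance 2 * (6.4 - 0.15)
  log2 <- constant_log(n = 400, vel_y = 2, pos_y_rate = 2)
  m2 <- trial_metrics(log2, onset_event())
  expect_equal(m2$distance_D, 12.5, tolerance = 1e-9)
  # constant joystick angle: zero variability
  expect_equal(m$joystick_sd, 0)
  # constant heading/wave: alignment error constant
  expect_equal(m$mean_abs_beta, 0)
  # missing onset marker is an error
  expect_error(
    trial_metrics(log, tibble::tibble(
      trial = 1L, sample = NA_integer_, label = "onset"
    )),
    class = "alphasurf_input_error"
  )
})

test_that("metrics are invariant to position translations as defined", {
  log <- constant_log(n = 400, vel_x = 1, vel_y = 2, pos_y_rate = 2,
    gamma = 3
  )
  shifted <- dplyr::mutate(log, pos_x = pos_x + 57, pos_y = pos_y + 100)
  m0 <- trial_metrics(log, onset_event())
  m1 <- trial_metrics(shifted, onset_event())
  expect_equal(m1$distance_D, m0$distance_D)
  expect_equal(m1$mean_speed, m0$mean_speed)
  expect_equal(m1$joystick_sd, m0$joystick_sd)
})

test_that("hit classification applies the two-percent decay rule exactly", {
  expect_true(classify_hit(1.05 * 5, 5))
  expect_true(classify_hit(0.99 * 5, 5))
  expect_false(classify_hit(0.95 * 5, 5))
  # boundary: ratio exactly 0.98 is a Hit (>=, not >)
  expect_true(classify_hit(0.98 * 5, 5))
  # brute-force grid oracle over speed ratios
  ratios <- seq(0.9, 1.1, by = 0.001)
  oracle <- vapply(ratios, function(r) r >= 0.98, logical(1))
  expect_equal(classify_hit(ratios * 7, rep(7, length(ratios))), oracle)
  # v0 = 0 edge rule: hit iff any speed was gained
  expect_true(classify_hit(0.1, 0))
  expect_false(classify_hit(0, 0))
})

test_that("obstacle-task outcomes follow the 20-degree misalignment rule", {
  expect_equal(classify_ot_outcome(25, TRUE), "TP")
  expect_equal(classify_ot_outcome(5, FALSE), "TN")
  expect_equal(classify_ot_outcome(5, TRUE), "FN")
  expect_equal(classify_ot_outcome(25, FALSE), "FP")
  # boundary at exactly 20 degrees counts as misaligned
  expect_equal(classify_ot_outcome(20, TRUE), "TP")
  # exhaustive grid oracle over misalignment maxima and obstacle presence
  grid <- expand.grid(beta = seq(0, 60, by = 0.5), obs = c(TRUE, FALSE))
  oracle <- with(grid, ifelse(beta >= 20,
    ifelse(obs, "TP", "FP"), ifelse(obs, "FN", "TN")
  ))
  expect_equal(classify_ot_outcome(grid$beta, grid$obs), oracle)
})

test_that("obstacle-task rates are simple outcome ratios", {
  out <- c(rep("TP", 3), rep("TN", 4), "FP", rep("FN", 2))
  r <- ot_rates(out)
  expect_equal(r$success_rate, 0.7)
  expect_equal(r$avoidance_inability, 0.2)
  expect_equal(ot_rates(rep("TN", 5))$success_rate, 1)
  expect_equal(ot_rates(rep("FN", 5))$avoidance_inability, 1)
  expect_error(ot_rates(character(0)), class = "alphasurf_input_error")
})

test_that("participant summaries average the stated trial subsets", {
  mk_metrics <- function(shift) {
    tidyr::expand_grid(
      subject = c("S1", "S2"), group = "E",
      phase = c("Baseline", "Retention"), task = c("HT", "OT"),
      trial = 1:4
    ) |>
      dplyr::mutate(
        mean_speed = 5 + (phase == "Retention") * shift,
        distance_D = 10, mean_abs_beta = 8, joystick_sd = 2,
        v0 = 5, hit = TRUE,
        obstacle_present = ifelse(task == "OT", trial <= 2, NA),
        ot_outcome = dplyr::case_when(
          task != "OT" ~ NA_character_,
          trial <= 2 ~ "TP",
          TRUE ~ "TN"
        )
      )
  }
  # identical phases: all changes zero
  s0 <- summarize_participants(mk_metrics(0))
  expect_true(all(s0$change == 0, na.rm = TRUE))
  # a uniform +1 shift moves the mean-speed change to 1
  s1 <- summarize_participants(mk_metrics(1))
  expect_equal(
    unique(s1$change[s1$metric == "mean_speed"]), 1
  )
  # OT kinematic means use obstacle trials only
  m <- mk_metrics(0) |>
    dplyr::mutate(mean_speed = ifelse(
      task == "OT" & !obstacle_present, 1000, mean_speed
    ))
  s2 <- summarize_participants(m)
  expect_equal(
    unique(s2$baseline[s2$task == "OT" & s2$metric == "mean_speed"]), 5
  )
  # an empty subset is a missing value, not zero
  m3 <- mk_metrics(0) |>
    dplyr::filter(!(task == "OT" & phase == "Retention" & obstacle_present))
  s3 <- summarize_participants(m3)
  ot_speed <- s3[s3$task == "OT" & s3$metric == "mean_speed", ]
  expect_true(all(is.na(ot_speed$retention)))
  expect_true(all(is.na(ot_speed$change)))
})
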
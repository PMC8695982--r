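#' Time-of-interest window
#'
#' The fixed post-onset window over which kinematic metrics are averaged:
#' 0.15 to 6.4 s after incoming wave onset for the free-surfing Horizon
#' task (the lower bound absorbs visuomotor reaction time, the upper bound
#' is a conservative bound on the time to peak speed), 0 to 7 s for the
#' Obstacle task (covering the full detection-avoidance process). Sample
#' inclusion is half-open: `[lower, upper)`.
#'
#' @param task `"HT"` or `"OT"`.
#' @param lower,upper Optional overrides, s after onset.
#' @return A list of class `surf_toi` with `lower`, `upper`, `task`.
#' @export
#' @examples
#' toi_window("HT")
toi_window <- function(task = c("HT", "OT"), lower = NULL, upper = NULL) {
  task <- match.arg(task)
  defaults <- list(HT = c(0.15, 6.4), OT = c(0, 7))[[task]]
  lower <- lower %||% defaults[1]
  upper <- upper %||% defaults[2]
  if (lower >= upper) {
    abort("`lower` must be below `upper`.", class = "alphasurf_config_error")
  }
  structure(list(lower = lower, upper = upper, task = task),
    class = "surf_toi"
  )
}

#' Resample an irregular kinematics log onto a uniform grid
#'
#' Linearly interpolates every channel of a raw log with irregular
#' timestamps onto a uniform grid, as done to the raw recordings before any
#' metric is computed. The grid starts at the first raw timestamp and
#' covers the raw span half-open (a 10 s span at 50 Hz yields 500 points).
#'
#' @param raw A data frame with a `time` column (s, strictly increasing)
#'   and numeric channel columns.
#' @param rate Target sampling rate, Hz.
#' @return A tibble on the uniform grid with the same columns.
#' @export
resample_log <- function(raw, rate = 50) {
  if (!"time" %in% names(raw) || nrow(raw) < 2) {
    abort("`raw` needs a `time` column and at least 2 samples.",
      class = "alphasurf_input_error"
    )
  }
  t <- raw$time
  if (any(diff(t) <= 0)) {
    abort("raw timestamps must be strictly increasing (no duplicates).",
      class = "alphasurf_input_error"
    )
  }
  n <- floor((t[length(t)] - t[1]) * rate + 1e-9)
  grid <- t[1] + (seq_len(n) - 1) / rate
  chans <- setdiff(names(raw), "time")
  out <- purrr::map(chans, function(ch) {
    approx(t, raw[[ch]], xout = grid, rule = 2)$y
  })
  names(out) <- chans
  dplyr::bind_cols(tibble(time = grid), tibble::as_tibble(out))
}

#' Zero-phase Butterworth smoothing of a speed trace
#'
#' Second-order low-pass Butterworth filter applied forward and backward
#' (zero phase), used to locate the peak of the boat speed when determining
#' the time of interest; it removes the medium-frequency speed ripple
#' caused by variable joystick commands.
#'
#' @param x Speed series on a uniform grid.
#' @param rate Sampling rate, Hz.
#' @param cutoff Low-pass cutoff, Hz. Default 5.
#' @param order Filter order. Default 2.
#' @return Filtered series, same length.
#' @export
smooth_speed <- function(x, rate = 50, cutoff = 5, order = 2) {
  if (rate <= 2 * cutoff) {
    abort("`rate` must exceed twice the cutoff frequency.",
      class = "alphasurf_config_error"
    )
  }
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  mu <- mean(x) # filter deviations only: keeps the DC gain exactly 1
  mu + as.numeric(signal::filtfilt(bf, x - mu))
}

#' Determine the time of interest from trial speed peaks
#'
#' Reports, per trial, the time of maximum smoothed horizontal boat speed
#' after the incoming wave onset, and summarizes the distribution (median
#' and 2.5/97.5 percentile interval) across trials. The returned analysis
#' window itself is the fixed task default from [toi_window()]; the
#' diagnostics justify (or challenge) that choice for a given dataset.
#'
#' @param log Long kinematics tibble (as from [simulate_cohort()]; must
#'   contain `time`, `vel_x`, `vel_y` and the trial key columns).
#' @param events Onset markers matching `log` (key columns plus `sample`).
#' @param task `"HT"` or `"OT"`.
#' @param rate Sampling rate of the log, Hz.
#' @return A list of class `surf_toi_fit`: `window` (the [toi_window()]),
#'   `peaks` (per-trial peak times, s after onset), `median`, `ci`
#'   (2.5/97.5 percentiles; degenerate at n = 1).
#' @export
compute_toi <- function(log, events, task = c("HT", "OT"), rate = 50) {
  task <- match.arg(task)
  keys <- intersect(c("subject", "group", "phase", "task", "trial"), names(log))
  if (length(keys) == 0) {
    abort("`log` carries no trial key columns.",
      class = "alphasurf_input_error"
    )
  }
  df <- log |>
    dplyr::left_join(
      dplyr::select(events, dplyr::all_of(keys), "sample"),
      by = keys
    ) |>
    dplyr::mutate(rel_time = .data$time - (.data$sample - 1) / rate)
  peaks <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      peak_time = {
        sp <- smooth_speed(sqrt(.data$vel_x^2 + .data$vel_y^2), rate = rate)
        post <- .data$rel_time >= 0
        .data$rel_time[post][which.max(sp[post])]
      },
      .groups = "drop"
    )
  structure(
    list(
      window = toi_window(task),
      peaks = peaks,
      median = median(peaks$peak_time),
      ci = quantile(peaks$peak_time, c(0.025, 0.975), names = FALSE)
    ),
    class = "surf_toi_fit"
  )
}

#' Classify a trial as Hit or Missed wave
#'
#' A trial counts as a Hit when the mean boat speed over the time of
#' interest does not fall below the instantaneous speed at the window start
#' by more than the allowed drag decay: `mean_speed >= (1 - tolerance) *
#' v0`. When `v0` is zero the trial is a Hit exactly when any speed was
#' gained (`mean_speed > 0`).
#'
#' @param mean_speed Mean speed over the ToI, m.u./s.
#' @param v0 Speed at the ToI start, m.u./s.
#' @param tolerance Allowed relative decay. Default 0.02.
#' @return Logical vector: `TRUE` for Hit.
#' @export
#' @examples
#' classify_hit(c(4.9, 5.1), v0 = 5)
classify_hit <- function(mean_speed, v0, tolerance = 0.02) {
  ifelse(v0 > 0, mean_speed >= (1 - tolerance) * v0, mean_speed > 0)
}

#' Classify an Obstacle-task trial outcome
#'
#' A trial is "misaligned" when the maximum absolute alignment error within
#' the OT window reaches 20 deg. Crossed with obstacle presence this gives:
#' TP (obstacle, misaligned), TN (no obstacle, aligned), FP (no obstacle,
#' misaligned), FN (obstacle, aligned).
#'
#' @param max_abs_beta Maximum absolute alignment error over the OT ToI, deg.
#' @param obstacle_present Logical.
#' @param threshold Misalignment threshold, deg. Default 20.
#' @return Character vector in `c("TP", "TN", "FP", "FN")`.
#' @export
#' @examples
#' classify_ot_outcome(25, TRUE) # "TP"
classify_ot_outcome <- function(max_abs_beta, obstacle_present,
                                threshold = 20) {
  misaligned <- max_abs_beta >= threshold
  dplyr::case_when(
    obstacle_present & misaligned ~ "TP",
    obstacle_present & !misaligned ~ "FN",
    !obstacle_present & misaligned ~ "FP",
    TRUE ~ "TN"
  )
}

#' Obstacle-task success and avoidance-inability rates
#'
#' @param outcomes Character vector of OT outcomes (`"TP"`, `"TN"`,
#'   `"FP"`, `"FN"`).
#' @return A tibble with `success_rate` = (TP + TN) / N and
#'   `avoidance_inability` = FN / N.
#' @export
ot_rates <- function(outcomes) {
  outcomes <- outcomes[!is.na(outcomes)]
  if (length(outcomes) == 0) {
    abort("no outcomes supplied.", class = "alphasurf_input_error")
  }
  n <- length(outcomes)
  tibble(
    success_rate = sum(outcomes %in% c("TP", "TN")) / n,
    avoidance_inability = sum(outcomes == "FN") / n
  )
}

#' Per-trial kinematic performance metrics
#'
#' Computes, for every trial in a long kinematics log, the mean horizontal
#' boat speed, the distance surfed toward the finish line (absolute change
#' in the global y position between the exact ToI bounds, linearly
#' interpolated), the mean absolute alignment error, the sample standard
#' deviation of the joystick angle, the speed at the ToI start (`v0`), the
#' Hit/Missed classification, and — for Obstacle-task trials with known
#' obstacle presence — the OT outcome.
#'
#' Averages use the half-open sample window `[lower, upper)` relative to
#' the trial's onset marker; `v0` and the distance bounds are interpolated
#' at the exact window edges.
#'
#' @param log Long kinematics tibble with trial key columns (any of
#'   `subject`, `group`, `phase`, `task`, `trial`) and channels `time`,
#'   `pos_y`, `vel_x`, `vel_y`, `heading_alpha`, `joystick_gamma`,
#'   `wave_dir_omega`.
#' @param events Onset markers: key columns plus `sample` (1-based index
#'   into each trial's log).
#' @param toi A [toi_window()]; defaults to the HT window, or per-task
#'   defaults when `log` has a `task` column and `toi = NULL`.
#' @param trials Optional per-trial design (key columns plus
#'   `obstacle_present`) enabling OT outcome classification.
#' @param rate Sampling rate, Hz.
#' @param hit_tolerance Allowed relative speed decay for a Hit. Default 0.02.
#' @return A tibble with one row per trial: the key columns plus
#'   `mean_speed`, `distance_D`, `mean_abs_beta`, `joystick_sd`, `v0`,
#'   `hit`, `ot_outcome`.
#' @export
trial_metrics <- function(log, events, toi = NULL, trials = NULL,
                          rate = 50, hit_tolerance = 0.02) {
  keys <- intersect(c("subject", "group", "phase", "task", "trial"), names(log))
  if (length(keys) == 0) {
    abort("`log` carries no trial key columns.",
      class = "alphasurf_input_error"
    )
  }
  ev <- dplyr::select(events, dplyr::all_of(keys), "sample")
  if (anyNA(ev$sample)) {
    abort("missing onset marker for at least one trial.",
      class = "alphasurf_input_error"
    )
  }
  df <- log |>
    dplyr::left_join(ev, by = keys) |>
    dplyr::mutate(
      rel_time = .data$time - (.data$sample - 1) / rate,
      speed = sqrt(.data$vel_x^2 + .data$vel_y^2),
      abs_beta = fold_beta(.data$wave_dir_omega - .data$heading_alpha)
    )

  per_task_window <- function(task) {
    if (!is.null(toi)) {
      return(toi)
    }
    toi_window(if (identical(task, "OT")) "OT" else "HT")
  }

  out <- df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      {
        w <- per_task_window(
          if ("task" %in% keys) .data$task[1] else "HT"
        )
        rel <- .data$rel_time
        spd <- .data$speed
        py <- .data$pos_y
        ab <- .data$abs_beta
        gz <- .data$joystick_gamma
        inw <- rel >= w$lower & rel < w$upper
        up <- min(w$upper, max(rel))
        tibble(
          mean_speed = mean(spd[inw]),
          distance_D = abs(
            approx(rel, py, xout = up, rule = 2)$y -
              approx(rel, py, xout = w$lower, rule = 2)$y
          ),
          mean_abs_beta = mean(ab[inw]),
          joystick_sd = sd(gz[inw]),
          v0 = approx(rel, spd, xout = w$lower, rule = 2)$y,
          max_abs_beta = max(ab[inw])
        )
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(hit = classify_hit(.data$mean_speed, .data$v0,
      tolerance = hit_tolerance
    ))

  if (!is.null(trials) && "obstacle_present" %in% names(trials)) {
    out <- out |>
      dplyr::left_join(
        dplyr::select(trials, dplyr::all_of(keys), "obstacle_present"),
        by = keys
      ) |>
      dplyr::mutate(
        ot_outcome = dplyr::if_else(
          ("task" %in% keys) & .data$task == "OT" &
            !is.na(.data$obstacle_present),
          classify_ot_outcome(.data$max_abs_beta, .data$obstacle_present),
          NA_character_
        )
      )
  } else {
    out$obstacle_present <- NA
    out$ot_outcome <- NA_character_
  }
  dplyr::select(out, -"max_abs_beta")
}

#' Participant-level summaries and pre-post change scores
#'
#' Averages each kinematic metric across the stated trial subsets per
#' participant and phase, and computes the pre-post training change
#' (Retention minus Baseline). Horizon-task metrics pool Hit and Missed
#' trials; Obstacle-task kinematic metrics use Obstacle trials only, while
#' the OT success rate and obstacle-avoidance inability use all trials.
#' Phases with an empty trial subset yield `NA`, never zero.
#'
#' @param metrics Per-trial metrics from [trial_metrics()] with `subject`,
#'   `phase` and `task` columns.
#' @return A tibble with one row per subject x task x metric: `baseline`,
#'   `retention`, and `change` (= retention - baseline). Group labels are
#'   carried through when present.
#' @export
summarize_participants <- function(metrics) {
  need <- c("subject", "phase", "task")
  if (!all(need %in% names(metrics))) {
    abort("`metrics` must carry subject, phase and task columns.",
      class = "alphasurf_input_error"
    )
  }
  grp <- intersect("group", names(metrics))

  kin_vars <- c("mean_speed", "distance_D", "mean_abs_beta", "joystick_sd")
  kin <- metrics |>
    dplyr::filter(.data$task != "OT" |
      (!is.na(.data$obstacle_present) & .data$obstacle_present)) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("subject", grp, "task", "phase")))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(kin_vars), ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(kin_vars),
      names_to = "metric", values_to = "value"
    )

  ot <- dplyr::filter(metrics, .data$task == "OT", !is.na(.data$ot_outcome))
  rates <- if (nrow(ot) > 0) {
    ot |>
      dplyr::group_by(dplyr::across(dplyr::all_of(c("subject", grp, "task", "phase")))) |>
      dplyr::summarise(ot_rates(.data$ot_outcome), .groups = "drop") |>
      tidyr::pivot_longer(c("success_rate", "avoidance_inability"),
        names_to = "metric", values_to = "value"
      )
  } else {
    NULL
  }

  dplyr::bind_rows(kin, rates) |>
    tidyr::pivot_wider(names_from = "phase", values_from = "value") |>
    dplyr::rename_with(tolower, dplyr::any_of(c("Baseline", "Retention"))) |>
    dplyr::mutate(change = .data$retention - .data$baseline) |>
    dplyr::arrange(.data$task, .data$metric, .data$subject)
}
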
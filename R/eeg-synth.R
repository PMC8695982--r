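#' Synthetic EEG generator configuration
#'
#' Desk-scale defaults for the epoched-EEG generator: three instruction
#' groups, epochs spanning one second either side of the incoming wave
#' onset, a 10 Hz alpha carrier with trial-random phase, additive pink
#' (1/f) and white noise per electrode, and a per-subject random amplitude
#' offset. The study-scale design (12 subjects per group, roughly 40-70
#' epochs per subject and phase) is available by raising the counts.
#'
#' @param subjects_per_group Subjects per instruction group. Default 4.
#' @param trials_per_cell Epochs per subject and (phase x trial-type) cell.
#'   Default 12.
#' @param fs Sampling rate, Hz. Default 250.
#' @param window Epoch window relative to onset, s. Default `c(-1, 1)`.
#' @param alpha_freq Alpha carrier frequency, Hz. Default 10 (mid 7-15 Hz
#'   band).
#' @param baseline_amp Baseline alpha envelope amplitude, uV. Default 10.
#' @param subject_sd SD of the per-subject amplitude offset, uV. Default 1.
#' @param pink_sd,white_sd Noise SDs, uV. Defaults 2 and 1.
#' @param n_electrodes Montage size. Default 32.
#' @param groups Group labels.
#' @param trial_types Trial-type labels (e.g. Hit/Missed for the free
#'   surfing task, Obstacle/NonObstacle for the obstacle task).
#' @return A list of class `surf_eeg_config`.
#' @export
synth_eeg_config <- function(subjects_per_group = 4,
                             trials_per_cell = 12,
                             fs = 250,
                             window = c(-1, 1),
                             alpha_freq = 10,
                             baseline_amp = 10,
                             subject_sd = 1,
                             pink_sd = 2,
                             white_sd = 1,
                             n_electrodes = 32,
                             groups = c("IMP", "E", "E-IMP"),
                             trial_types = c("Hit", "Missed")) {
  if (any(c(subject_sd, pink_sd, white_sd) < 0)) {
    abort("noise SDs must be non-negative.", class = "alphasurf_config_error")
  }
  if (window[1] >= window[2]) {
    abort("epoch window must have lower < upper.",
      class = "alphasurf_config_error"
    )
  }
  structure(
    list(
      subjects_per_group = subjects_per_group,
      trials_per_cell = trials_per_cell, fs = fs, window = window,
      alpha_freq = alpha_freq, baseline_amp = baseline_amp,
      subject_sd = subject_sd, pink_sd = pink_sd, white_sd = white_sd,
      n_electrodes = n_electrodes, groups = groups,
      trial_types = trial_types
    ),
    class = "surf_eeg_config"
  )
}

#' Topographic effect specification
#'
#' One planted condition effect: a spherical Gaussian patch on the scalp,
#' a smooth time window, and an amplitude delta (uV) per design cell.
#'
#' @param center Patch center: a unit 3-vector, or azimuth/elevation via
#'   [direction_vector()].
#' @param width Patch angular width (Gaussian sigma), radians.
#' @param deltas A tibble with columns `group`, `phase`, `trial_type`,
#'   `delta` (uV); unlisted cells get zero.
#' @param window Active time window relative to onset, s.
#' @param ramp Cosine ramp length of the time window, s. Default 0.05.
#' @return A list of class `surf_effect`.
#' @export
effect_spec <- function(center, width, deltas, window, ramp = 0.05) {
  if (width <= 0) {
    abort("patch `width` must be positive.", class = "alphasurf_config_error")
  }
  stopifnot(all(c("group", "phase", "trial_type", "delta") %in% names(deltas)))
  structure(
    list(
      center = center, width = width, deltas = tibble::as_tibble(deltas),
      window = window, ramp = ramp
    ),
    class = "surf_effect"
  )
}

# smooth 0/1 window with cosine ramps
smooth_window <- function(t, lo, hi, ramp = 0.05) {
  w <- numeric(length(t))
  core <- t >= lo + ramp & t <= hi - ramp
  w[core] <- 1
  up <- t >= lo & t < lo + ramp
  w[up] <- 0.5 * (1 - cos(pi * (t[up] - lo) / ramp))
  dn <- t > hi - ramp & t <= hi
  w[dn] <- 0.5 * (1 - cos(pi * (hi - t[dn]) / ramp))
  w
}

# pink (1/f amplitude) noise, one column per series, unit SD
pink_noise <- function(n, m) {
  white <- matrix(rnorm(n * m), n, m)
  k <- seq_len(n) - 1
  fk <- pmin(k, n - k) # symmetric shaping keeps the series real
  shape <- 1 / sqrt(pmax(fk, 1))
  sp <- stats::mvfft(white) * shape
  x <- Re(stats::mvfft(sp, inverse = TRUE)) / n
  sweep(x, 2, apply(x, 2, sd), `/`)
}

#' Planted topographic learning pattern
#'
#' Preset effect list encoding the expected instruction-dependent change in
#' the alpha-strength Hit-minus-Missed contrast after training: the
#' visually cued group (E-IMP) gains contrast over frontal, occipital and
#' right-parietal patches at Retention; the written-instruction group (E)
#' loses contrast over bilateral fronto-temporal patches at Retention; the
#' uninstructed group (IMP) carries no phase-dependent change. The active
#' window is -130 to 170 ms around the incoming wave onset.
#'
#' @param scale Contrast magnitude, uV. `scale = 0` yields a null pattern.
#' @param trial_types Length-2 labels; the first takes the positive half
#'   of the contrast.
#' @return A list of [effect_spec()] objects.
#' @export
plant_alpha_pattern <- function(scale, trial_types = c("Hit", "Missed")) {
  if (scale < 0) {
    abort("`scale` must be non-negative.", class = "alphasurf_config_error")
  }
  win <- c(-0.13, 0.17)
  half <- scale / 2
  eimp <- tidyr::expand_grid(
    group = "E-IMP", phase = "Retention", trial_type = trial_types
  )
  eimp$delta <- c(half, -half)
  e <- tidyr::expand_grid(
    group = "E", phase = "Retention", trial_type = trial_types
  )
  e$delta <- c(-half, half)
  centers_eimp <- list(
    direction_vector(0, 30), # frontal
    direction_vector(180, 20), # occipital
    direction_vector(100, 45) # right parietal
  )
  centers_e <- list(
    direction_vector(-70, 10), # left fronto-temporal
    direction_vector(70, 10) # right fronto-temporal
  )
  c(
    purrr::map(centers_eimp, ~ effect_spec(.x, 0.6, eimp, win)),
    purrr::map(centers_e, ~ effect_spec(.x, 0.6, e, win))
  )
}

#' Epoched EEG container
#'
#' @param data Numeric array, trials x electrodes x samples (uV).
#' @param fs Sampling rate, Hz.
#' @param window Epoch window relative to onset, s (`lower < 0 < upper`).
#' @param labels Tibble with one row per trial (at least `phase` and
#'   `trial_type`, or a `condition` column).
#' @param subject Subject id.
#' @param electrodes Electrode ids (defaults to dimnames or E001...).
#' @return A list of class `surf_epochs`.
#' @export
epoch_set <- function(data, fs, window, labels = NULL, subject = NA_character_,
                      electrodes = NULL) {
  stopifnot(length(dim(data)) == 3)
  if (!(window[1] < 0 && window[2] > 0)) {
    abort("epoch window must span the onset (lower < 0 < upper).",
      class = "alphasurf_config_error"
    )
  }
  if (is.null(labels)) {
    labels <- tibble(trial = seq_len(dim(data)[1]))
  }
  if (nrow(labels) != dim(data)[1]) {
    abort("`labels` must have one row per trial.",
      class = "alphasurf_input_error"
    )
  }
  electrodes <- electrodes %||% dimnames(data)[[2]] %||%
    sprintf("E%03d", seq_len(dim(data)[2]))
  structure(
    list(
      data = data, fs = fs, window = window,
      labels = tibble::as_tibble(labels), subject = subject,
      electrodes = electrodes
    ),
    class = "surf_epochs"
  )
}

#' @export
print.surf_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<surf_epochs> subject %s: %d trials x %d electrodes x %d samples @ %g Hz, window [%g, %g] s\n",
    x$subject, d[1], d[2], d[3], x$fs, x$window[1], x$window[2]
  ))
  invisible(x)
}

# time grid of an epoch window (half-open)
epoch_times <- function(window, fs) {
  n <- round((window[2] - window[1]) * fs)
  window[1] + (seq_len(n) - 1) / fs
}

#' Generate synthetic epoched EEG for a full design
#'
#' Per epoch and electrode the signal is an alpha carrier with a
#' spatially-and-temporally modulated amplitude envelope plus noise:
#' `x(e,t) = [A0 + u_subj + sum_k delta_k(cell) G_k(e) W_k(t)] *
#' sin(2 pi f t + phi_trial) + pink + white`, with `G_k` a spherical
#' Gaussian patch, `W_k` a smooth time window, `u_subj` a subject random
#' offset, and `phi_trial` a uniform random phase shared across electrodes
#' within a trial. Negative envelope values are clamped to zero with a
#' warning. Fully reproducible given `seed`.
#'
#' @param cfg A [synth_eeg_config()].
#' @param effects List of [effect_spec()] (e.g. [plant_alpha_pattern()]);
#'   empty list for a null generator.
#' @param montage A [make_montage()] with `cfg$n_electrodes` rows.
#' @param seed Integer seed.
#' @return A list of class `surf_eeg_cohort`: `epochs` (named list of
#'   [epoch_set()] per subject, labels covering phase x trial type),
#'   `design` (tibble subject/group), `montage`, `cfg`.
#' @export
synth_epochs <- function(cfg = synth_eeg_config(), effects = list(),
                         montage = make_montage(cfg$n_electrodes),
                         seed = 1) {
  stopifnot(inherits(cfg, "surf_eeg_config"))
  if (nrow(montage) != cfg$n_electrodes) {
    cfg$n_electrodes <- nrow(montage)
  }
  t <- epoch_times(cfg$window, cfg$fs)
  n_t <- length(t)
  n_e <- nrow(montage)
  cells <- tidyr::expand_grid(
    phase = c("Baseline", "Retention"),
    trial_type = cfg$trial_types
  )
  design <- tibble(
    subject = sprintf(
      "S%02d",
      seq_len(cfg$subjects_per_group * length(cfg$groups))
    ),
    group = rep(cfg$groups, each = cfg$subjects_per_group)
  )

  # precompute per-effect spatial weights and time windows
  eff_pre <- purrr::map(effects, function(ef) {
    list(
      g = patch_weights(montage, ef$center, ef$width),
      w = smooth_window(t, ef$window[1], ef$window[2], ef$ramp),
      deltas = ef$deltas
    )
  })
  clamped <- 0L

  epochs <- with_seed_(seed, {
    out <- vector("list", nrow(design))
    names(out) <- design$subject
    for (s in seq_len(nrow(design))) {
      u_subj <- rnorm(1, 0, cfg$subject_sd)
      n_trials <- cfg$trials_per_cell * nrow(cells)
      dat <- array(0, dim = c(n_trials, n_e, n_t))
      labels <- cells[rep(seq_len(nrow(cells)), each = cfg$trials_per_cell), ]
      labels$trial <- seq_len(n_trials)
      for (tr in seq_len(n_trials)) {
        cell <- labels[tr, ]
        env <- matrix(cfg$baseline_amp + u_subj, n_e, n_t)
        for (ep in eff_pre) {
          hit <- ep$deltas$group == design$group[s] &
            ep$deltas$phase == cell$phase &
            ep$deltas$trial_type == cell$trial_type
          if (any(hit)) {
            d <- sum(ep$deltas$delta[hit])
            env <- env + d * outer(ep$g, ep$w)
          }
        }
        if (any(env < 0)) {
          clamped <- clamped + 1L
          env[env < 0] <- 0
        }
        phase_rand <- runif(1, 0, 2 * pi)
        carrier <- sin(2 * pi * cfg$alpha_freq * t + phase_rand)
        sig <- sweep(env, 2, carrier, `*`)
        noise <- cfg$pink_sd * t(pink_noise(n_t, n_e)) +
          cfg$white_sd * matrix(rnorm(n_e * n_t), n_e, n_t)
        dat[tr, , ] <- sig + noise
      }
      dimnames(dat) <- list(NULL, montage$electrode, NULL)
      out[[s]] <- epoch_set(dat, cfg$fs, cfg$window,
        labels = labels,
        subject = design$subject[s], electrodes = montage$electrode
      )
    }
    out
  })
  if (clamped > 0) {
    warn(sprintf(
      "negative amplitude envelope clamped to 0 in %d epochs", clamped
    ))
  }
  structure(
    list(epochs = epochs, design = design, montage = montage, cfg = cfg),
    class = "surf_eeg_cohort"
  )
}

#' @export
print.surf_eeg_cohort <- function(x, ...) {
  cat(sprintf(
    "<surf_eeg_cohort> %d subjects (%s), %d electrodes, fs %g Hz\n",
    length(x$epochs), paste(unique(x$design$group), collapse = "/"),
    nrow(x$montage), x$cfg$fs
  ))
  invisible(x)
}
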
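# ---- zero-phase FIR filtering -------------------------------------------

# Hamming windowed-sinc FIR taps; length from the transition width
fir_taps <- function(fs, cutoff, type = c("low", "pass"), trans = 2) {
  type <- match.arg(type)
  ntaps <- ceiling(3.3 * fs / trans) # Hamming window transition ~3.3/N
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  w <- cutoff / (fs / 2)
  if (type == "low") {
    as.numeric(signal::fir1(ntaps - 1, w, type = "low"))
  } else {
    as.numeric(signal::fir1(ntaps - 1, w, type = "pass"))
  }
}

# Zero-phase linear-phase FIR filtering of matrix columns.
# Mirror-pads each column by the filter length, convolves by FFT, and
# compensates the exact (ntaps-1)/2 group delay of the symmetric taps.
filter_cols_fir <- function(X, taps) {
  X <- as.matrix(X)
  n <- nrow(X)
  ntaps <- length(taps)
  p <- min(ntaps, n - 1)
  Xp <- rbind(
    X[(p + 1):2, , drop = FALSE],
    X,
    X[(n - 1):(n - p), , drop = FALSE]
  )
  np <- nrow(Xp)
  nfft <- stats::nextn(np + ntaps - 1, 2)
  H <- fft(c(taps, numeric(nfft - ntaps)))
  Xpad <- rbind(Xp, matrix(0, nfft - np, ncol(X)))
  Y <- Re(stats::mvfft(stats::mvfft(Xpad) * H, inverse = TRUE)) / nfft
  d <- (ntaps - 1) / 2
  Y[p + d + seq_len(n), , drop = FALSE]
}

# ---- epoch extraction ----------------------------------------------------

#' Extract epochs from a continuous multichannel recording
#'
#' Cuts one epoch per event, aligning epoch time 0 to the event sample.
#' The sample interval is half-open: an epoch window `[-1, 1)` s at 250 Hz
#' yields 500 samples starting 250 samples before the event. Events whose
#' window does not fit inside the recording are rejected and counted.
#'
#' @param x Numeric matrix, electrodes x samples (continuous recording),
#'   or samples x electrodes with `channels_first = FALSE`.
#' @param events Integer event sample indices (1-based).
#' @param window Epoch window, s relative to the event.
#' @param fs Sampling rate, Hz.
#' @param channels_first Whether `x` is electrodes x samples. Default TRUE.
#' @return A [epoch_set()]; the number of rejected events is attached as
#'   attribute `rejected`.
#' @export
extract_epochs <- function(x, events, window = c(-1, 1), fs,
                           channels_first = TRUE) {
  if (!channels_first) x <- t(x)
  n_s <- ncol(x)
  off_lo <- round(window[1] * fs)
  n_t <- round((window[2] - window[1]) * fs)
  starts <- events + off_lo
  ok <- starts >= 1 & (starts + n_t - 1) <= n_s
  rejected <- sum(!ok)
  starts <- starts[ok]
  dat <- array(0, dim = c(length(starts), nrow(x), n_t))
  for (k in seq_along(starts)) {
    dat[k, , ] <- x[, starts[k] + seq_len(n_t) - 1]
  }
  es <- epoch_set(dat, fs, window,
    labels = tibble(trial = seq_along(starts), event_sample = events[ok])
  )
  attr(es, "rejected") <- rejected
  es
}

# ---- TSE transform -------------------------------------------------------

#' Temporal-spectral evolution of the alpha band
#'
#' Computes the temporal-spectral-evolution (TSE) transform per trial and
#' electrode: zero-phase band-pass to the alpha band, full-wave
#' rectification, then zero-phase low-pass smoothing at half the band's
#' low-cut frequency. The result is a smooth, non-negative amplitude (uV)
#' map of band-limited strength per electrode over time; small negative
#' values produced by the smoothing filter are clamped to zero and
#' counted. With `average = TRUE` trials are averaged within each
#' phase x trial-type cell of the epoch labels.
#'
#' @param epochs A [epoch_set()].
#' @param band Pass band, Hz. Default `c(7, 15)`.
#' @param smooth_cutoff Low-pass smoothing cutoff, Hz. Default half the
#'   band low-cut (3.5 Hz).
#' @param trans FIR transition width, Hz. Default 2.
#' @param average Average trials within condition cells. Default TRUE.
#' @return With `average = TRUE`, a list of class `surf_tse`: `maps`
#'   (named list of electrodes x samples matrices per condition), `counts`
#'   (trials per condition), `band`, `smooth_cutoff`, `fs`, `times`,
#'   `electrodes`, `subject`, `n_clamped`. With `average = FALSE`, the
#'   per-trial array (trials x electrodes x samples) with the same
#'   metadata.
#' @export
tse_transform <- function(epochs, band = c(7, 15),
                          smooth_cutoff = band[1] / 2, trans = 2,
                          average = TRUE) {
  stopifnot(inherits(epochs, "surf_epochs"))
  fs <- epochs$fs
  if (fs <= 2 * band[2]) {
    abort("sampling rate must exceed twice the band's upper edge.",
      class = "alphasurf_config_error"
    )
  }
  d <- dim(epochs$data)
  n_trial <- d[1]
  n_e <- d[2]
  n_t <- d[3]
  # time x (trial*electrode) matrix
  X <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_t)
  bp <- fir_taps(fs, band, type = "pass", trans = trans)
  lp <- fir_taps(fs, smooth_cutoff, type = "low", trans = trans)
  Y <- filter_cols_fir(abs(filter_cols_fir(X, bp)), lp)
  n_clamped <- sum(Y < 0)
  Y[Y < 0] <- 0
  tse <- aperm(array(Y, dim = c(n_t, n_trial, n_e)), c(2, 3, 1))
  dimnames(tse) <- list(NULL, epochs$electrodes, NULL)
  out <- list(
    data = tse, band = band, smooth_cutoff = smooth_cutoff, fs = fs,
    times = epoch_times(epochs$window, fs), electrodes = epochs$electrodes,
    labels = epochs$labels, subject = epochs$subject, n_clamped = n_clamped
  )
  class(out) <- "surf_tse_trials"
  if (average) average_conditions(out) else out
}

#' Average per-trial TSE maps within condition cells
#'
#' Arithmetic mean of per-trial TSE maps over the trials of each condition
#' cell; cell trial counts are reported alongside. Cells without trials
#' are flagged missing (absent from the output with a warning), never
#' zero-filled.
#'
#' @param tse_trials A `surf_tse_trials` from
#'   `tse_transform(average = FALSE)`.
#' @param by Label columns defining the cells. Defaults to the
#'   phase/trial-type columns present, else all trials pooled.
#' @return A list of class `surf_tse` (see [tse_transform()]).
#' @export
average_conditions <- function(tse_trials,
                               by = intersect(
                                 c("phase", "trial_type"),
                                 names(tse_trials$labels)
                               )) {
  stopifnot(inherits(tse_trials, "surf_tse_trials"))
  labs <- tse_trials$labels
  if (length(by) == 0) {
    labs$condition <- "all"
    by <- "condition"
  }
  key <- do.call(paste, c(labs[by], sep = "."))
  maps <- list()
  counts <- integer()
  for (k in unique(key)) {
    idx <- which(key == k)
    m <- apply(tse_trials$data[idx, , , drop = FALSE], c(2, 3), mean)
    maps[[k]] <- m
    counts[k] <- length(idx)
  }
  structure(
    list(
      maps = maps, counts = counts, band = tse_trials$band,
      smooth_cutoff = tse_trials$smooth_cutoff, fs = tse_trials$fs,
      times = tse_trials$times, electrodes = tse_trials$electrodes,
      subject = tse_trials$subject, n_clamped = tse_trials$n_clamped,
      by = by
    ),
    class = "surf_tse"
  )
}

#' @export
print.surf_tse <- function(x, ...) {
  cat(sprintf(
    "<surf_tse> subject %s: %d conditions (%s), %d electrodes x %d samples, band %g-%g Hz\n",
    x$subject, length(x$maps), paste(names(x$maps), collapse = ", "),
    length(x$electrodes), length(x$times), x$band[1], x$band[2]
  ))
  invisible(x)
}

#' TSE condition maps for a whole cohort
#'
#' Runs [tse_transform()] on every subject of a synthetic (or loaded) EEG
#' cohort and assembles the subject x condition TSE maps into the tidy
#' table the topographic ANOVA consumes.
#'
#' @param eeg A `surf_eeg_cohort` from [synth_epochs()].
#' @param ... Passed to [tse_transform()].
#' @return A tibble of class `surf_tse_tbl`: `subject`, `group`, `phase`,
#'   `trial_type`, `n_trials`, `map` (list-column of electrodes x samples
#'   matrices); epoch times and electrode ids are attached as attributes
#'   `times` and `electrodes`.
#' @export
tse_cohort <- function(eeg, ...) {
  stopifnot(inherits(eeg, "surf_eeg_cohort"))
  rows <- purrr::imap(eeg$epochs, function(ep, sid) {
    ts <- tse_transform(ep, ...)
    cells <- strsplit(names(ts$maps), ".", fixed = TRUE)
    tibble(
      subject = sid,
      group = eeg$design$group[match(sid, eeg$design$subject)],
      phase = vapply(cells, `[`, "", 1),
      trial_type = vapply(cells, `[`, "", 2),
      n_trials = unname(ts$counts),
      map = unname(ts$maps)
    )
  })
  out <- dplyr::bind_rows(rows)
  ep1 <- eeg$epochs[[1]]
  attr(out, "times") <- epoch_times(ep1$window, ep1$fs)
  attr(out, "electrodes") <- ep1$electrodes
  class(out) <- c("surf_tse_tbl", class(out))
  out
}
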
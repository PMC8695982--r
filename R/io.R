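# ---- tabular formats -----------------------------------------------------

#' Read and write package tables as CSV
#'
#' Thin, schema-checked wrappers around readr for the package's tabular
#' artifacts: kinematics logs, onset event markers, per-trial metrics,
#' electrode montages and t maps. Each reader validates the expected
#' columns and returns a typed tibble; each writer returns its input
#' invisibly so calls can be piped.
#'
#' @param x The object to write.
#' @param path File path.
#' @name surf_csv
NULL

kinematics_cols <- c(
  "time", "pos_x", "pos_y", "vel_x", "vel_y", "heading_alpha",
  "pitch_phi", "accel_aw", "joystick_gamma", "wave_dir_omega"
)

check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0) {
    abort(
      sprintf(
        "%s is missing column(s): %s", what,
        paste(miss, collapse = ", ")
      ),
      class = "alphasurf_schema_error"
    )
  }
  df
}

#' @rdname surf_csv
#' @export
write_kinematics_csv <- function(x, path) {
  check_cols(x, kinematics_cols, "kinematics log")
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname surf_csv
#' @export
read_kinematics_csv <- function(path) {
  check_cols(
    readr::read_csv(path, show_col_types = FALSE),
    kinematics_cols, "kinematics log"
  )
}

#' @rdname surf_csv
#' @export
write_events_csv <- function(x, path) {
  check_cols(x, c("trial", "sample", "label"), "event table")
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname surf_csv
#' @export
read_events_csv <- function(path) {
  check_cols(
    readr::read_csv(path, show_col_types = FALSE),
    c("trial", "sample", "label"), "event table"
  )
}

#' @rdname surf_csv
#' @export
write_metrics_csv <- function(x, path) {
  check_cols(x, c("mean_speed", "distance_D", "joystick_sd"), "metrics table")
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname surf_csv
#' @export
read_metrics_csv <- function(path) {
  check_cols(
    readr::read_csv(path, show_col_types = FALSE),
    c("mean_speed", "distance_D", "joystick_sd"), "metrics table"
  )
}

#' @rdname surf_csv
#' @export
write_montage_csv <- function(x, path) {
  check_cols(x, c("electrode", "x", "y", "z", "region"), "montage")
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname surf_csv
#' @export
read_montage_csv <- function(path) {
  out <- check_cols(
    readr::read_csv(path, show_col_types = FALSE),
    c("electrode", "x", "y", "z", "region"), "montage"
  )
  class(out) <- c("surf_montage", class(out))
  out
}

#' @rdname surf_csv
#' @export
write_tmap_csv <- function(x, path) {
  check_cols(x, c("electrode", "t", "masked"), "t map")
  readr::write_csv(x, path)
  invisible(x)
}

#' @rdname surf_csv
#' @export
read_tmap_csv <- function(path) {
  out <- check_cols(
    readr::read_csv(path, show_col_types = FALSE),
    c("electrode", "t", "masked"), "t map"
  )
  class(out) <- c("surf_tmap", class(out))
  out
}

# ---- epoch container -----------------------------------------------------

#' Epoched-EEG directory container
#'
#' Stores an [epoch_set()] as a plain-text directory: `meta.json`
#' (sampling rate, epoch window, electrode ids, subject, trial labels)
#' plus `data.csv` holding the tensor in long form (`trial`, `electrode`,
#' `sample`, `value`). The round trip preserves values to single
#' precision. TSE condition maps use the same layout with one map per
#' condition.
#'
#' @param x An [epoch_set()].
#' @param dir Container directory (created if needed).
#' @return `read_epochs()` returns an [epoch_set()]; writers return the
#'   input invisibly.
#' @export
write_epochs <- function(x, dir) {
  stopifnot(inherits(x, "surf_epochs"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    fs = x$fs, window = x$window, electrodes = x$electrodes,
    subject = x$subject, labels = x$labels, dim = dim(x$data)
  )
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  d <- dim(x$data)
  long <- tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    electrode = rep(rep(x$electrodes, each = d[1]), times = d[3]),
    sample = rep(seq_len(d[3]), each = d[1] * d[2]),
    value = signif(as.vector(x$data), 8)
  )
  readr::write_csv(long, file.path(dir, "data.csv"))
  invisible(x)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
    simplifyVector = TRUE
  )
  long <- readr::read_csv(file.path(dir, "data.csv"),
    show_col_types = FALSE
  )
  check_cols(long, c("trial", "electrode", "sample", "value"), "epoch data")
  d <- as.integer(meta$dim)
  dat <- array(long$value, dim = d)
  dimnames(dat) <- list(NULL, meta$electrodes, NULL)
  epoch_set(dat, meta$fs, as.numeric(meta$window),
    labels = tibble::as_tibble(meta$labels), subject = meta$subject,
    electrodes = meta$electrodes
  )
}

# ---- results -------------------------------------------------------------

#' Write and read TANOVA results as JSON
#'
#' Serializes a [tanova_pointwise()] result (p series, observed
#' statistic, critical duration, significant windows) to JSON and back.
#'
#' @param x A `surf_tanova`.
#' @param path JSON file path.
#' @export
write_tanova_json <- function(x, path) {
  stopifnot(inherits(x, "surf_tanova"))
  jsonlite::write_json(
    list(
      effect = x$effect, n_perm = x$n_perm, alpha = x$alpha,
      critical_duration_ms = x$critical_duration_ms,
      series = x$series, windows = x$windows
    ),
    path,
    auto_unbox = TRUE, digits = NA, dataframe = "columns"
  )
  invisible(x)
}

#' @rdname write_tanova_json
#' @export
read_tanova_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      series = tibble::as_tibble(j$series),
      critical_duration_ms = j$critical_duration_ms,
      windows = tibble::as_tibble(j$windows),
      effect = j$effect, n_perm = j$n_perm, alpha = j$alpha
    ),
    class = "surf_tanova"
  )
}
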
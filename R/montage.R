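#' Idealized electrode montage
#'
#' Lays out `n` electrodes on the upper unit hemisphere with a Fibonacci
#' (golden-angle) lattice and labels each with a scalp region (frontal,
#' central, temporal-left, temporal-right, parietal, occipital) by angular
#' sector. The layout is deterministic. Coordinates use +y toward the
#' nose, +x toward the right ear, +z toward the vertex.
#'
#' @param n Number of electrodes (>= 8).
#' @return A tibble of class `surf_montage`: `electrode`, `x`, `y`, `z`
#'   (unit norm), `region`.
#' @export
#' @examples
#' make_montage(32)
make_montage <- function(n) {
  if (!is.numeric(n) || n < 8) {
    abort("need at least 8 electrodes.", class = "alphasurf_config_error")
  }
  n <- as.integer(n)
  i <- seq_len(n)
  z <- (i - 0.5) / n # uniform in area over the upper hemisphere
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  az <- (i - 1) * golden
  x <- r * sin(az)
  y <- r * cos(az)
  elev_deg <- asin(z) * 180 / pi
  az_deg <- atan2(x, y) * 180 / pi # 0 = front, positive = right
  region <- dplyr::case_when(
    elev_deg >= 65 ~ "central",
    abs(az_deg) <= 55 ~ "frontal",
    abs(az_deg) >= 125 ~ "occipital",
    elev_deg >= 30 ~ "parietal",
    az_deg > 0 ~ "temporal-right",
    TRUE ~ "temporal-left"
  )
  out <- tibble(
    electrode = sprintf("E%03d", i),
    x = x, y = y, z = z, region = region
  )
  class(out) <- c("surf_montage", class(out))
  out
}

# unit direction from azimuth (deg, 0 = front, + = right) and elevation (deg)
direction_vector <- function(az_deg, elev_deg) {
  az <- az_deg * pi / 180
  el <- elev_deg * pi / 180
  c(x = cos(el) * sin(az), y = cos(el) * cos(az), z = sin(el))
}

# spherical Gaussian patch weights on montage electrodes
patch_weights <- function(montage, center, width) {
  m <- as.matrix(montage[, c("x", "y", "z")])
  center <- center / sqrt(sum(center^2))
  ang <- acos(pmin(pmax(as.vector(m %*% center), -1), 1))
  exp(-0.5 * (ang / width)^2)
}
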
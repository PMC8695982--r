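#' Tidy a pointwise TANOVA result
#'
#' @param x A `surf_tanova`.
#' @param ... Unused.
#' @return A tibble with one row per time point: `time`, `stat`, `p`,
#'   `significant` (inside a supra-critical-duration window).
#' @export
tidy.surf_tanova <- function(x, ...) {
  sig <- rep(FALSE, nrow(x$series))
  if (nrow(x$windows) > 0) {
    for (k in seq_len(nrow(x$windows))) {
      sig <- sig | (x$series$time >= x$windows$start[k] &
        x$series$time <= x$windows$end[k])
    }
  }
  dplyr::mutate(x$series, significant = sig, effect = x$effect)
}

#' One-row summary of a pointwise TANOVA result
#'
#' @inheritParams tidy.surf_tanova
#' @return A one-row tibble: `effect`, `min_p`, `critical_duration_ms`,
#'   `n_windows`, `n_perm`, `alpha`.
#' @export
glance.surf_tanova <- function(x, ...) {
  tibble(
    effect = x$effect,
    min_p = min(x$series$p),
    critical_duration_ms = x$critical_duration_ms,
    n_windows = nrow(x$windows),
    n_perm = x$n_perm,
    alpha = x$alpha
  )
}

#' Tidy a between-group test battery result
#'
#' @param x A `surf_group_test`.
#' @param ... Unused.
#' @return Omnibus and post-hoc rows stacked in one tibble.
#' @export
tidy.surf_group_test <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$omnibus, comparison = "omnibus"),
    dplyr::mutate(x$posthoc, branch = x$omnibus$branch)
  )
}

#' @rdname tidy.surf_group_test
#' @export
glance.surf_group_test <- function(x, ...) {
  dplyr::mutate(x$omnibus,
    any_posthoc = any(x$posthoc$p_value < x$alpha, na.rm = TRUE)
  )
}

#' Plot a pointwise TANOVA p series
#'
#' Time course of the pointwise randomization p values with the
#' sub-threshold level and supra-critical-duration windows shaded.
#'
#' @param object A `surf_tanova`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surf_tanova <- function(object, ...) {
  df <- tidy(object)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$p))
  if (nrow(object$windows) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = object$windows,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = 0, ymax = 1
      ),
      inherit.aes = FALSE, fill = "gold", alpha = 0.35
    )
  }
  gg +
    ggplot2::geom_line() +
    ggplot2::geom_hline(
      yintercept = object$alpha,
      linetype = "dashed", colour = "red"
    ) +
    ggplot2::labs(
      x = "time from incoming wave onset (s)", y = "pointwise p",
      title = paste("TANOVA:", object$effect),
      subtitle = sprintf(
        "critical duration %.0f ms, %d permutations",
        object$critical_duration_ms, object$n_perm
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot an electrode t map on the flattened scalp
#'
#' Projects the montage onto the horizontal plane and colours each
#' electrode by its t value; electrodes past the masking threshold are
#' ringed.
#'
#' @param object A `surf_tmap`.
#' @param montage The [make_montage()] the contrasts were computed on.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surf_tmap <- function(object, montage, ...) {
  df <- dplyr::inner_join(object, montage, by = "electrode")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$t), size = 4) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$masked),
      shape = 21, size = 6, stroke = 1.1, colour = "black"
    ) +
    ggplot2::scale_colour_gradient2(
      low = "blue", mid = "white", high = "red"
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "left-right", y = "back-front",
      title = "electrode t map",
      subtitle = sprintf(
        "|t| > %.2f ringed", attr(object, "threshold") %||% 2.36
      )
    ) +
    ggplot2::theme_minimal()
}

#' Boxplots of pre-post change scores by group
#'
#' One panel per metric, mirroring the standard presentation of pre-post
#' training behavioural changes.
#'
#' @param summary_tbl Output of [summarize_participants()].
#' @param task Task to display. Default `"HT"`.
#' @return A ggplot object.
#' @export
plot_change_scores <- function(summary_tbl, task = "HT") {
  df <- dplyr::filter(summary_tbl, .data$task == !!task)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$group, y = .data$change,
    fill = .data$group
  )) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.shape = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "pre-post training change",
      title = paste(task, "task: change scores by instruction group")
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
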
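#' Within-group pre-post change test
#'
#' Two-sided Wilcoxon signed-rank test on the Retention minus Baseline
#' change scores of one group. The exact null distribution is used up to
#' n = 25 when the differences are free of ties and zeros; otherwise the
#' normal approximation with tie correction applies.
#'
#' @param baseline,retention Paired values; alternatively pass the
#'   differences as `baseline` and leave `retention = NULL`.
#' @return A one-row tibble: `test`, `statistic`, `p_value`, `n`,
#'   `degenerate` (TRUE when all differences are zero).
#' @export
#' @examples
#' within_group_change_test(rnorm(12), rnorm(12, 0.5))
within_group_change_test <- function(baseline, retention = NULL) {
  d <- if (is.null(retention)) baseline else retention - baseline
  d <- d[!is.na(d)]
  if (length(d) < 5) {
    abort("need at least 5 paired observations.",
      class = "alphasurf_input_error"
    )
  }
  if (all(d == 0)) {
    warn("all differences are zero; signed-rank test is degenerate.")
    return(tibble(
      test = "wilcoxon_signed_rank", statistic = NA_real_,
      p_value = NA_real_, n = length(d), degenerate = TRUE
    ))
  }
  nz <- d[d != 0]
  exact <- length(nz) <= 25 && !any(duplicated(abs(nz)))
  wt <- suppressWarnings(
    wilcox.test(d, mu = 0, exact = exact, correct = !exact)
  )
  tibble(
    test = "wilcoxon_signed_rank",
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n = length(d),
    degenerate = FALSE
  )
}

#' Effect size for a two-group contrast
#'
#' Pooled-SD Cohen's d and its r transform, `r = d / sqrt(d^2 + 4)`.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return A one-row tibble: `cohens_d`, `r`, `n_a`, `n_b`; both are `NA`
#'   (with a warning) when the pooled SD is zero.
#' @export
#' @examples
#' effect_size(rnorm(12), rnorm(12, 1))
effect_size <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    abort("each sample needs at least 2 values.",
      class = "alphasurf_input_error"
    )
  }
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  if (sp2 <= 0) {
    warn("zero pooled SD; effect size undefined.")
    d <- NA_real_
  } else {
    d <- (mean(a) - mean(b)) / sqrt(sp2)
  }
  tibble(
    cohens_d = d, r = d / sqrt(d^2 + 4),
    n_a = length(a), n_b = length(b)
  )
}

#' Between-group test battery on change scores
#'
#' Compares pre-post change scores across instruction groups with the
#' study's assumption-gated battery: Kolmogorov-Smirnov normality checks
#' (Lilliefors form, estimated parameters) per group and Levene's
#' homogeneity test decide between the parametric branch (one-way ANOVA
#' followed by Tukey-Kramer post-hoc comparisons) and the nonparametric
#' branch (Kruskal-Wallis followed by Holm-corrected pairwise
#' Mann-Whitney U tests). A group with zero variance forces the
#' nonparametric branch. Effect sizes (Cohen's d and its r transform) are
#' attached to every pairwise comparison.
#'
#' @param data A data frame with the value and group columns.
#' @param value,group Column names (strings). Defaults `"change"`,
#'   `"group"`.
#' @param alpha Significance level for the omnibus and post-hoc decisions.
#'   Default 0.05.
#' @return A list of class `surf_group_test`: `omnibus` (one-row tibble:
#'   branch, test, statistic, df, p_value), `posthoc` (tibble of pairwise
#'   comparisons with adjusted p and effect sizes), `assumptions` (the
#'   gate results).
#' @export
between_group_test <- function(data, value = "change", group = "group",
                               alpha = 0.05) {
  x <- data[[value]]
  g <- factor(data[[group]])
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]
  g <- droplevels(g[ok])
  if (nlevels(g) < 2 || any(table(g) < 3)) {
    abort("need >= 2 groups with >= 3 observations each.",
      class = "alphasurf_input_error"
    )
  }

  zero_var <- tapply(x, g, function(v) var(v) == 0)
  if (any(zero_var)) {
    warn("a group has zero variance; using the nonparametric branch.")
    normal <- FALSE
    ks_p <- rep(NA_real_, nlevels(g))
    lev_p <- NA_real_
  } else {
    ks_p <- vapply(
      split(x, g),
      function(v) nortest::lillie.test(v)$p.value, numeric(1)
    )
    lev_p <- car::leveneTest(x ~ g)[1, "Pr(>F)"]
    normal <- all(ks_p >= 0.05) && lev_p > 0.05
  }
  assumptions <- tibble(
    check = c(paste0("ks_normality_", levels(g)), "levene_homogeneity"),
    p_value = c(ks_p, lev_p)
  )

  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  es <- purrr::map(pairs, function(pr) {
    effect_size(x[g == pr[1]], x[g == pr[2]])
  })

  if (normal) {
    fit <- aov(x ~ g)
    an <- summary(fit)[[1]]
    omnibus <- tibble(
      branch = "parametric", test = "one_way_anova",
      statistic = an[["F value"]][1],
      df = paste(an[["Df"]], collapse = ","),
      p_value = an[["Pr(>F)"]][1]
    )
    tk <- TukeyHSD(fit)$g
    posthoc <- tibble(
      comparison = rownames(tk),
      test = "tukey_kramer",
      estimate = tk[, "diff"],
      p_value = tk[, "p adj"]
    )
    # align effect sizes with Tukey's "b-a" comparison labels (flip sign)
    lab <- vapply(pairs, function(pr) paste(pr[2], pr[1], sep = "-"), "")
    es_tk <- dplyr::bind_rows(es)[match(posthoc$comparison, lab), ]
    posthoc <- dplyr::bind_cols(
      posthoc,
      dplyr::mutate(es_tk[, c("cohens_d", "r")],
        cohens_d = -.data$cohens_d, r = -.data$r
      )
    )
  } else {
    kw <- kruskal.test(x ~ g)
    omnibus <- tibble(
      branch = "nonparametric", test = "kruskal_wallis",
      statistic = unname(kw$statistic),
      df = as.character(unname(kw$parameter)),
      p_value = kw$p.value
    )
    raw <- vapply(pairs, function(pr) {
      suppressWarnings(
        wilcox.test(x[g == pr[1]], x[g == pr[2]], exact = FALSE)$p.value
      )
    }, numeric(1))
    posthoc <- tibble(
      comparison = vapply(pairs, paste, "", collapse = "-"),
      test = "mann_whitney_holm",
      estimate = vapply(pairs, function(pr) {
        median(x[g == pr[1]]) - median(x[g == pr[2]])
      }, numeric(1)),
      p_value = p.adjust(raw, method = "holm")
    )
    posthoc <- dplyr::bind_cols(
      posthoc,
      dplyr::bind_rows(es)[, c("cohens_d", "r")]
    )
  }
  structure(
    list(
      omnibus = omnibus,
      posthoc = posthoc,
      assumptions = assumptions,
      alpha = alpha
    ),
    class = "surf_group_test"
  )
}

#' @export
print.surf_group_test <- function(x, ...) {
  cat("<surf_group_test>\n")
  print(x$omnibus)
  if (x$omnibus$p_value < x$alpha) {
    cat("post-hoc comparisons:\n")
    print(x$posthoc)
  } else {
    cat(sprintf("omnibus p >= %g; post-hocs not indicated\n", x$alpha))
  }
  invisible(x)
}

#' Behavioural test battery over all metrics
#'
#' Applies [within_group_change_test()] per group and
#' [between_group_test()] across groups to every (task, metric) change
#' score in a participant summary table, mirroring the layout of a
#' pre-post training comparison table.
#'
#' @param summary_tbl Output of [summarize_participants()] (needs `group`).
#' @param alpha Significance level. Default 0.05.
#' @return A tibble with one row per task x metric x test.
#' @export
behaviour_test_battery <- function(summary_tbl, alpha = 0.05) {
  stopifnot("group" %in% names(summary_tbl))
  summary_tbl |>
    dplyr::filter(!is.na(.data$change)) |>
    dplyr::group_by(.data$task, .data$metric) |>
    dplyr::group_modify(function(df, key) {
      within <- df |>
        dplyr::group_by(.data$group) |>
        dplyr::group_modify(function(gdf, gkey) {
          if (nrow(gdf) < 5) { # too few pairs for a signed-rank test
            return(tibble(
              test = "wilcoxon_signed_rank", statistic = NA_real_,
              p_value = NA_real_, n = nrow(gdf), degenerate = NA
            ))
          }
          within_group_change_test(gdf$change)
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(comparison = .data$group, .keep = "unused")
      bt <- between_group_test(df, alpha = alpha)
      between <- dplyr::bind_rows(
        dplyr::mutate(bt$omnibus,
          comparison = "omnibus",
          statistic = .data$statistic, n = nrow(df)
        ),
        dplyr::mutate(bt$posthoc, branch = bt$omnibus$branch, n = nrow(df))
      )
      dplyr::bind_rows(
        dplyr::mutate(within, branch = "within"),
        between
      )
    }) |>
    dplyr::ungroup()
}
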
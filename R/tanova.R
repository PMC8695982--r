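# ---- design preparation --------------------------------------------------
#
# The TANOVA operates on a tidy table of subject x condition topographic
# map series (electrodes x samples matrices in a `map` list-column), with
# an optional between-subject `group` column and within-subject factor
# columns `phase` and/or `trial_type`. Internally maps are flattened to a
# rows x (electrode*time) matrix; cell means are recovered with rowsum()
# and ANOVA components with Kronecker-built projectors, so the same code
# path serves observed and permuted datasets.

tanova_prep <- function(data) {
  stopifnot(is.data.frame(data), all(c("subject", "map") %in% names(data)))
  within_all <- intersect(c("phase", "trial_type"), names(data))
  within <- within_all[vapply(
    within_all,
    function(f) length(unique(data[[f]])) > 1, logical(1)
  )]
  has_group <- "group" %in% names(data) &&
    length(unique(data$group)) > 1

  lev <- lapply(within, function(f) sort(unique(data[[f]])))
  names(lev) <- within
  n_cells <- prod(vapply(lev, length, integer(1)), 1)

  cell_of <- function(df) {
    if (length(within) == 0) {
      return(rep(1L, nrow(df)))
    }
    idx <- rep(1L, nrow(df))
    mult <- 1L
    for (f in rev(within)) { # last factor fastest
      k <- match(df[[f]], lev[[f]]) - 1L
      idx <- idx + k * mult
      mult <- mult * length(lev[[f]])
    }
    idx
  }
  data$cell <- cell_of(data)

  # drop subjects missing any within cell
  counts <- table(data$subject, data$cell)
  complete <- rownames(counts)[apply(counts == 1, 1, all)]
  if (length(complete) < length(unique(data$subject))) {
    warn(sprintf(
      "%d subject(s) excluded: incomplete within-subject cells",
      length(unique(data$subject)) - length(complete)
    ))
    data <- data[data$subject %in% complete, , drop = FALSE]
  }
  data <- data[order(data$subject, data$cell), , drop = FALSE]

  subjects <- unique(data$subject)
  subj_idx <- match(data$subject, subjects)
  groups <- if (has_group) {
    g <- data$group[match(subjects, data$subject)]
    factor(g, levels = sort(unique(g)))
  } else {
    factor(rep("all", length(subjects)))
  }

  dims <- dim(data$map[[1]])
  Y <- t(vapply(data$map, as.vector, numeric(prod(dims))))

  list(
    Y = Y, subjects = subjects, subj_idx = subj_idx, groups = groups,
    cell = data$cell, n_cells = n_cells, within = within, lev = lev,
    n_e = dims[1], n_t = dims[2],
    times = attr(data, "times", exact = TRUE)
  )
}

# averaging (J/n) and centering (I - J/n) blocks
avg_mat <- function(n) matrix(1 / n, n, n)
ctr_mat <- function(n) diag(n) - avg_mat(n)

# projector onto an effect's component, cells ordered group-slowest
tanova_projector <- function(effect_factors, sizes) {
  P <- matrix(1, 1, 1)
  for (f in names(sizes)) {
    blk <- if (f %in% effect_factors) ctr_mat(sizes[f]) else avg_mat(sizes[f])
    P <- P %x% blk
  }
  P
}

parse_effect <- function(effect, prep) {
  fac <- strsplit(effect, ":", fixed = TRUE)[[1]]
  avail <- c(
    if (nlevels(prep$groups) > 1) "group",
    prep$within
  )
  if (!all(fac %in% avail)) {
    abort(
      sprintf(
        "effect `%s` not available; factors present: %s",
        effect, paste(avail, collapse = ", ")
      ),
      class = "alphasurf_input_error"
    )
  }
  fac
}

# observed / permuted effect statistic series.
# cell: per-row within-cell index; grp_row: per-row group index.
tanova_stat <- function(Y, cell, grp_row, n_groups, n_cells, P, n_e, n_t) {
  code <- (grp_row - 1L) * n_cells + cell
  K <- n_groups * n_cells
  Z <- rowsum(Y, code, reorder = TRUE)
  cnt <- tabulate(code, nbins = K)
  Z <- Z / cnt # every code occurs: each subject has all cells
  C <- P %*% Z
  s2 <- colSums(C * C)
  dim(s2) <- c(n_e, n_t)
  sqrt(colSums(s2) / (n_e * nrow(C)))
}

# all permutations of a small vector's positions (multiset-aware for groups)
all_perms <- function(v) {
  if (length(v) == 1) {
    return(list(v))
  }
  out <- list()
  for (i in seq_along(v)) {
    rest <- all_perms(v[-i])
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

unique_perms <- function(v) {
  unique(all_perms(v))
}

# generate the permutation plan for an effect
tanova_perms <- function(prep, fac, n_perm, exhaustive = FALSE) {
  S <- length(prep$subjects)
  group_only <- identical(fac, "group")
  within_only <- !("group" %in% fac)
  mixed <- ("group" %in% fac) && length(fac) > 1

  if (exhaustive) {
    if (group_only) {
      gs <- unique_perms(as.integer(prep$groups))
      return(list(
        type = "group", n = length(gs),
        draw = function(i) gs[[i]]
      ))
    }
    cellperms <- all_perms(seq_len(prep$n_cells))
    total <- length(cellperms)^S
    idx_grid <- as.matrix(expand.grid(rep(list(seq_along(cellperms)), S)))
    return(list(
      type = if (mixed) "mixed" else "within", n = nrow(idx_grid),
      draw = function(i) {
        unlist(lapply(idx_grid[i, ], function(k) cellperms[[k]]))
      }
    ))
  }
  if (group_only) {
    list(
      type = "group", n = n_perm,
      draw = function(i) sample(as.integer(prep$groups))
    )
  } else {
    list(
      type = if (mixed) "mixed" else "within", n = n_perm,
      draw = function(i) {
        as.vector(vapply(
          seq_len(S), function(s) sample.int(prep$n_cells),
          integer(prep$n_cells)
        ))
      }
    )
  }
}

# core engine shared by the pointwise, window and duration operations
tanova_engine <- function(data, effect, n_perm, seed, exhaustive = FALSE) {
  prep <- tanova_prep(data)
  fac <- parse_effect(effect, prep)
  sizes <- c(
    group = nlevels(prep$groups),
    vapply(prep$lev, length, integer(1))
  )
  P <- tanova_projector(fac, sizes)

  n_groups <- nlevels(prep$groups)
  grp_row <- as.integer(prep$groups)[prep$subj_idx]

  Y <- prep$Y
  mixed <- ("group" %in% fac) && length(fac) > 1
  if (mixed) {
    # remove subject mean maps before shuffling within-subject labels
    subj_means <- rowsum(Y, prep$subj_idx) / prep$n_cells
    Y <- Y - subj_means[prep$subj_idx, , drop = FALSE]
  }

  obs <- tanova_stat(
    Y, prep$cell, grp_row, n_groups, prep$n_cells, P,
    prep$n_e, prep$n_t
  )

  plan <- tanova_perms(prep, fac, n_perm, exhaustive = exhaustive)
  perm_stats <- with_seed_(seed, {
    M <- matrix(0, plan$n, length(obs))
    for (i in seq_len(plan$n)) {
      if (plan$type == "group") {
        g_new <- plan$draw(i)
        M[i, ] <- tanova_stat(
          Y, prep$cell, g_new[prep$subj_idx], n_groups,
          prep$n_cells, P, prep$n_e, prep$n_t
        )
      } else {
        cell_new <- plan$draw(i)
        M[i, ] <- tanova_stat(
          Y, cell_new, grp_row, n_groups,
          prep$n_cells, P, prep$n_e, prep$n_t
        )
      }
    }
    M
  })

  p <- if (exhaustive) {
    colMeans(sweep(perm_stats, 2, obs, `>=`))
  } else {
    (1 + colSums(sweep(perm_stats, 2, obs, `>=`))) / (1 + plan$n)
  }
  list(
    prep = prep, obs = obs, perm_stats = perm_stats, p = p,
    effect = effect, n_perm = plan$n, exhaustive = exhaustive
  )
}

# longest run of TRUE in a logical vector
longest_run <- function(x) {
  if (!any(x)) {
    return(0L)
  }
  r <- rle(x)
  max(r$lengths[r$values])
}

# runs of TRUE as (start, end) index pairs
run_spans <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

# critical duration (in samples) from a permutation stat matrix: each
# permutation is scored against the whole pool and its longest sub-alpha
# run recorded; returns the 95th percentile of those maximal runs. The
# pool size n+1 mirrors the add-one rule of the observed p series.
critical_run_samples <- function(perm_stats, alpha, prob = 0.95) {
  n <- nrow(perm_stats)
  pmat <- apply(perm_stats, 2, function(v) {
    (n - rank(v, ties.method = "min") + 1) / (n + 1)
  })
  if (is.null(dim(pmat))) pmat <- matrix(pmat, nrow = n)
  maxruns <- apply(pmat < alpha, 1, longest_run)
  as.numeric(quantile(maxruns, prob, type = 1))
}

#' Observed effect topographies of the mixed-design TANOVA
#'
#' Classical (unweighted) marginal-mean decomposition of the subject x
#' condition maps: the grand mean is removed, main-effect maps are
#' factor-level marginal means minus the grand mean, and interaction maps
#' are cell means minus the additive lower-order reconstruction. The
#' effect statistic at each time point is the root-mean-square of the
#' effect maps across electrodes and effect levels (a generalized global
#' field power of the effect).
#'
#' @param data A `surf_tse_tbl` (see [tse_cohort()]) or any tibble with
#'   `subject`, `map` (electrodes x samples matrices) and factor columns
#'   `group`, `phase`, `trial_type` as applicable.
#' @param effect Effect name: factors joined by `:`, e.g. `"group"`,
#'   `"phase:trial_type"`, `"group:phase:trial_type"`.
#' @return A list: `maps` (component array, design cells x electrodes x
#'   samples), `stat` (RMS series over time), `cell_means` (for
#'   reconstruction checks), `effect`.
#' @export
effect_maps <- function(data, effect) {
  prep <- tanova_prep(data)
  fac <- parse_effect(effect, prep)
  sizes <- c(
    group = nlevels(prep$groups),
    vapply(prep$lev, length, integer(1))
  )
  P <- tanova_projector(fac, sizes)
  grp_row <- as.integer(prep$groups)[prep$subj_idx]
  code <- (grp_row - 1L) * prep$n_cells + prep$cell
  Z <- rowsum(prep$Y, code, reorder = TRUE) /
    tabulate(code, nbins = nlevels(prep$groups) * prep$n_cells)
  C <- P %*% Z
  s2 <- colSums(C * C)
  dim(s2) <- c(prep$n_e, prep$n_t)
  stat <- sqrt(colSums(s2) / (prep$n_e * nrow(C)))
  maps <- array(t(C), dim = c(prep$n_e, prep$n_t, nrow(C)))
  maps <- aperm(maps, c(3, 1, 2))
  list(maps = maps, stat = stat, cell_means = Z, effect = effect)
}

#' Pointwise randomization TANOVA with duration correction
#'
#' At every time point, tests the chosen effect of the mixed
#' group x phase x trial-type design with a randomization test on the
#' map-dissimilarity statistic (RMS of the effect maps across electrodes
#' and levels): `p = (1 + #{permuted >= observed}) / (1 + n_perm)`.
#' Permutation schemes follow the design role of the effect: purely
#' within-subject effects shuffle the condition labels independently
#' inside each subject; the between-subject effect shuffles the group
#' assignment across subjects; interactions involving group shuffle
#' condition labels within subjects after removing each subject's mean
#' map. One permutation sequence is reused across all time points, so the
#' smoothness of the p series reflects the data.
#'
#' The same permutation pool then yields the duration-based correction
#' for multiple testing across time: each permutation is scored against
#' the pool, its longest run of sub-`alpha` p values recorded, and the
#' 95th percentile of those runs becomes the critical duration; only
#' observed runs longer than it are reported as significant windows.
#'
#' @inheritParams effect_maps
#' @param n_perm Number of permutations. Default 5000.
#' @param seed Integer seed.
#' @param alpha Pointwise threshold for run formation. Default 0.05.
#' @param exhaustive Enumerate all permutations instead of sampling (tiny
#'   designs only); p becomes the exact randomization p.
#' @return A list of class `surf_tanova`: `series` (tibble `time`,
#'   `stat`, `p`), `critical_duration_ms`, `windows` (tibble of
#'   significant windows in s), `effect`, `n_perm`, `alpha`, `fs`.
#' @export
tanova_pointwise <- function(data, effect, n_perm = 5000, seed = 1,
                             alpha = 0.05, exhaustive = FALSE) {
  if (!exhaustive && n_perm < 100) {
    warn("fewer than 100 permutations: p-value resolution is coarse.")
  }
  eng <- tanova_engine(data, effect, n_perm, seed, exhaustive = exhaustive)
  times <- eng$prep$times %||% attr(data, "times", exact = TRUE) %||%
    seq_len(eng$prep$n_t)
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  crit_samples <- critical_run_samples(eng$perm_stats, alpha)
  crit_ms <- crit_samples * dt * 1000
  below <- eng$p < alpha
  spans <- run_spans(below)
  spans <- spans[spans$length > crit_samples, , drop = FALSE]
  windows <- tibble(
    start = times[spans$start],
    end = times[spans$end],
    n_samples = spans$length
  )
  structure(
    list(
      series = tibble(time = times, stat = eng$obs, p = eng$p),
      critical_duration_ms = crit_ms,
      windows = windows,
      effect = effect, n_perm = eng$n_perm, alpha = alpha,
      exhaustive = exhaustive
    ),
    class = "surf_tanova"
  )
}

#' @export
print.surf_tanova <- function(x, ...) {
  cat(sprintf(
    "<surf_tanova> effect %s: %d time points, %d permutations\n",
    x$effect, nrow(x$series), x$n_perm
  ))
  cat(sprintf(
    "  min p = %.4g; critical duration %.1f ms; %d significant window(s)\n",
    min(x$series$p), x$critical_duration_ms, nrow(x$windows)
  ))
  invisible(x)
}

#' Critical duration of sub-threshold runs under the permutation null
#'
#' Estimates the run length that pointwise sub-`alpha` p values must
#' exceed to keep the family-wise false-positive rate across time at 5 %:
#' each of `n_null` permuted datasets is scored against the permutation
#' pool, the longest sub-`alpha` run per permutation recorded, and the
#' 95th percentile of those maximal run lengths returned in milliseconds.
#'
#' @inheritParams tanova_pointwise
#' @param n_null Number of null datasets (permutations). Default 1000.
#' @return Critical duration in ms.
#' @export
critical_duration <- function(data, effect, alpha = 0.05, n_null = 1000,
                              seed = 1, exhaustive = FALSE) {
  eng <- tanova_engine(data, effect, n_null, seed, exhaustive = exhaustive)
  times <- eng$prep$times %||% attr(data, "times", exact = TRUE) %||%
    seq_len(eng$prep$n_t)
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  critical_run_samples(eng$perm_stats, alpha) * dt * 1000
}

#' Averaged-window TANOVA
#'
#' Averages the maps over a time window and runs a single randomization
#' test of the effect on the averaged topographies (same statistic and
#' permutation scheme as [tanova_pointwise()]).
#'
#' @inheritParams tanova_pointwise
#' @param window Window bounds in epoch time, s (`c(lower, upper)`,
#'   half-open on the upper edge); must contain at least one sample.
#' @return A one-row tibble: `effect`, `window_start`, `window_end`,
#'   `stat`, `p`, `n_perm`.
#' @export
window_tanova <- function(data, effect, window, n_perm = 5000, seed = 1,
                          exhaustive = FALSE) {
  times <- attr(data, "times", exact = TRUE)
  if (is.null(times)) {
    times <- seq_len(ncol(data$map[[1]]))
  }
  keep <- times >= window[1] & times < window[2]
  if (!any(keep)) {
    abort("empty averaging window.", class = "alphasurf_input_error")
  }
  data2 <- data
  data2$map <- purrr::map(data$map, function(m) {
    matrix(rowMeans(m[, keep, drop = FALSE]), ncol = 1)
  })
  attr(data2, "times") <- mean(times[keep])
  eng <- tanova_engine(data2, effect, n_perm, seed, exhaustive = exhaustive)
  tibble(
    effect = effect, window_start = window[1], window_end = window[2],
    stat = eng$obs[1], p = eng$p[1], n_perm = eng$n_perm
  )
}

#' Per-subject condition contrast maps
#'
#' Elementwise subtraction of two condition topographies per subject
#' (e.g. Hit minus Missed), optionally baseline-normalized as the
#' Retention contrast minus the Baseline contrast.
#'
#' @param data A `surf_tse_tbl` or compatible tibble.
#' @param a,b Levels of `within` to subtract (`a - b`).
#' @param within Factor column holding `a` and `b`. Default
#'   `"trial_type"`.
#' @param phase Optional single phase to restrict to.
#' @param baseline_normalize Return (Retention contrast) - (Baseline
#'   contrast) per subject. Default FALSE.
#' @return A tibble with `subject`, `group` (if present), `phase` (unless
#'   normalized or restricted) and `map` list-column; attribute `times`
#'   is carried over.
#' @export
contrast_map <- function(data, a, b, within = "trial_type", phase = NULL,
                         baseline_normalize = FALSE) {
  stopifnot(all(c("subject", "map", within) %in% names(data)))
  if (!is.null(phase)) {
    data <- data[data$phase == phase, , drop = FALSE]
  }
  keys <- intersect(c("subject", "group", "phase"), names(data))
  if (baseline_normalize) keys <- setdiff(keys, NULL) # phases needed first
  da <- data[data[[within]] == a, c(keys, "map")]
  db <- data[data[[within]] == b, c(keys, "map")]
  names(db)[names(db) == "map"] <- "map_b"
  out <- dplyr::inner_join(da, db, by = keys)
  out$map <- purrr::map2(out$map, out$map_b, `-`)
  out$map_b <- NULL
  if (baseline_normalize) {
    if (!"phase" %in% names(out)) {
      abort("baseline normalization needs a `phase` column.",
        class = "alphasurf_input_error"
      )
    }
    keys2 <- setdiff(keys, "phase")
    ret <- out[out$phase == "Retention", c(keys2, "map")]
    bas <- out[out$phase == "Baseline", c(keys2, "map")]
    names(bas)[names(bas) == "map"] <- "map_b"
    out <- dplyr::inner_join(ret, bas, by = keys2)
    out$map <- purrr::map2(out$map, out$map_b, `-`)
    out$map_b <- NULL
  }
  attr(out, "times") <- attr(data, "times", exact = TRUE)
  out
}

#' Two-sample randomization TANOVA on contrast maps
#'
#' Tests whether two groups differ in their subject-level contrast
#' topographies. The statistic is the RMS across electrodes (and samples)
#' of the difference between group mean maps; the null is built by
#' shuffling group labels across subjects.
#'
#' @param contrasts Tibble with `subject`, `group`, `map` (one row per
#'   subject), e.g. from [contrast_map()].
#' @param group_a,group_b Group labels to compare.
#' @param n_perm Number of permutations. Default 5000.
#' @param seed Integer seed.
#' @param exhaustive Enumerate all label assignments (small n only).
#' @return A one-row tibble: `comparison`, `stat`, `p`, `n_perm`.
#' @export
pairwise_tanova <- function(contrasts, group_a, group_b, n_perm = 5000,
                            seed = 1, exhaustive = FALSE) {
  df <- contrasts[contrasts$group %in% c(group_a, group_b), , drop = FALSE]
  if (length(unique(df$subject)) != nrow(df)) {
    abort("`contrasts` must have one map per subject.",
      class = "alphasurf_input_error"
    )
  }
  g <- df$group == group_a
  if (sum(g) < 2 || sum(!g) < 2) {
    abort("each group needs at least 2 subjects.",
      class = "alphasurf_input_error"
    )
  }
  Y <- t(vapply(df$map, as.vector, numeric(length(df$map[[1]]))))
  stat_fun <- function(lab) {
    sqrt(mean((colMeans(Y[lab, , drop = FALSE]) -
      colMeans(Y[!lab, , drop = FALSE]))^2))
  }
  obs <- stat_fun(g)
  if (exhaustive) {
    labs <- utils::combn(nrow(Y), sum(g), simplify = FALSE)
    stats <- vapply(labs, function(ix) {
      stat_fun(seq_len(nrow(Y)) %in% ix)
    }, numeric(1))
    p <- mean(stats >= obs)
    n_used <- length(stats)
  } else {
    stats <- with_seed_(seed, {
      vapply(seq_len(n_perm), function(i) stat_fun(sample(g)), numeric(1))
    })
    p <- (1 + sum(stats >= obs)) / (1 + n_perm)
    n_used <- n_perm
  }
  tibble(
    comparison = paste(group_a, group_b, sep = " vs "),
    stat = obs, p = p, n_perm = n_used
  )
}

#' Electrode-wise t map of a contrast
#'
#' Descriptive electrode-wise t statistics of subject-level contrast maps
#' (averaged over samples when maps carry a time dimension): one-sample
#' against zero, or two-sample between groups when `group_b` is given.
#' Electrodes with zero variance yield an undefined t and are masked out
#' with a warning. The mask marks `|t| >` the threshold; hypothesis
#' decisions rest on the TANOVA, not on this map.
#'
#' @param contrasts Tibble with `subject`, `map` (and `group` for the
#'   two-sample form).
#' @param threshold Masking threshold on |t|. Default 2.36.
#' @param group_a,group_b Optional group labels for a two-sample t map.
#' @param electrodes Electrode ids (defaults to map rownames or E001...).
#' @return A tibble of class `surf_tmap`: `electrode`, `t`, `masked`.
#' @export
t_map <- function(contrasts, threshold = 2.36, group_a = NULL,
                  group_b = NULL, electrodes = NULL) {
  M <- vapply(
    contrasts$map, function(m) rowMeans(as.matrix(m)),
    numeric(nrow(contrasts$map[[1]]))
  ) # electrodes x subjects
  electrodes <- electrodes %||% rownames(contrasts$map[[1]]) %||%
    sprintf("E%03d", seq_len(nrow(M)))
  if (is.null(group_b)) {
    if (ncol(M) < 2) {
      abort("need at least 2 subjects.", class = "alphasurf_input_error")
    }
    mu <- rowMeans(M)
    s <- apply(M, 1, sd)
    tval <- mu / (s / sqrt(ncol(M)))
  } else {
    ga <- contrasts$group == group_a
    gb <- contrasts$group == group_b
    if (sum(ga) < 2 || sum(gb) < 2) {
      abort("each group needs at least 2 subjects.",
        class = "alphasurf_input_error"
      )
    }
    va <- apply(M[, ga, drop = FALSE], 1, var)
    vb <- apply(M[, gb, drop = FALSE], 1, var)
    sp <- sqrt(((sum(ga) - 1) * va + (sum(gb) - 1) * vb) /
      (sum(ga) + sum(gb) - 2))
    tval <- (rowMeans(M[, ga, drop = FALSE]) -
      rowMeans(M[, gb, drop = FALSE])) /
      (sp * sqrt(1 / sum(ga) + 1 / sum(gb)))
  }
  undef <- !is.finite(tval)
  if (any(undef)) {
    warn(sprintf(
      "%d electrode(s) with zero variance masked out", sum(undef)
    ))
  }
  out <- tibble(
    electrode = electrodes,
    t = ifelse(undef, NA_real_, tval),
    masked = !undef & abs(tval) > threshold
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("surf_tmap", class(out))
  out
}
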
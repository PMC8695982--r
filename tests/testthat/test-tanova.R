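# build a subject x condition map table directly (electrodes x samples)
make_map_tbl <- function(n_per_group = 3, groups = c("A", "B"),
                         n_e = 4, n_t = 5, noise = 1, seed = 1,
                         cell_fun = NULL) {
  subjects <- sprintf("S%02d", seq_len(n_per_group * length(groups)))
  grp <- rep(groups, each = n_per_group)
  rows <- list()
  withr::with_seed(seed, {
    for (s in seq_along(subjects)) {
      for (ph in c("Baseline", "Retention")) {
        for (tt in c("Hit", "Missed")) {
          m <- matrix(rnorm(n_e * n_t, sd = noise), n_e, n_t)
          if (!is.null(cell_fun)) {
            m <- m + cell_fun(grp[s], ph, tt, n_e, n_t)
          }
          rows[[length(rows) + 1]] <- tibble::tibble(
            subject = subjects[s], group = grp[s], phase = ph,
            trial_type = tt, map = list(m)
          )
        }
      }
    }
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "times") <- (seq_len(n_t) - 1) / 100
  out
}

test_that("effect decomposition matches hand-built structure", {
  # purely additive two-factor data: the interaction component vanishes
  add_fun <- function(g, ph, tt, n_e, n_t) {
    (g == "A") * 2 + (ph == "Retention") * 3
  }
  tbl <- make_map_tbl(noise = 0, cell_fun = add_fun)
  em <- effect_maps(tbl, "group:phase")
  expect_equal(max(abs(em$stat)), 0, tolerance = 1e-12)
  # but both main effects are present
  expect_gt(min(effect_maps(tbl, "group")$stat), 0)
  expect_gt(min(effect_maps(tbl, "phase")$stat), 0)

  # one-factor two-level data with maps M and -M: stat equals RMS(M)
  M <- matrix(seq_len(20) / 10, 4, 5)
  pm_fun <- function(g, ph, tt, n_e, n_t) {
    if (ph == "Retention") M else -M
  }
  tbl2 <- make_map_tbl(noise = 0, cell_fun = pm_fun)
  em2 <- effect_maps(tbl2, "phase")
  expect_equal(em2$stat, sqrt(colMeans(M^2)), tolerance = 1e-12)

  # constant identical maps: every effect statistic is zero
  tbl3 <- make_map_tbl(noise = 0, cell_fun = function(...) 7)
  for (ef in c("group", "phase", "trial_type", "group:phase:trial_type")) {
    expect_equal(max(effect_maps(tbl3, ef)$stat), 0, tolerance = 1e-12)
  }
})

test_that("effect components reconstruct the cell means exactly", {
  tbl <- make_map_tbl(noise = 1, seed = 8)
  effects <- c(
    "group", "phase", "trial_type", "group:phase", "group:trial_type",
    "phase:trial_type", "group:phase:trial_type"
  )
  parts <- lapply(effects, function(ef) effect_maps(tbl, ef))
  Z <- parts[[1]]$cell_means
  grand <- matrix(colMeans(Z), nrow(Z), ncol(Z), byrow = TRUE)
  recon <- grand
  for (p in parts) {
    comp <- apply(p$maps, 1, as.vector) # (E*T) x cells
    recon <- recon + t(comp)
  }
  expect_equal(unname(recon), unname(Z), tolerance = 1e-10)
})

test_that("exhaustive group randomization matches a brute-force oracle", {
  # 4 subjects, 2 groups, no within factor: 6 distinct assignments
  withr::with_seed(3, {
    maps <- lapply(1:4, function(i) matrix(rnorm(12), 3, 4))
  })
  tbl <- tibble::tibble(
    subject = sprintf("S%d", 1:4),
    group = c("A", "A", "B", "B"),
    map = maps
  )
  res <- tanova_pointwise(tbl, "group",
    exhaustive = TRUE,
    alpha = 0.05, seed = 1
  )
  # independent oracle: stat is RMS of half the group-mean difference
  oracle_stat <- function(ga) {
    mA <- Reduce(`+`, maps[ga]) / 2
    mB <- Reduce(`+`, maps[!ga]) / 2
    apply((mA - mB) / 2, 2, function(col) sqrt(mean(col^2)))
  }
  obs <- oracle_stat(c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$series$stat, obs, tolerance = 1e-12)
  assigns <- utils::combn(4, 2, simplify = FALSE)
  all_stats <- t(vapply(assigns, function(ix) {
    oracle_stat(seq_len(4) %in% ix)
  }, numeric(4)))
  # each assignment appears twice among label orderings (A/B symmetric),
  # so the enumeration p equals the share of the 6 assignments >= observed
  p_oracle <- colMeans(sweep(all_stats, 2, obs, `>=`))
  expect_equal(res$series$p, p_oracle, tolerance = 1e-12)
  expect_equal(res$n_perm, 6)
})

test_that("exhaustive within-subject randomization matches sign-flip enumeration", {
  # 3 subjects x 2 phase cells: 2^3 = 8 total label assignments
  withr::with_seed(4, {
    maps <- lapply(1:6, function(i) matrix(rnorm(6), 2, 3))
  })
  tbl <- tibble::tibble(
    subject = rep(sprintf("S%d", 1:3), each = 2),
    phase = rep(c("Baseline", "Retention"), 3),
    map = maps
  )
  res <- tanova_pointwise(tbl, "phase", exhaustive = TRUE, seed = 1)
  # oracle: flipping a subject's labels swaps its pair of maps
  stat_of <- function(flip) {
    m1 <- m2 <- list()
    for (s in 1:3) {
      a <- maps[[2 * s - 1]]
      b <- maps[[2 * s]]
      if (flip[s]) {
        tmp <- a
        a <- b
        b <- tmp
      }
      m1[[s]] <- a
      m2[[s]] <- b
    }
    z1 <- Reduce(`+`, m1) / 3
    z2 <- Reduce(`+`, m2) / 3
    apply((z1 - z2) / 2, 2, function(col) sqrt(mean(col^2)))
  }
  flips <- expand.grid(c(FALSE, TRUE), c(FALSE, TRUE), c(FALSE, TRUE))
  all_stats <- t(apply(flips, 1, function(f) stat_of(as.logical(f))))
  obs <- stat_of(c(FALSE, FALSE, FALSE))
  expect_equal(res$series$stat, obs, tolerance = 1e-12)
  expect_equal(
    res$series$p,
    colMeans(sweep(all_stats, 2, obs, `>=`)),
    tolerance = 1e-12
  )
})

test_that("permutation p-values obey the add-one rule and can reach 1", {
  tbl <- make_map_tbl(noise = 1, seed = 5)
  res <- tanova_pointwise(tbl, "phase", n_perm = 199, seed = 2)
  expect_true(all(res$series$p >= 1 / 200))
  expect_true(all(res$series$p <= 1))
  # constant identical maps: observed stat 0, every permutation ties, p = 1
  tbl0 <- make_map_tbl(noise = 0, cell_fun = function(...) 1)
  expect_warning(
    res0 <- tanova_pointwise(tbl0, "phase", n_perm = 99, seed = 2),
    "resolution"
  )
  expect_true(all(res0$series$p == 1))
})

test_that("a window test on a single sample equals the pointwise test there", {
  tbl <- make_map_tbl(noise = 1, seed = 6)
  times <- attr(tbl, "times")
  res_pt <- tanova_pointwise(tbl, "phase:trial_type", n_perm = 199, seed = 7)
  k <- 3
  res_w <- window_tanova(
    tbl, "phase:trial_type",
    window = c(times[k], times[k] + 0.005), n_perm = 199, seed = 7
  )
  expect_equal(res_w$p, res_pt$series$p[k], tolerance = 1e-12)
  expect_equal(res_w$stat, res_pt$series$stat[k], tolerance = 1e-12)
  expect_error(
    window_tanova(tbl, "phase", c(9, 10), n_perm = 99, seed = 1),
    class = "alphasurf_input_error"
  )
})

test_that("critical duration behaves under nested thresholds and degenerate alpha", {
  tbl <- make_map_tbl(n_per_group = 4, n_t = 12, noise = 1, seed = 9)
  times <- attr(tbl, "times")
  dt_ms <- (times[2] - times[1]) * 1000
  # alpha = 1: every point is sub-threshold in every permutation
  cd_full <- critical_duration(tbl, "phase", alpha = 1, n_null = 50, seed = 3)
  expect_equal(cd_full, 12 * dt_ms)
  # non-decreasing in alpha (same seed, nested sub-threshold sets)
  cds <- vapply(c(0.01, 0.05, 0.2, 0.5, 1), function(a) {
    critical_duration(tbl, "phase", alpha = a, n_null = 50, seed = 3)
  }, numeric(1))
  expect_true(all(diff(cds) >= 0))
})

test_that("contrast maps are linear and baseline-normalizable", {
  C <- matrix(1:20 / 5, 4, 5)
  fun <- function(g, ph, tt, n_e, n_t) {
    (tt == "Hit") * C + (ph == "Retention") * (tt == "Hit") * 2 * C
  }
  tbl <- make_map_tbl(noise = 0, cell_fun = fun)
  cm_b <- contrast_map(tbl, "Hit", "Missed", phase = "Baseline")
  expect_equal(cm_b$map[[1]], C, tolerance = 1e-12)
  cm_bn <- contrast_map(tbl, "Hit", "Missed", baseline_normalize = TRUE)
  expect_equal(cm_bn$map[[1]], 2 * C, tolerance = 1e-12)
  # identical cells yield a zero map
  tbl_id <- make_map_tbl(noise = 0, cell_fun = function(...) 3)
  cm0 <- contrast_map(tbl_id, "Hit", "Missed", phase = "Baseline")
  expect_true(all(cm0$map[[1]] == 0))
  # phase-invariant data: baseline-normalized contrast vanishes
  fun_inv <- function(g, ph, tt, n_e, n_t) (tt == "Hit") * C
  cm_inv <- contrast_map(
    make_map_tbl(noise = 0, cell_fun = fun_inv),
    "Hit", "Missed",
    baseline_normalize = TRUE
  )
  expect_true(all(abs(cm_inv$map[[1]]) < 1e-12))
})

test_that("pairwise group randomization is symmetric and separates planted shifts", {
  tbl <- make_map_tbl(n_per_group = 4, noise = 1, seed = 10)
  cm <- contrast_map(tbl, "Hit", "Missed", baseline_normalize = TRUE)
  p_ab <- pairwise_tanova(cm, "A", "B", n_perm = 199, seed = 4)
  p_ba <- pairwise_tanova(cm, "B", "A", n_perm = 199, seed = 4)
  expect_equal(p_ab$p, p_ba$p)
  # a shift far above noise: only the true split (and its mirror) among
  # all 70 label assignments reaches the observed separation
  shift_fun <- function(g, ph, tt, n_e, n_t) {
    (g == "A") * (tt == "Hit") * (ph == "Retention") * 100
  }
  tbl_s <- make_map_tbl(n_per_group = 4, noise = 0.1, cell_fun = shift_fun)
  cm_s <- contrast_map(tbl_s, "Hit", "Missed", baseline_normalize = TRUE)
  p_s <- pairwise_tanova(cm_s, "A", "B", exhaustive = TRUE)
  expect_equal(p_s$p, 2 / 70, tolerance = 1e-12)
  expect_error(
    pairwise_tanova(cm[1:3, ], "A", "B", n_perm = 99, seed = 1),
    class = "alphasurf_input_error"
  )
})

test_that("t maps mask planted electrodes and respect the null tail rate", {
  n_sub <- 12
  n_e <- 150
  withr::with_seed(20, {
    maps <- lapply(seq_len(n_sub), function(i) {
      m <- matrix(rnorm(n_e), n_e, 1)
      m[5, 1] <- m[5, 1] + 50 # planted strong shift at electrode 5
      m
    })
  })
  tm <- t_map(tibble::tibble(subject = 1:n_sub, map = maps))
  expect_true(tm$masked[5])
  # under the null the expected masked fraction is the t tail probability
  expected <- 2 * pt(-2.36, df = n_sub - 1)
  observed <- mean(tm$masked[-5])
  expect_lt(abs(observed - expected), 3 * sqrt(expected / n_e))
  # zero-variance electrodes are masked out with a warning
  maps0 <- lapply(1:4, function(i) matrix(c(1, rnorm(3)), 4, 1))
  expect_warning(tm0 <- t_map(tibble::tibble(subject = 1:4, map = maps0)),
    "zero variance"
  )
  expect_true(is.na(tm0$t[1]))
  expect_false(tm0$masked[1])
})

test_that("tanova results tidy, glance and plot", {
  tbl <- make_map_tbl(noise = 1, seed = 11)
  res <- tanova_pointwise(tbl, "phase", n_perm = 199, seed = 2)
  td <- tidy(res)
  expect_true(all(c("time", "stat", "p", "significant") %in% names(td)))
  gl <- glance(res)
  expect_equal(gl$n_perm, 199)
  expect_s3_class(autoplot(res), "gg")
  tm <- t_map(contrast_map(tbl, "Hit", "Missed", phase = "Baseline"))
  expect_s3_class(autoplot(tm, montage = make_montage(8)[1:4, ]), "gg")
})
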
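#' Pipeline configuration
#'
#' Assembles and validates the configuration of the full analysis
#' pipeline. Sections mirror the stage constructors ([sim_config()],
#' [cohort_design()], [synth_eeg_config()]) and are given as named lists
#' of overrides; unknown fields raise a schema error naming the field.
#' The master `seed` deterministically derives one seed per stage, so a
#' rerun with the same configuration reproduces every stochastic stage.
#'
#' @param sim Named overrides for [sim_config()].
#' @param design Named overrides for [cohort_design()].
#' @param eeg Named overrides for [synth_eeg_config()].
#' @param effect_scale Planted topographic contrast magnitude, uV, fed to
#'   [plant_alpha_pattern()]. Default 0 (null pattern).
#' @param tse Named list: `band` (Hz, default `c(7, 15)`) and
#'   `smooth_cutoff` (Hz, default half the band low-cut).
#' @param tanova Named list: `n_perm` (default 5000), `alpha` (default
#'   0.05), `t_threshold` (default 2.36).
#' @param tasks Behavioural tasks to simulate. Default `c("HT", "OT")`.
#' @param seed Master seed. Default 1.
#' @return A list of class `surf_pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), design = list(), eeg = list(),
                            effect_scale = 0,
                            tse = list(), tanova = list(),
                            tasks = c("HT", "OT"), seed = 1) {
  check_fields <- function(given, allowed, section) {
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0) {
      abort(
        sprintf(
          "unknown field(s) in `%s`: %s", section,
          paste(bad, collapse = ", ")
        ),
        class = "alphasurf_schema_error"
      )
    }
    given
  }
  sim <- check_fields(sim, names(formals(sim_config)), "sim")
  design <- check_fields(design, names(formals(cohort_design)), "design")
  eeg <- check_fields(eeg, names(formals(synth_eeg_config)), "eeg")
  tse <- check_fields(tse, c("band", "smooth_cutoff"), "tse")
  tanova <- check_fields(
    tanova, c("n_perm", "alpha", "t_threshold"), "tanova"
  )
  tse$band <- tse$band %||% c(7, 15)
  tse$smooth_cutoff <- tse$smooth_cutoff %||% (tse$band[1] / 2)
  tanova$n_perm <- tanova$n_perm %||% 5000
  tanova$alpha <- tanova$alpha %||% 0.05
  tanova$t_threshold <- tanova$t_threshold %||% 2.36
  structure(
    list(
      sim = do.call(sim_config, sim),
      design = do.call(cohort_design, design),
      eeg = do.call(synth_eeg_config, eeg),
      effect_scale = effect_scale,
      tse = tse, tanova = tanova,
      tasks = match.arg(tasks, c("HT", "OT"), several.ok = TRUE),
      seed = as.integer(seed)
    ),
    class = "surf_pipeline_config"
  )
}

#' Write and read a pipeline configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`) serialization of the override
#' sections of a [pipeline_config()]; reading re-validates through the
#' constructor, so defaults round-trip exactly.
#'
#' @param config A [pipeline_config()] or the plain override list.
#' @param path Target file; the extension selects the format.
#' @export
write_config <- function(config, path) {
  plain <- if (inherits(config, "surf_pipeline_config")) {
    list(
      sim = unclass(config$sim)[!vapply(unclass(config$sim), is.null, NA)],
      design = unclass(config$design),
      eeg = unclass(config$eeg),
      effect_scale = config$effect_scale,
      tse = config$tse, tanova = config$tanova,
      tasks = config$tasks, seed = config$seed
    )
  } else {
    config
  }
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    yaml::write_yaml(plain, path)
  } else if (ext == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  } else {
    abort("config path must end in .yaml, .yml or .json.",
      class = "alphasurf_schema_error"
    )
  }
  invisible(config)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    abort("config path must end in .yaml, .yml or .json.",
      class = "alphasurf_schema_error"
    )
  }
  # normalize sections to the constructor's argument lists
  take <- function(x, fn) {
    x <- x[intersect(names(x), names(formals(fn)))]
    lapply(x, function(v) if (is.list(v)) unlist(v) else v)
  }
  pipeline_config(
    sim = take(raw$sim %||% list(), sim_config),
    design = take(raw$design %||% list(), cohort_design),
    eeg = take(raw$eeg %||% list(), synth_eeg_config),
    effect_scale = raw$effect_scale %||% 0,
    tse = raw$tse %||% list(),
    tanova = raw$tanova %||% list(),
    tasks = raw$tasks %||% c("HT", "OT"),
    seed = raw$seed %||% 1
  )
}

#' Run the full analysis pipeline
#'
#' Executes both analysis chains end to end from one configuration:
#' behavioural (cohort simulation, time-of-interest metrics, participant
#' summaries, group test battery) and electrophysiological (synthetic
#' epoched EEG with the configured planted pattern, TSE transform, the
#' mixed three-way TANOVA with duration correction, trial-type contrast
#' maps, baseline-normalized pairwise group comparisons and t maps).
#' Every stochastic stage is seeded from the master seed, so a rerun
#' with the same configuration is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @param stages Which chains to run: subset of
#'   `c("behaviour", "eeg")`.
#' @return A list of class `surf_pipeline` with elements `cohort`,
#'   `metrics`, `summary`, `behaviour_tests`, `eeg`, `tse`, `tanova`
#'   (per-effect pointwise results), `window_tests`, `pairwise`,
#'   `tmaps`, and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("behaviour", "eeg")) {
  stopifnot(inherits(config, "surf_pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  out <- list(config = config)

  if ("behaviour" %in% stages) {
    message("stage: simulate behavioural cohort")
    cohort <- simulate_cohort(config$design, config$sim,
      seed = derive_seed(config$seed, "behaviour"), tasks = config$tasks
    )
    message("stage: trial metrics")
    metrics <- trial_metrics(cohort$log, cohort$events,
      trials = cohort$trials, rate = config$sim$sample_rate
    )
    summary_tbl <- summarize_participants(metrics)
    message("stage: behavioural test battery")
    tests <- behaviour_test_battery(summary_tbl,
      alpha = config$tanova$alpha
    )
    out$cohort <- cohort
    out$metrics <- metrics
    out$summary <- summary_tbl
    out$behaviour_tests <- tests
  }

  if ("eeg" %in% stages) {
    message("stage: synthetic EEG")
    effects <- if (config$effect_scale > 0) {
      plant_alpha_pattern(config$effect_scale,
        trial_types = config$eeg$trial_types
      )
    } else {
      list()
    }
    eeg <- synth_epochs(config$eeg,
      effects = effects,
      seed = derive_seed(config$seed, "eeg")
    )
    message("stage: TSE transform")
    tse_tbl <- tse_cohort(eeg,
      band = config$tse$band,
      smooth_cutoff = config$tse$smooth_cutoff
    )
    message("stage: TANOVA")
    effect_names <- c(
      "group", "phase", "trial_type", "phase:trial_type",
      "group:phase:trial_type"
    )
    tanovas <- purrr::map(effect_names, function(ef) {
      tanova_pointwise(tse_tbl, ef,
        n_perm = config$tanova$n_perm, alpha = config$tanova$alpha,
        seed = derive_seed(config$seed, "tanova")
      )
    })
    names(tanovas) <- effect_names

    three <- tanovas[["group:phase:trial_type"]]
    win <- if (nrow(three$windows) > 0) {
      c(three$windows$start[1], three$windows$end[1])
    } else {
      NULL
    }
    window_tests <- if (!is.null(win)) {
      window_tanova(tse_tbl, "group:phase:trial_type", win,
        n_perm = config$tanova$n_perm,
        seed = derive_seed(config$seed, "tanova")
      )
    } else {
      NULL
    }

    tt <- config$eeg$trial_types
    cmaps <- contrast_map(tse_tbl, tt[1], tt[2],
      baseline_normalize = TRUE
    )
    grps <- unique(eeg$design$group)
    pairs <- utils::combn(grps, 2, simplify = FALSE)
    pairwise <- dplyr::bind_rows(purrr::map(pairs, function(pr) {
      pairwise_tanova(cmaps, pr[1], pr[2],
        n_perm = config$tanova$n_perm,
        seed = derive_seed(config$seed, "tanova")
      )
    }))
    tmaps <- purrr::map(pairs, function(pr) {
      t_map(cmaps,
        threshold = config$tanova$t_threshold,
        group_a = pr[1], group_b = pr[2]
      )
    })
    names(tmaps) <- vapply(pairs, paste, "", collapse = " vs ")

    out$eeg <- eeg
    out$tse <- tse_tbl
    out$tanova <- tanovas
    out$window_tests <- window_tests
    out$pairwise <- pairwise
    out$tmaps <- tmaps
  }
  class(out) <- "surf_pipeline"
  out
}

#' @export
print.surf_pipeline <- function(x, ...) {
  cat("<surf_pipeline>\n")
  cat("  stages run:", paste(
    intersect(c("cohort", "tanova"), names(x)),
    collapse = ", "
  ), "\n")
  invisible(x)
}
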
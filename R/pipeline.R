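# End-to-end orchestration: simulate (or load) -> represent -> intensity ->
# group statistics, with optional searchlight, under one validated config.

#' Pipeline configuration
#'
#' Validated bundle of every analysis parameter. The config (and its hash)
#' is stamped into the results so a run is fully reproducible.
#'
#' @param spec A [synthetic_spec()] used when no `dataset_dir` is given.
#' @param dataset_dir Optional directory of a dataset written by
#'   [make_dataset()]; `NULL` simulates in memory.
#' @param n_top `"auto"` (estimate per subject via [estimate_ntop()] and
#'   aggregate) or a fixed count (default 15 for the ROI analysis).
#' @param ntop_grid Candidate grid for the auto estimator.
#' @param drop_fraction Informative-voxel filter fraction (default 0.03).
#' @param discard_initial Leading resting frames discarded before analysis
#'   (T1-saturation dummies; default taken from `spec$discard_frames`).
#' @param sidedness Named list of test sidedness flags: `main` (merged
#'   correlation vs zero), `comparison` (between conditions), `split`
#'   (above/below), `stability` (post vs pre session).
#' @param run_searchlight Run the voxelwise stage too (slower)?
#' @param n_permutations Permutations for the searchlight contrast.
#' @param searchlight_n_top Top frames for the searchlight statistic
#'   (default 13).
#' @param searchlight_radius Cube radius (default 2).
#' @param seed Analysis-level seed (permutations); data generation is seeded
#'   by `spec$seed`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(spec = synthetic_spec(),
                            dataset_dir = NULL,
                            n_top = 15,
                            ntop_grid = seq(10, 80, by = 5),
                            drop_fraction = 0.03,
                            discard_initial = NULL,
                            sidedness = list(
                              main = "greater",
                              comparison = "two.sided",
                              split = "greater",
                              stability = "greater"
                            ),
                            run_searchlight = FALSE,
                            n_permutations = 5000L,
                            searchlight_n_top = 13L,
                            searchlight_radius = 2L,
                            seed = 1L) {
  if (!identical(n_top, "auto") &&
      (!is.numeric(n_top) || n_top < 1 || n_top != round(n_top))) {
    abort("`n_top` must be \"auto\" or a positive integer.")
  }
  for (f in c("main", "comparison", "split", "stability")) {
    if (!sidedness[[f]] %in% c("greater", "less", "two.sided")) {
      abort(sprintf("sidedness$%s must be greater/less/two.sided.", f))
    }
  }
  if (drop_fraction < 0 || drop_fraction >= 1) {
    abort("`drop_fraction` must be in [0, 1).")
  }
  structure(
    list(
      spec = spec, dataset_dir = dataset_dir, n_top = n_top,
      ntop_grid = ntop_grid, drop_fraction = drop_fraction,
      discard_initial = discard_initial %||% spec$discard_frames,
      sidedness = sidedness, run_searchlight = isTRUE(run_searchlight),
      n_permutations = as.integer(n_permutations),
      searchlight_n_top = as.integer(searchlight_n_top),
      searchlight_radius = as.integer(searchlight_radius),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline config from YAML or JSON
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; a `spec`
#' block maps onto [synthetic_spec()].
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  spec <- if (!is.null(raw$spec)) do.call(synthetic_spec, raw$spec) else synthetic_spec()
  args <- raw[setdiff(names(raw), "spec")]
  do.call(pipeline_config, c(list(spec = spec), args))
}

#' Run the full analysis pipeline
#'
#' Stages: obtain a cohort (simulate from `config$spec`, or load
#' `config$dataset_dir`); per subject, fit the first-level GLM on the induced
#' sessions and extract per-sentence t-maps, apply the informative-voxel
#' filter; compute reactivation intensities in all three resting sessions
#' (after discarding the leading dummy frames); label conditions from the
#' association tables; then the group statistics behind the headline
#' analyses: merged intensity-rating correlation per condition with z-tests,
#' their comparison, the above/below-average split per condition, and the
#' post-vs-pre session stability contrast.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `preplay_results`: `config`, `config_hash`,
#'   `n_top_used`, `intensities`, `ratings`, `per_subject`, and `tests`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(spec = synthetic_spec(
#'   n_subjects = 3, n_posterior = 8, n_associated = 5, n_prior = 4,
#'   roi_shape = c(5, 5, 5), n_rest_frames = 80, discard_frames = 3,
#'   reactivation_events_per_sentence = 6, n_induced_sessions = 2
#' ), n_top = 10)
#' res <- run_pipeline(cfg)
#' res$tests$w_prior
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- if (is.null(config$dataset_dir)) {
    simulate_cohort(config$spec)
  } else {
    read_dataset(config$dataset_dir)
  }
  spec <- cohort$spec
  sessions <- c("day1", "day2pre", "day2post")

  # --- representation stage: t-maps from induced sessions, voxel filter ---
  subject_reps <- lapply(cohort$subjects, function(sub) {
    design <- build_design_matrix(
      sub$induced$events,
      n_frames = sub$induced$n_frames, tr = spec$tr_seconds
    )
    tmaps <- fit_glm_tmaps(sub$induced$sessions, design, sub$mask)
    keep <- select_informative_voxels(tmaps, config$drop_fraction)
    apply_voxel_filter(tmaps, keep)
  })

  prepare_series <- function(series) {
    k <- config$discard_initial
    if (k > 0) {
      series <- resting_series(
        series$data[-seq_len(k), , drop = FALSE], series$mask,
        session = series$session
      )
    }
    zscore_voxels(series)
  }

  # --- N_top stage ---
  n_top_detail <- NULL
  if (identical(config$n_top, "auto")) {
    ests <- purrr::map2(cohort$subjects, subject_reps, function(sub, reps) {
      estimate_ntop(
        prepare_series(sub$rest$day2pre$series), reps, config$ntop_grid
      )
    })
    chosen <- vapply(ests, `[[`, numeric(1), "chosen")
    n_top_used <- aggregate_ntop(chosen, config$ntop_grid)
    n_top_detail <- chosen
  } else {
    n_top_used <- as.integer(config$n_top)
  }

  # --- intensity stage ---
  intensities <- purrr::map2_dfr(
    cohort$subjects, subject_reps,
    function(sub, reps) {
      purrr::map_dfr(sessions, function(sess) {
        intensity_table(
          prepare_series(sub$rest[[sess]]$series), reps, n_top_used,
          subject = sub$id
        )
      }) |>
        label_conditions(sub$association)
    }
  )
  ratings <- purrr::map_dfr(cohort$subjects, function(sub) {
    tibble::tibble(
      subject = sub$id,
      sentence_id = sub$ratings$sentence_id,
      rating = sub$ratings$rating
    )
  })

  # --- group stage (main session: day2pre) ---
  pre <- dplyr::filter(intensities, .data$session == "day2pre")
  per_subject <- list(
    w_prior = per_subject_correlation(pre, ratings, "w_prior"),
    wo_prior = per_subject_correlation(pre, ratings, "wo_prior")
  )
  m_w <- test_merged_zero(
    merge_correlations(per_subject$w_prior), config$sidedness$main
  )
  m_wo <- test_merged_zero(
    merge_correlations(per_subject$wo_prior), config$sidedness$main
  )
  p_corr <- bonferroni(c(m_w$p_value, m_wo$p_value), 2)

  stability <- stability_test(
    intensities, "day2pre", "day2post",
    alternative = config$sidedness$stability
  )

  tests <- list(
    w_prior = m_w,
    wo_prior = m_wo,
    p_bonferroni = setNames(p_corr, c("w_prior", "wo_prior")),
    comparison = compare_merged(m_w, m_wo, config$sidedness$comparison),
    split_w_prior = above_below_split(
      pre, ratings, "w_prior", config$sidedness$split
    ),
    split_wo_prior = above_below_split(
      pre, ratings, "wo_prior", config$sidedness$split
    ),
    stability = stability
  )

  results <- list(
    config = config,
    config_hash = rlang::hash(config),
    seed = config$seed,
    n_top_used = n_top_used,
    n_top_by_subject = n_top_detail,
    intensities = intensities,
    ratings = ratings,
    per_subject = per_subject,
    tests = tests
  )

  if (config$run_searchlight) {
    results$searchlight <- run_searchlight_stage(cohort, subject_reps, config)
  }
  structure(results, class = "preplay_results")
}

# Paired across subjects: mean intensity per subject in session B minus A,
# within each condition.
stability_test <- function(intensities, session_a, session_b,
                           alternative = "greater") {
  by_cond <- lapply(c("w_prior", "wo_prior"), function(cond) {
    wide <- intensities |>
      dplyr::filter(
        .data$condition == cond,
        .data$session %in% c(session_a, session_b)
      ) |>
      dplyr::group_by(.data$subject, .data$session) |>
      dplyr::summarise(mean_intensity = mean(.data$intensity), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "session", values_from = "mean_intensity")
    ht <- t.test(wide[[session_b]], wide[[session_a]],
      paired = TRUE, alternative = alternative
    )
    tibble::tibble(
      condition = cond,
      mean_diff = unname(ht$estimate),
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      sidedness = alternative
    )
  })
  dplyr::bind_rows(by_cond)
}

run_searchlight_stage <- function(cohort, subject_reps, config) {
  spec <- cohort$spec
  maps <- lapply(cohort$subjects, function(sub) {
    # full-grid t-map volumes for this subject's filtered reps
    reps <- subject_reps[[sub$id]]
    mask <- reps[[1]]$mask
    tvols <- lapply(reps, function(r) {
      v <- array(0, dim(mask))
      v[which(mask)] <- r$values
      v
    })
    series <- sub$rest$day2pre$series
    k <- config$discard_initial
    dat <- if (k > 0) series$data[-seq_len(k), , drop = FALSE] else series$data
    vol <- matrix_to_volume(dat, series$mask)
    sl <- searchlight_intensity(
      vol, tvols, mask,
      n_top = config$searchlight_n_top,
      radius = config$searchlight_radius
    )
    searchlight_matrix(
      sl, vapply(reps, function(r) as.character(r$sentence_id), character(1))
    )
  })
  names(maps) <- vapply(cohort$subjects, function(s) as.character(s$id), character(1))
  conditions <- purrr::map_dfr(cohort$subjects, function(sub) {
    tibble::tibble(
      subject = sub$id,
      sentence_id = sub$association$posterior_id,
      condition = ifelse(sub$association$associated, "w_prior", "wo_prior")
    )
  })
  ratings <- purrr::map_dfr(cohort$subjects, function(sub) {
    tibble::tibble(
      subject = sub$id,
      sentence_id = sub$ratings$sentence_id,
      rating = sub$ratings$rating
    )
  })
  mask <- subject_reps[[1]][[1]]$mask
  condition_contrast_map(
    maps, ratings, conditions, mask,
    n_permutations = config$n_permutations, seed = config$seed
  )
}

#' @export
print.preplay_results <- function(x, ...) {
  cat(sprintf(
    "<preplay_results> N_top = %d, %d subjects (config %s)\n",
    x$n_top_used, length(unique(x$intensities$subject)),
    substr(x$config_hash, 1, 8)
  ))
  cat(sprintf(
    "  w/prior:  r_merged = %.3f, p = %.4g\n",
    x$tests$w_prior$r_merged, x$tests$w_prior$p_value
  ))
  cat(sprintf(
    "  w/o prior: r_merged = %.3f, p = %.4g\n",
    x$tests$wo_prior$r_merged, x$tests$wo_prior$p_value
  ))
  cat(sprintf(
    "  comparison p = %.4g; split p (w/prior) = %.4g, (w/o prior) = %.4g\n",
    x$tests$comparison$p_value, x$tests$split_w_prior$p_value,
    x$tests$split_wo_prior$p_value
  ))
  invisible(x)
}

#' Serialize a results bundle to JSON
#'
#' Writes the scalar test results (per test: zeta, SE, r_merged, z, p), the
#' chosen N, the config and its hash to a JSON file; per-subject correlation
#' tables go to a TSV next to it.
#'
#' @param results A `preplay_results` from [run_pipeline()].
#' @param dir Output directory.
#' @return Invisibly, the JSON path.
#' @export
write_results <- function(results, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  as_row <- function(m) {
    list(
      zeta = m$zeta, se = m$se, r_merged = m$r_merged,
      z = m$z_stat, p_value = m$p_value, sidedness = m$sidedness,
      n_subjects = m$n_subjects
    )
  }
  payload <- list(
    config_hash = results$config_hash,
    seed = results$seed,
    n_top_used = results$n_top_used,
    tests = list(
      w_prior = as_row(results$tests$w_prior),
      wo_prior = as_row(results$tests$wo_prior),
      p_bonferroni = as.list(results$tests$p_bonferroni),
      comparison = as.list(results$tests$comparison),
      split_w_prior = list(
        statistic = results$tests$split_w_prior$statistic,
        df = results$tests$split_w_prior$df,
        p_value = results$tests$split_w_prior$p_value
      ),
      split_wo_prior = list(
        statistic = results$tests$split_wo_prior$statistic,
        df = results$tests$split_wo_prior$df,
        p_value = results$tests$split_wo_prior$p_value
      ),
      stability = lapply(
        split(results$tests$stability, results$tests$stability$condition),
        as.list
      )
    ),
    config = unclass_deep(results$config)
  )
  path <- file.path(dir, "results.json")
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_tsv(
    dplyr::bind_rows(results$per_subject),
    file.path(dir, "per_subject_correlations.tsv"),
    progress = FALSE
  )
  invisible(path)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}
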
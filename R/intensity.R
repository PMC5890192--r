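# The core reactivation statistic: z-scored resting frames, per-frame pattern
# correlation, Fisher Z, top-N mean, and the variance-decomposition estimator
# of N.

#' Standardize voxel time courses to z-scores
#'
#' Each voxel's resting time course is centered and scaled to unit variance
#' (population SD), removing spatial mean/scale biases before pattern
#' correlation. Voxels with (numerically) constant time courses are flagged
#' degenerate and excluded from all later correlations rather than producing
#' NaNs.
#'
#' @param series A [resting_series] with at least 2 frames.
#' @return The z-scored [resting_series] (idempotent: z-scoring twice changes
#'   nothing beyond numerical noise).
#' @export
zscore_voxels <- function(series) {
  stopifnot(inherits(series, "resting_series"))
  if (nrow(series$data) < 2L) {
    abort("need at least 2 frames to z-score voxel time courses.")
  }
  mu <- colMeans(series$data)
  sdv <- sqrt(col_vars(series$data, ddof = 0L))
  degenerate <- sdv <= 1e-12 * pmax(abs(mu), 1)
  if (all(degenerate)) {
    abort("all voxel time courses are constant; nothing to standardize.")
  }
  data <- sweep(series$data, 2L, mu)
  data[, !degenerate] <- sweep(
    data[, !degenerate, drop = FALSE], 2L, sdv[!degenerate], "/"
  )
  data[, degenerate] <- 0
  resting_series(data, series$mask,
    session = series$session, zscored = TRUE,
    degenerate = degenerate | series$degenerate
  )
}

#' Per-frame correlation between a resting series and a representation
#'
#' For every resting frame, the Pearson correlation between the
#' representation's voxel values and the frame's voxel pattern, over the
#' voxels shared by the series and the map (degenerate voxels excluded).
#' Frames whose pattern has zero variance across voxels yield `NA` and are
#' excluded downstream.
#'
#' @param series A z-scored [resting_series] (see [zscore_voxels()]).
#' @param rep A [representation_map] on the same voxel grid.
#' @return Numeric vector, one correlation per frame (may contain `NA`).
#' @export
pattern_correlation_timecourse <- function(series, rep) {
  stopifnot(inherits(series, "resting_series"), inherits(rep, "representation_map"))
  if (!series$zscored) {
    warn("series is not z-scored; call zscore_voxels() first.")
  }
  idx <- shared_voxel_index(series, rep)
  frames <- series$data[, idx$series_cols, drop = FALSE]
  row_correlations(frames, rep$values[idx$rep_cols])
}

#' Reactivation intensities for a set of sentences in one resting session
#'
#' Composes the statistic: z-score the series, correlate every frame with
#' each sentence's representation, Fisher-transform, and average the `n_top`
#' largest values per sentence.
#'
#' @param series A [resting_series] (z-scored automatically if not already).
#' @param reps List of [representation_map] objects sharing one (filtered)
#'   mask.
#' @param n_top Number of top Fisher Z values to average.
#' @param subject Subject identifier stamped on the records.
#' @param condition Optional condition label (otherwise `NA`; use
#'   [label_conditions()] to fill from an association table).
#' @return Tibble with one row per sentence: `subject`, `sentence_id`,
#'   `session`, `condition`, `n_top`, `intensity`.
#' @export
intensity_table <- function(series, reps, n_top, subject = NA,
                            condition = NA_character_) {
  if (!series$zscored) {
    series <- zscore_voxels(series)
  }
  purrr::map_dfr(reps, function(rep) {
    r <- pattern_correlation_timecourse(series, rep)
    tibble::tibble(
      subject = subject,
      sentence_id = rep$sentence_id,
      session = series$session,
      condition = condition,
      n_top = as.integer(n_top),
      intensity = topn_mean(fisher_z(r), n_top)
    )
  })
}

#' Label intensity records with their association condition
#'
#' Joins an intensity table with a subject's association table, labelling
#' each posterior sentence `"w_prior"` or `"wo_prior"`.
#'
#' @param intensities Tibble from [intensity_table()].
#' @param association Tibble with columns `posterior_id`, `associated` (per
#'   subject: also a `subject` column if `intensities` spans subjects).
#' @return `intensities` with `condition` filled in.
#' @export
label_conditions <- function(intensities, association) {
  by <- intersect(c("subject", "sentence_id"), names(intensities))
  assoc <- association |>
    dplyr::rename(sentence_id = "posterior_id") |>
    dplyr::select(dplyr::any_of(c("subject", "sentence_id", "associated")))
  intensities |>
    dplyr::select(-"condition") |>
    dplyr::left_join(assoc, by = intersect(by, names(assoc))) |>
    dplyr::mutate(
      condition = dplyr::if_else(.data$associated, "w_prior", "wo_prior")
    ) |>
    dplyr::select(-"associated")
}

#' Estimate the number of top frames to average
#'
#' The intensity's variance across sentences decomposes into a noise part
#' proportional to \eqn{1/N} and a signal part. For each candidate `N` in
#' `grid`, the variance across sentences of the top-`N` intensities is
#' computed; an ordinary least-squares fit of variance on \eqn{1/N} (with
#' intercept) absorbs the noise component, and the per-point residual is
#' taken as the signal component. The chosen `N` maximizes that residual;
#' exact ties (including the all-zero residual profile of pure noise) resolve
#' to the smallest grid value.
#'
#' @param series A [resting_series].
#' @param reps List of [representation_map] objects (at least 2 sentences).
#' @param grid Candidate counts (at least 3), all within the frame count.
#' @return An object of class `ntop_estimate` with fields `grid`,
#'   `variance_curve`, `signal_curve`, `chosen`.
#' @seealso [choose_ntop()], [aggregate_ntop()]
#' @export
estimate_ntop <- function(series, reps, grid = seq(10, 80, by = 5)) {
  if (length(reps) < 2L) {
    abort("need at least 2 sentences to compute a variance across sentences.")
  }
  if (length(grid) < 3L) {
    abort("`grid` needs at least 3 candidate values.")
  }
  if (!series$zscored) {
    series <- zscore_voxels(series)
  }
  z <- vapply(
    reps,
    function(rep) fisher_z(pattern_correlation_timecourse(series, rep)),
    numeric(nrow(series$data))
  )
  n_avail <- min(colSums(!is.na(z)))
  if (max(grid) > n_avail) {
    abort(sprintf(
      "grid maximum (%d) exceeds available frames (%d).",
      max(grid), n_avail
    ))
  }
  variance_curve <- vapply(grid, function(n) {
    var(apply(z, 2L, topn_mean, n_top = n))
  }, numeric(1))
  choose_ntop(grid, variance_curve)
}

#' Pick N from a variance curve
#'
#' The curve-fitting core of [estimate_ntop()], exposed so analytic curves
#' can be fed in directly: OLS of the variance curve on `1/grid` with
#' intercept, residuals as the signal component, argmax with smallest-value
#' tie breaking.
#'
#' @param grid Candidate counts.
#' @param variance_curve Variance across sentences at each grid point.
#' @return An `ntop_estimate` object.
#' @export
choose_ntop <- function(grid, variance_curve) {
  stopifnot(length(grid) == length(variance_curve), length(grid) >= 3L)
  fit <- lm.fit(cbind(intercept = 1, inv_n = 1 / grid), variance_curve)
  signal <- as.numeric(fit$residuals)
  tol <- 1e-8 * max(abs(variance_curve), 1e-300)
  top <- max(signal)
  chosen <- min(grid[signal >= top - tol])
  structure(
    list(
      grid = as.numeric(grid),
      variance_curve = as.numeric(variance_curve),
      signal_curve = signal,
      coefficients = coef(fit),
      chosen = chosen
    ),
    class = "ntop_estimate"
  )
}

#' @export
print.ntop_estimate <- function(x, ...) {
  cat(sprintf(
    "<ntop_estimate> chosen N = %g over grid [%g..%g] (%d points)\n",
    x$chosen, min(x$grid), max(x$grid), length(x$grid)
  ))
  invisible(x)
}

#' Aggregate per-subject N estimates to a group value
#'
#' The group-level choice is the mean of per-subject chosen values, rounded
#' half-up to the nearest grid value (so e.g. a mean of 14.8 on a grid with
#' step 5 snaps to 15).
#'
#' @param chosen Numeric vector of per-subject chosen values.
#' @param grid The candidate grid.
#' @return A single grid value.
#' @export
aggregate_ntop <- function(chosen, grid) {
  m <- mean(chosen)
  d <- abs(grid - m)
  max(grid[d == min(d)]) # equidistant -> round up
}
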
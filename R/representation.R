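# First-level GLM: design construction, voxelwise OLS t-maps, and the
# informative-voxel filter.

#' Build a first-level design matrix
#'
#' One HRF-convolved boxcar regressor per sentence (spanning all sessions,
#' convolved within session) plus one intercept column per session. Sessions
#' are concatenated in order.
#'
#' @param events Data frame with columns `onset` (seconds), `duration`
#'   (seconds), `sentence_id`, `session`.
#' @param n_frames Frames per session: a scalar (all sessions equal) or a
#'   vector named/ordered by session.
#' @param tr Repetition time in seconds.
#' @param hrf `"spm"` (canonical double-gamma), `"identity"` (raw boxcar), or
#'   a numeric kernel.
#' @return An object of class `design_matrix`: the matrix `X`, `labels`,
#'   indices of the task columns (`task_cols`), per-frame `session` index and
#'   `tr`.
#' @export
build_design_matrix <- function(events, n_frames, tr, hrf = "spm") {
  req <- c("onset", "duration", "sentence_id", "session")
  if (!all(req %in% names(events))) {
    abort(sprintf("`events` needs columns %s.", paste(req, collapse = ", ")))
  }
  sessions <- sort(unique(events$session))
  n_sessions <- length(sessions)
  if (length(n_frames) == 1L) {
    n_frames <- rep(n_frames, n_sessions)
  }
  if (length(n_frames) != n_sessions) {
    abort("`n_frames` must be scalar or one value per session.")
  }
  sentence_ids <- sort(unique(events$sentence_id))
  for (k in seq_len(n_sessions)) {
    ev <- events[events$session == sessions[k], ]
    if (any(ev$onset < 0 | ev$onset + ev$duration > n_frames[k] * tr)) {
      abort(sprintf(
        "events fall outside session %s (duration %g s).",
        format(sessions[k]), n_frames[k] * tr
      ))
    }
  }
  total <- sum(n_frames)
  x_task <- matrix(0, total, length(sentence_ids))
  offset <- c(0, cumsum(n_frames))[seq_len(n_sessions)]
  for (k in seq_len(n_sessions)) {
    ev <- events[events$session == sessions[k], ]
    for (j in seq_len(nrow(ev))) {
      col <- match(ev$sentence_id[j], sentence_ids)
      box <- event_boxcar(ev$onset[j], ev$duration[j], n_frames[k], tr)
      x_task[offset[k] + seq_len(n_frames[k]), col] <-
        x_task[offset[k] + seq_len(n_frames[k]), col] +
        convolve_boxcar(box, tr, hrf)
    }
  }
  x_sess <- matrix(0, total, n_sessions)
  for (k in seq_len(n_sessions)) {
    x_sess[offset[k] + seq_len(n_frames[k]), k] <- 1
  }
  x <- cbind(x_task, x_sess)
  labels <- c(
    paste0("sentence_", sentence_ids),
    paste0("session_", sessions)
  )
  colnames(x) <- labels
  qr_x <- qr(x)
  if (qr_x$rank < ncol(x)) {
    dropped <- labels[qr_x$pivot[seq.int(qr_x$rank + 1, ncol(x))]]
    abort(sprintf(
      "design matrix is rank deficient; collinear columns: %s.",
      paste(dropped, collapse = ", ")
    ))
  }
  structure(
    list(
      X = x, labels = labels,
      task_cols = seq_along(sentence_ids),
      sentence_ids = sentence_ids,
      session_index = rep(seq_len(n_sessions), n_frames),
      tr = tr, hrf = if (is.numeric(hrf)) "custom" else hrf
    ),
    class = "design_matrix"
  )
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf(
    "<design_matrix> %d frames x %d regressors (%d task, %d session), hrf = %s\n",
    nrow(x$X), ncol(x$X), length(x$task_cols),
    ncol(x$X) - length(x$task_cols), x$hrf
  ))
  invisible(x)
}

#' Fit voxelwise GLM and extract per-sentence t-maps
#'
#' Ordinary least squares per voxel over the concatenated sessions; each
#' sentence's t-statistic is its regressor's estimate divided by its standard
#' error, with residual degrees of freedom `frames - rank(X)`. The resulting
#' t-map per sentence is the sentence's neural representation.
#'
#' @param series Frames-by-voxels numeric matrix (concatenated sessions), or
#'   a list of per-session matrices which are row-concatenated.
#' @param design A `design_matrix` from [build_design_matrix()].
#' @param mask Logical 3D array giving the voxel geometry of the columns.
#' @return A list of [representation_map] objects, one per sentence, in
#'   `design$sentence_ids` order.
#' @export
fit_glm_tmaps <- function(series, design, mask) {
  if (is.list(series) && !is.matrix(series)) {
    series <- do.call(rbind, series)
  }
  x <- design$X
  if (nrow(series) != nrow(x)) {
    abort(sprintf(
      "series has %d frames but design expects %d.", nrow(series), nrow(x)
    ))
  }
  dof <- nrow(x) - qr(x)$rank
  if (dof <= 0) {
    abort("non-positive residual degrees of freedom.")
  }
  fit <- lm.fit(x, series)
  beta <- fit$coefficients
  res <- fit$residuals
  sigma2 <- colSums(res^2) / dof
  xtx_inv <- chol2inv(chol(crossprod(x)))
  lapply(seq_along(design$task_cols), function(j) {
    col <- design$task_cols[j]
    se <- sqrt(sigma2 * xtx_inv[col, col])
    tval <- beta[col, ] / se
    representation_map(
      design$sentence_ids[j], as.numeric(tval), mask,
      source = "glm"
    )
  })
}

#' Drop the least informative voxels across sentence t-maps
#'
#' For each voxel, the variance of its t-value across sentences is computed
#' (population variance); voxels strictly below the `drop_fraction` quantile
#' of these variances are removed. Ties at the cutoff are kept, so the filter
#' is deterministic and conservative; with an all-equal variance profile no
#' voxel is removed.
#'
#' @param tmaps List of [representation_map] objects sharing a mask (at least
#'   two).
#' @param drop_fraction Fraction of voxels to drop (default 0.03, the lowest
#'   3% of t-value variances).
#' @return Logical vector over the in-mask voxels: `TRUE` = keep. The updated
#'   3D mask is attached as attribute `"mask"`.
#' @seealso [apply_voxel_filter()]
#' @export
select_informative_voxels <- function(tmaps, drop_fraction = 0.03) {
  if (length(tmaps) < 2L) {
    abort("need at least 2 t-maps to compute cross-sentence variances.")
  }
  if (drop_fraction < 0 || drop_fraction >= 1) {
    abort("`drop_fraction` must be in [0, 1).")
  }
  tmat <- do.call(rbind, lapply(tmaps, `[[`, "values"))
  v <- col_vars(tmat, ddof = 0L)
  cutoff <- quantile(v, drop_fraction, names = FALSE, type = 7)
  keep <- v >= cutoff
  mask3d <- tmaps[[1]]$mask
  new_mask <- array(FALSE, dim(mask3d))
  new_mask[which(mask3d)[keep]] <- TRUE
  attr(keep, "mask") <- new_mask
  keep
}

#' Apply a voxel filter to a set of representation maps
#'
#' @param tmaps List of [representation_map] objects.
#' @param keep Logical keep-vector from [select_informative_voxels()].
#' @return The filtered list, with values subset and masks updated.
#' @export
apply_voxel_filter <- function(tmaps, keep) {
  new_mask <- attr(keep, "mask")
  if (is.null(new_mask)) {
    new_mask <- array(FALSE, dim(tmaps[[1]]$mask))
    new_mask[which(tmaps[[1]]$mask)[keep]] <- TRUE
  }
  lapply(tmaps, function(r) {
    representation_map(r$sentence_id, r$values[keep], new_mask, r$source)
  })
}
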
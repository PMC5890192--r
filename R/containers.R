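# Lightweight S3 containers for volumetric objects. Tabular results are plain
# tibbles; these classes only wrap what is genuinely non-tabular: a voxel
# pattern over a mask, and a frames-by-voxels resting time series.

#' Construct a representation map
#'
#' A representation map is one sentence's neural representation: a value per
#' in-mask voxel (a t-statistic after GLM fitting, or a planted ground-truth
#' pattern in synthetic data). Values are stored in the column-major order of
#' `which(mask)`.
#'
#' @param sentence_id Identifier of the sentence the pattern encodes.
#' @param values Numeric vector, one value per `TRUE` voxel of `mask`.
#' @param mask Logical 3D array marking the voxels the pattern covers.
#' @param source Optional character tag recording where the map came from
#'   (e.g. session ids).
#' @return An object of class `representation_map`.
#' @export
representation_map <- function(sentence_id, values, mask, source = NULL) {
  mask <- validate_mask(mask)
  if (!is.numeric(values) || length(values) != sum(mask)) {
    abort("`values` must be numeric with one entry per in-mask voxel.")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort("representation values must all be finite.")
  }
  structure(
    list(
      sentence_id = sentence_id,
      values = as.numeric(values),
      mask = mask,
      source = source
    ),
    class = "representation_map"
  )
}

#' @export
print.representation_map <- function(x, ...) {
  cat(
    sprintf(
      "<representation_map> sentence %s: %d voxels, grid %s\n",
      format(x$sentence_id), length(x$values),
      paste(dim(x$mask), collapse = "x")
    )
  )
  invisible(x)
}

#' Construct a resting-state series
#'
#' A resting series is a frames-by-voxels matrix of BOLD values over an
#' in-mask voxel set, plus bookkeeping: whether voxel time courses have been
#' z-scored, which voxels are degenerate (constant over time, excluded from
#' correlations), and a session label.
#'
#' @param data Numeric matrix, frames in rows, in-mask voxels in columns
#'   (column order = `which(mask)`).
#' @param mask Logical 3D array.
#' @param session Session label (e.g. `"day1"`, `"day2pre"`, `"day2post"`).
#' @param zscored Logical flag: have voxel time courses been standardized?
#' @param degenerate Logical vector marking constant voxels; defaults to none.
#' @return An object of class `resting_series`.
#' @seealso [zscore_voxels()]
#' @export
resting_series <- function(data, mask, session = "rest", zscored = FALSE,
                           degenerate = NULL) {
  mask <- validate_mask(mask)
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix (frames x voxels).")
  }
  if (ncol(data) != sum(mask)) {
    abort("`data` must have one column per in-mask voxel.")
  }
  degenerate <- degenerate %||% rep(FALSE, ncol(data))
  if (!is.logical(degenerate) || length(degenerate) != ncol(data)) {
    abort("`degenerate` must be a logical vector, one flag per voxel.")
  }
  structure(
    list(
      data = data,
      mask = mask,
      session = session,
      zscored = isTRUE(zscored),
      degenerate = degenerate
    ),
    class = "resting_series"
  )
}

#' @export
print.resting_series <- function(x, ...) {
  cat(
    sprintf(
      "<resting_series> session %s: %d frames x %d voxels%s (%d degenerate)\n",
      x$session, nrow(x$data), ncol(x$data),
      if (x$zscored) ", z-scored" else "", sum(x$degenerate)
    )
  )
  invisible(x)
}

validate_mask <- function(mask) {
  if (is.numeric(mask)) {
    mask <- array(mask != 0, dim = dim(mask))
  }
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask)) {
    abort("`mask` must be a logical 3D array.")
  }
  if (!any(mask)) {
    abort("`mask` is empty: no voxels selected.")
  }
  mask
}

# Indices (within series columns) of voxels shared by a series and a
# representation map, excluding degenerate ones. Both objects must live on the
# same grid.
shared_voxel_index <- function(series, rep) {
  if (!identical(dim(series$mask), dim(rep$mask))) {
    abort("series and representation masks are on different voxel grids.")
  }
  series_idx <- which(series$mask)
  rep_idx <- which(rep$mask)
  keep <- series_idx %in% rep_idx & !series$degenerate
  if (sum(keep) < 3L) {
    abort("fewer than 3 shared non-degenerate voxels between series and map.")
  }
  list(
    series_cols = which(keep),
    rep_cols = match(series_idx[keep], rep_idx)
  )
}
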
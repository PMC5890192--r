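# broom-style tidiers for the fitted objects.

#' Tidy a merged correlation
#'
#' One row per contributing subject, with Fisher Z values and merge weights.
#'
#' @param x A `merged_correlation`.
#' @param ... Unused.
#' @return A tibble with columns `subject` (if present), `r`, `n`, `z`,
#'   `weight`.
#' @export
tidy.merged_correlation <- function(x, ...) {
  x$subjects
}

#' @rdname tidy.merged_correlation
#' @return For `glance()`: a one-row tibble with `zeta`, `se`, `r_merged`,
#'   `z_stat`, `p_value`, `sidedness`, `n_subjects`.
#' @export
glance.merged_correlation <- function(x, ...) {
  tibble::tibble(
    zeta = x$zeta,
    se = x$se,
    r_merged = x$r_merged,
    z_stat = x$z_stat %||% NA_real_,
    p_value = x$p_value %||% NA_real_,
    sidedness = x$sidedness %||% NA_character_,
    n_subjects = x$n_subjects
  )
}

#' Tidy an above/below split test
#'
#' @param x A `split_test`.
#' @param ... Unused.
#' @return One row per subject with the two side means.
#' @export
tidy.split_test <- function(x, ...) {
  x$per_subject
}

#' @rdname tidy.split_test
#' @export
glance.split_test <- function(x, ...) {
  tibble::tibble(
    estimate = x$estimate,
    statistic = x$statistic,
    df = x$df,
    p_value = x$p_value,
    sidedness = x$sidedness,
    condition = x$condition,
    n_subjects = nrow(x$per_subject)
  )
}

#' Tidy an N-selection estimate
#'
#' @param x An `ntop_estimate`.
#' @param ... Unused.
#' @return One row per grid point: `n_top`, `variance`, `signal`.
#' @export
tidy.ntop_estimate <- function(x, ...) {
  tibble::tibble(
    n_top = x$grid,
    variance = x$variance_curve,
    signal = x$signal_curve
  )
}

#' @rdname tidy.ntop_estimate
#' @export
glance.ntop_estimate <- function(x, ...) {
  tibble::tibble(
    chosen = x$chosen,
    intercept = unname(x$coefficients[1]),
    slope_inv_n = unname(x$coefficients[2]),
    n_grid = length(x$grid)
  )
}
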
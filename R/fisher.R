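#' Fisher Z transform of a correlation coefficient
#'
#' `fisher_z()` computes the variance-stabilizing transform
#' \eqn{Z = \frac{1}{2}\ln\frac{1+r}{1-r}} and `inverse_fisher()` its inverse
#' \eqn{r = \tanh(Z)}. Correlations with \eqn{|r| \ge 1 - 10^{-12}} are clamped
#' to \eqn{\pm(1 - 10^{-12})} before transforming, so perfectly correlated
#' inputs (which arise in noiseless synthetic data) map to large finite values
#' rather than infinities.
#'
#' @param r Numeric vector of correlation coefficients in \eqn{[-1, 1]}.
#'   Values of `NA` pass through.
#' @return Numeric vector of Fisher Z values.
#' @examples
#' fisher_z(0.5)
#' inverse_fisher(fisher_z(0.3)) # 0.3
#' @seealso [topn_mean()], [merge_correlations()]
#' @export
fisher_z <- function(r) {
  if (!is.numeric(r)) {
    abort("`r` must be numeric.")
  }
  bad <- !is.na(r) & abs(r) > 1
  if (any(bad)) {
    abort("`r` contains values outside [-1, 1].")
  }
  atanh(clamp(r, -1 + 1e-12, 1 - 1e-12))
}

#' @rdname fisher_z
#' @param z Numeric vector of Fisher Z values.
#' @export
inverse_fisher <- function(z) {
  if (!is.numeric(z)) {
    abort("`z` must be numeric.")
  }
  tanh(z)
}

#' Mean of the largest n values
#'
#' The reactivation-intensity summary: the mean of the `n_top` largest values
#' of a vector of per-frame Fisher Z correlations. Missing values (undefined
#' correlations from degenerate frames) are excluded before selection;
#' requesting more values than are available is an error, never a silent
#' truncation.
#'
#' @param z Numeric vector (typically Fisher Z values, one per resting frame).
#' @param n_top Number of largest values to average; a single positive integer.
#' @return The mean of the `n_top` largest finite values of `z`.
#' @examples
#' topn_mean(c(0.5, 0.4, 0.3, 0.2), 2) # 0.45
#' @export
topn_mean <- function(z, n_top) {
  if (!is.numeric(z)) {
    abort("`z` must be numeric.")
  }
  if (length(n_top) != 1L || !is.finite(n_top) || n_top < 1 ||
      n_top != round(n_top)) {
    abort("`n_top` must be a single positive integer.")
  }
  z <- z[!is.na(z)]
  if (n_top > length(z)) {
    abort(sprintf(
      "`n_top` (%d) exceeds the number of available values (%d).",
      as.integer(n_top), length(z)
    ))
  }
  mean(sort(z, decreasing = TRUE)[seq_len(n_top)])
}
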
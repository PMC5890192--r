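# ggplot2 visualizations for each result type.

#' Scatter of reactivation intensity against understanding rating
#'
#' One point per (subject, sentence), coloured by subject and faceted by
#' condition, with per-subject least-squares lines — the standard display of
#' the intensity-rating coupling.
#'
#' @param intensities Tibble with `subject`, `sentence_id`, `condition`,
#'   `intensity`.
#' @param ratings Tibble with `subject`, `sentence_id`, `rating`.
#' @return A ggplot object.
#' @export
plot_intensity_rating <- function(intensities, ratings) {
  df <- dplyr::inner_join(intensities, ratings,
    by = c("subject", "sentence_id")
  )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$intensity, y = .data$rating,
      colour = factor(.data$subject)
    )
  ) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(
      method = "lm", formula = y ~ x, se = FALSE, linewidth = 0.4
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(
      x = "reactivation intensity (mean top-N Fisher Z)",
      y = "understanding rating",
      colour = "subject"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.merged_correlation <- function(object, ...) {
  df <- tidy(object)
  df$subject <- factor(df$subject %||% seq_len(nrow(df)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$r, y = .data$subject)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$weight)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_vline(
      xintercept = object$r_merged, colour = "red", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "per-subject correlation r", y = "subject",
      size = "merge weight",
      title = sprintf("merged r = %.3f", object$r_merged)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ntop_estimate <- function(object, ...) {
  df <- tidy(object)
  fit <- object$coefficients[1] + object$coefficients[2] / df$n_top
  df$fitted <- fit
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_top)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$variance)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "grey50") +
    ggplot2::geom_col(
      ggplot2::aes(y = .data$signal),
      alpha = 0.3, fill = "steelblue"
    ) +
    ggplot2::geom_vline(
      xintercept = object$chosen, colour = "red", linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "N (top frames averaged)",
      y = "variance across sentences / signal residual",
      title = sprintf("chosen N = %g", object$chosen)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.split_test <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(
      c("mean_above", "mean_below"),
      names_to = "side", values_to = "mean_rating"
    ) |>
    dplyr::mutate(
      side = dplyr::if_else(
        .data$side == "mean_above", "above average", "below average"
      )
    )
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = .data$side, y = .data$mean_rating, group = .data$subject
    )
  ) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "reactivation intensity side", y = "mean understanding rating",
      title = sprintf(
        "t(%d) = %.2f, p = %.3g", object$df, object$statistic, object$p_value
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a searchlight statistic or p-map slice
#'
#' @param x A `contrast_map`.
#' @param slice z-index of the axial slice to show (default: middle).
#' @param what `"statistic"` or `"p_fwe"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_contrast_slice <- function(x, slice = NULL, what = c("statistic", "p_fwe"),
                                ...) {
  what <- match.arg(what)
  vol <- x[[what]]
  slice <- slice %||% ceiling(dim(vol)[3] / 2)
  df <- expand.grid(x = seq_len(dim(vol)[1]), y = seq_len(dim(vol)[2]))
  df$value <- as.vector(vol[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%s, axial slice %d", what, slice), fill = what
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
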
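# Group-level statistics: per-subject intensity-rating correlations, the
# sample-size-weighted Fisher-Z merge, z-tests, the above/below-average split,
# and Bonferroni correction.

#' Per-subject correlation between reactivation intensity and rating
#'
#' Joins intensity records with ratings on subject and sentence, optionally
#' restricted to one condition, and computes each subject's Pearson
#' correlation. Subjects with fewer than `min_n` matched sentences, or with
#' zero variance in either variable, are dropped with a warning: the merge's
#' weights require `n > 3`.
#'
#' @param intensities Tibble with columns `subject`, `sentence_id`,
#'   `intensity` (and optionally `condition`).
#' @param ratings Tibble with columns `subject`, `sentence_id`, `rating`.
#' @param condition Optional condition filter (e.g. `"w_prior"`).
#' @param min_n Minimum sentences per subject (default 4).
#' @return Tibble with one row per retained subject: `subject`, `condition`,
#'   `r`, `n`.
#' @export
per_subject_correlation <- function(intensities, ratings, condition = NULL,
                                    min_n = 4L) {
  df <- dplyr::inner_join(
    intensities, ratings,
    by = c("subject", "sentence_id"),
    suffix = c("", ".rating")
  )
  if (!is.null(condition)) {
    df <- dplyr::filter(df, .data$condition == !!condition)
  }
  cond_label <- condition %||% NA_character_
  out <- df |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(
      n = dplyr::n(),
      sd_i = sd(.data$intensity),
      sd_r = sd(.data$rating),
      r = if (dplyr::n() >= 2 && sd(.data$intensity) > 0 && sd(.data$rating) > 0) {
        cor(.data$intensity, .data$rating)
      } else {
        NA_real_
      },
      .groups = "drop"
    )
  bad <- out$n < min_n | is.na(out$r)
  if (any(bad)) {
    warn(sprintf(
      "dropping %d subject(s) with too few sentences or degenerate data: %s",
      sum(bad), paste(out$subject[bad], collapse = ", ")
    ))
  }
  out |>
    dplyr::filter(!bad) |>
    dplyr::transmute(
      subject = .data$subject,
      condition = cond_label,
      r = .data$r,
      n = as.integer(.data$n)
    )
}

#' Merge per-subject correlations with sample-size weights
#'
#' The fixed-effect Fisher-Z merge: each correlation is transformed to
#' \eqn{Z_i = \mathrm{atanh}(r_i)}, weighted by
#' \eqn{w_i = (n_i - 3) / \sum_j (n_j - 3)}, and summed to
#' \eqn{\zeta = \sum_i w_i Z_i}. The merged correlation is
#' \eqn{r_{merged} = \tanh(\zeta)} and the standard error of \eqn{\zeta} is
#' \eqn{1 / \sqrt{\sum_i (n_i - 3)}} (each \eqn{Z_i} has standard error
#' \eqn{1/\sqrt{n_i - 3}}).
#'
#' @param subs Data frame with columns `r` and `n` (one row per subject),
#'   e.g. from [per_subject_correlation()]. All `n` must exceed 3.
#' @return An object of class `merged_correlation` with fields `zeta`, `se`,
#'   `r_merged`, `n_subjects` and the per-subject table (with weights).
#' @examples
#' m <- merge_correlations(data.frame(r = c(0.5, 0), n = c(13, 23)))
#' m$r_merged # 0.181
#' @export
merge_correlations <- function(subs) {
  if (!all(c("r", "n") %in% names(subs))) {
    abort("`subs` needs columns `r` and `n`.")
  }
  if (nrow(subs) < 1L) {
    abort("no subjects to merge.")
  }
  if (any(subs$n <= 3)) {
    abort("all sample sizes must exceed 3 (weights use n - 3).")
  }
  if (any(abs(subs$r) > 1)) {
    abort("correlations must lie in [-1, 1].")
  }
  k <- subs$n - 3
  w <- k / sum(k)
  z <- fisher_z(subs$r)
  zeta <- sum(w * z)
  structure(
    list(
      zeta = zeta,
      se = 1 / sqrt(sum(k)),
      r_merged = inverse_fisher(zeta),
      n_subjects = nrow(subs),
      subjects = tibble::as_tibble(subs) |>
        dplyr::mutate(z = z, weight = w),
      z_stat = NULL, p_value = NULL, sidedness = NULL
    ),
    class = "merged_correlation"
  )
}

#' @export
print.merged_correlation <- function(x, ...) {
  cat(sprintf(
    "<merged_correlation> r_merged = %.4f (zeta = %.4f, SE = %.4f, %d subjects)\n",
    x$r_merged, x$zeta, x$se, x$n_subjects
  ))
  if (!is.null(x$p_value)) {
    cat(sprintf(
      "  H0: zeta = 0, %s: z = %.3f, p = %.4g\n",
      x$sidedness, x$z_stat, x$p_value
    ))
  }
  invisible(x)
}

#' Test a merged correlation against zero
#'
#' Under the null \eqn{\zeta = 0}, \eqn{\zeta / SE_\zeta} is standard normal;
#' the p-value is taken from that distribution with the requested sidedness.
#'
#' @param m A `merged_correlation` from [merge_correlations()].
#' @param alternative `"greater"` (one-sided, positive association —
#'   the default for the directional main hypothesis), `"less"`, or
#'   `"two.sided"`.
#' @return `m` with `z_stat`, `p_value` and `sidedness` filled in.
#' @export
test_merged_zero <- function(m, alternative = c("greater", "less", "two.sided")) {
  stopifnot(inherits(m, "merged_correlation"))
  alternative <- match.arg(alternative)
  z <- m$zeta / m$se
  m$z_stat <- z
  m$p_value <- switch(alternative,
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z),
    two.sided = 2 * pnorm(-abs(z))
  )
  m$sidedness <- alternative
  m
}

#' Compare two merged correlations
#'
#' Under the null \eqn{\zeta_1 = \zeta_2} (independent subsets),
#' \eqn{(\zeta_1 - \zeta_2) / \sqrt{SE_1^2 + SE_2^2}} is standard normal.
#'
#' @param m1,m2 `merged_correlation` objects from independent condition
#'   subsets.
#' @param alternative `"two.sided"` (default), `"greater"` (\eqn{\zeta_1 >
#'   \zeta_2}), or `"less"`.
#' @return One-row tibble: `delta_zeta`, `se`, `z`, `p_value`, `sidedness`.
#' @export
compare_merged <- function(m1, m2,
                           alternative = c("two.sided", "greater", "less")) {
  stopifnot(
    inherits(m1, "merged_correlation"),
    inherits(m2, "merged_correlation")
  )
  alternative <- match.arg(alternative)
  se <- sqrt(m1$se^2 + m2$se^2)
  z <- (m1$zeta - m2$zeta) / se
  p <- switch(alternative,
    greater = pnorm(z, lower.tail = FALSE),
    less = pnorm(z),
    two.sided = 2 * pnorm(-abs(z))
  )
  tibble::tibble(
    delta_zeta = m1$zeta - m2$zeta, se = se, z = z,
    p_value = p, sidedness = alternative
  )
}

#' Split sentences at each subject's mean intensity and compare ratings
#'
#' Per subject, sentences are divided into those with reactivation intensity
#' above and below the subject's own mean; the subject contributes the mean
#' rating of each side. A paired t-test across subjects compares the two
#' sides. Subjects with all sentences on one side (e.g. constant intensity)
#' are dropped with a warning.
#'
#' @param intensities,ratings As in [per_subject_correlation()].
#' @param condition Optional condition filter.
#' @param alternative Sidedness of the paired t-test; default `"greater"`
#'   (above-mean reactivation predicts better understanding).
#' @return An object of class `split_test`: per-subject means, the t
#'   statistic, degrees of freedom, and p-value.
#' @export
above_below_split <- function(intensities, ratings, condition = NULL,
                              alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  df <- dplyr::inner_join(
    intensities, ratings,
    by = c("subject", "sentence_id"),
    suffix = c("", ".rating")
  )
  if (!is.null(condition)) {
    df <- dplyr::filter(df, .data$condition == !!condition)
  }
  per_subject <- df |>
    dplyr::group_by(.data$subject) |>
    dplyr::mutate(above = .data$intensity > mean(.data$intensity)) |>
    dplyr::summarise(
      mean_above = mean(.data$rating[.data$above]),
      mean_below = mean(.data$rating[!.data$above]),
      n_above = sum(.data$above),
      n_below = sum(!.data$above),
      .groups = "drop"
    )
  bad <- per_subject$n_above == 0 | per_subject$n_below == 0
  if (any(bad)) {
    warn(sprintf(
      "dropping %d subject(s) with an empty side of the split: %s",
      sum(bad), paste(per_subject$subject[bad], collapse = ", ")
    ))
    per_subject <- per_subject[!bad, ]
  }
  if (nrow(per_subject) < 2L) {
    abort("need at least 2 subjects for the paired comparison.")
  }
  ht <- t.test(per_subject$mean_above, per_subject$mean_below,
    paired = TRUE, alternative = alternative
  )
  structure(
    list(
      per_subject = per_subject,
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      estimate = unname(ht$estimate),
      sidedness = alternative,
      condition = condition %||% NA_character_
    ),
    class = "split_test"
  )
}

#' @export
print.split_test <- function(x, ...) {
  cat(sprintf(
    "<split_test> above vs below mean intensity: t(%d) = %.3f, p = %.4g (%s)\n",
    x$df, x$statistic, x$p_value, x$sidedness
  ))
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p Numeric vector of p-values.
#' @param m Number of comparisons in the family; must be at least
#'   `length(p)` (defaults to it).
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p)) {
    abort("`m` must be at least the number of p-values.")
  }
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1].")
  }
  pmin(1, m * p)
}
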
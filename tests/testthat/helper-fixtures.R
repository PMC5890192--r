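# Shared fixtures: all synthetic, built in code at test time.

# A small but non-degenerate cohort spec: both condition subsets keep
# at least 4 sentences per subject (the merge needs n > 3).
tiny_spec <- function(...) {
  defaults <- list(
    n_subjects = 3, n_prior = 4, n_posterior = 10, n_associated = 5,
    roi_shape = c(5, 5, 5), n_rest_frames = 80, discard_frames = 3,
    reactivation_events_per_sentence = 6, n_induced_sessions = 2,
    seed = 7L
  )
  do.call(synthetic_spec, utils::modifyList(defaults, list(...)))
}

# Conditions matching the acquisition emulated by the generator defaults,
# scaled only in subject count where a test loops over many cohorts.
study_spec <- function(...) {
  synthetic_spec(...)
}

full_mask <- function(shape = c(5, 5, 5)) array(TRUE, dim = shape)

# Per-subject Pearson correlations without the tidy plumbing; used where a
# test loops over thousands of simulated cohorts.
fast_subject_cor <- function(cohort_tbl) {
  r <- vapply(
    split(cohort_tbl, cohort_tbl$subject),
    function(d) cor(d$intensity, d$rating),
    numeric(1)
  )
  n <- vapply(split(cohort_tbl, cohort_tbl$subject), nrow, integer(1))
  data.frame(r = r, n = n)
}

# Literal-formula oracle for the weighted Fisher-Z merge, written against the
# printed formulas and kept independent of merge_correlations().
merge_oracle <- function(r, n) {
  z <- 0.5 * log((1 + r) / (1 - r))
  w <- (n - 3) / sum(n - 3)
  zeta <- sum(w * z)
  list(
    zeta = zeta,
    r_merged = (exp(2 * zeta) - 1) / (exp(2 * zeta) + 1),
    se = 1 / sqrt(sum(n - 3))
  )
}
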
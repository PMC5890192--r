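#' Parameterization of a synthetic cohort
#'
#' Bundles every knob of the synthetic-data generator into a validated spec.
#' The defaults emulate the structure of the two-day sentence-comprehension
#' study the pipeline is designed for: 16 subjects; 10 prior and 20 posterior
#' sentences with ~11 posterior sentences associated to a prior sentence per
#' subject; resting sessions of 200 frames at TR 3 s of which the first 3 are
#' reserved as discardable dummy frames; five block-design induced sessions
#' per sentence set with 6-scan sentence blocks separated by 2-scan rests.
#'
#' @param n_subjects Number of subjects.
#' @param n_prior,n_posterior Number of prior / posterior sentences.
#' @param n_associated Posterior sentences per subject that are associated
#'   with a prior sentence.
#' @param roi_shape Integer vector of 3 voxel-grid dimensions for the ROI.
#' @param n_rest_frames Frames acquired per resting session (before any
#'   dummy-frame discarding).
#' @param discard_frames Leading frames reserved for T1 saturation; the
#'   generator never embeds reactivation events there, so discarding them
#'   downstream cannot remove planted signal.
#' @param tr_seconds Repetition time in seconds.
#' @param n_induced_sessions Induced (block-design) sessions per sentence set.
#' @param block_scans,rest_scans,lead_scans Scans per sentence block, per
#'   inter-trial rest, and at session start/end.
#' @param reactivation_events_per_sentence Resting frames per sentence that
#'   carry the sentence's pattern. The per-session embed budget
#'   (`events * n_posterior`) must fit into the non-reserved frames.
#' @param amplitude_mean,amplitude_sd Mean and SD of the per-sentence
#'   reactivation amplitude (signal units; the pattern is unit-norm, so the
#'   amplitude is the total embedded signal energy over the ROI).
#' @param induced_amplitude Amplitude of the stimulus-evoked response in
#'   induced sessions.
#' @param noise_sd Per-voxel i.i.d. Gaussian noise SD in every session.
#' @param day2post_multiplier Amplitude multiplier applied to the post-task
#'   resting session, emulating stabilization of representations after
#'   experience (> 1 strengthens reactivation on day-2-post).
#' @param rating_coupling_rho Latent correlation in (-1, 1) between a
#'   sentence's reactivation amplitude and its understanding rating,
#'   applied only to associated sentences.
#' @param rating_scale Length-2 numeric, the closed rating interval.
#' @param smooth_fwhm Spatial FWHM (in voxels) used when generating
#'   representation patterns; 0 disables smoothing.
#' @param seed Integer master seed; fixing it makes the whole cohort (and its
#'   on-disk serialization) reproducible bit for bit.
#' @return A validated list of class `synthetic_spec`.
#' @examples
#' spec <- synthetic_spec(n_subjects = 2, roi_shape = c(4, 4, 4))
#' spec$n_posterior
#' @export
synthetic_spec <- function(n_subjects = 16,
                           n_prior = 10,
                           n_posterior = 20,
                           n_associated = 11,
                           roi_shape = c(8, 8, 8),
                           n_rest_frames = 200,
                           discard_frames = 3,
                           tr_seconds = 3,
                           n_induced_sessions = 5,
                           block_scans = 6,
                           rest_scans = 2,
                           lead_scans = 3,
                           reactivation_events_per_sentence = 8,
                           amplitude_mean = 12,
                           amplitude_sd = 4,
                           induced_amplitude = 12,
                           noise_sd = 1,
                           day2post_multiplier = 1.5,
                           rating_coupling_rho = 0.4,
                           rating_scale = c(0, 100),
                           smooth_fwhm = 0,
                           seed = 1L) {
  spec <- structure(
    list(
      n_subjects = n_subjects, n_prior = n_prior, n_posterior = n_posterior,
      n_associated = n_associated, roi_shape = as.integer(roi_shape),
      n_rest_frames = n_rest_frames, discard_frames = discard_frames,
      tr_seconds = tr_seconds, n_induced_sessions = n_induced_sessions,
      block_scans = block_scans, rest_scans = rest_scans,
      lead_scans = lead_scans,
      reactivation_events_per_sentence = reactivation_events_per_sentence,
      amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
      induced_amplitude = induced_amplitude, noise_sd = noise_sd,
      day2post_multiplier = day2post_multiplier,
      rating_coupling_rho = rating_coupling_rho,
      rating_scale = as.numeric(rating_scale),
      smooth_fwhm = smooth_fwhm, seed = as.integer(seed)
    ),
    class = "synthetic_spec"
  )
  validate_synthetic_spec(spec)
}

validate_synthetic_spec <- function(spec) {
  counts <- c(
    "n_subjects", "n_prior", "n_posterior", "n_associated", "n_rest_frames",
    "n_induced_sessions", "block_scans",
    "reactivation_events_per_sentence"
  )
  for (f in counts) {
    v <- spec[[f]]
    if (length(v) != 1L || !is.finite(v) || v <= 0 || v != round(v)) {
      abort(sprintf("`%s` must be a single positive integer.", f))
    }
  }
  if (spec$n_associated > spec$n_posterior) {
    abort("`n_associated` cannot exceed `n_posterior`.")
  }
  if (abs(spec$rating_coupling_rho) >= 1) {
    abort("`rating_coupling_rho` must lie strictly inside (-1, 1).")
  }
  if (length(spec$roi_shape) != 3L || any(spec$roi_shape < 1)) {
    abort("`roi_shape` must be three positive grid dimensions.")
  }
  if (spec$noise_sd < 0 || spec$amplitude_sd < 0) {
    abort("`noise_sd` and `amplitude_sd` must be non-negative.")
  }
  if (length(spec$rating_scale) != 2L ||
      spec$rating_scale[1] >= spec$rating_scale[2]) {
    abort("`rating_scale` must be an increasing pair (lo, hi).")
  }
  budget <- spec$n_rest_frames - spec$discard_frames
  need <- spec$reactivation_events_per_sentence * spec$n_posterior
  if (need > budget) {
    abort(sprintf(
      "embed budget exceeded: %d events x %d sentences = %d frames > %d available.",
      spec$reactivation_events_per_sentence, spec$n_posterior, need, budget
    ))
  }
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d subjects, %d prior + %d posterior sentences (%d associated)\n",
    x$n_subjects, x$n_prior, x$n_posterior, x$n_associated
  ))
  cat(sprintf(
    "  ROI %s, rest %d frames (TR %gs), %d events/sentence, rho = %g, seed = %d\n",
    paste(x$roi_shape, collapse = "x"), x$n_rest_frames, x$tr_seconds,
    x$reactivation_events_per_sentence, x$rating_coupling_rho, x$seed
  ))
  invisible(x)
}

#' Generate ground-truth sentence representations
#'
#' Draws one unit-norm voxel pattern per sentence over the in-mask voxels of
#' an ROI: i.i.d. Gaussian fields, optionally spatially smoothed, then
#' normalized. Distinct sentences get (near-)orthogonal patterns, with
#' pairwise correlations centered at zero and shrinking like \eqn{1/\sqrt{V}}.
#'
#' @param n_sentences Number of patterns to generate.
#' @param roi_mask Logical 3D array; must select at least one voxel.
#' @param smooth_fwhm Spatial Gaussian FWHM in voxels (0 = none).
#' @param seed Integer seed (`NULL` uses the ambient RNG).
#' @param ids Optional sentence identifiers (defaults to `1:n_sentences`).
#' @return A list of [representation_map] objects.
#' @export
make_representations <- function(n_sentences, roi_mask, smooth_fwhm = 0,
                                 seed = NULL, ids = NULL) {
  roi_mask <- validate_mask(roi_mask)
  ids <- ids %||% seq_len(n_sentences)
  stopifnot(length(ids) == n_sentences)
  with_seed(seed, {
    lapply(seq_len(n_sentences), function(i) {
      field <- array(rnorm(prod(dim(roi_mask))), dim = dim(roi_mask))
      if (smooth_fwhm > 0) {
        field <- smooth_3d(field, smooth_fwhm)
      }
      v <- field[roi_mask]
      representation_map(ids[i], v / sqrt(sum(v^2)), roi_mask,
        source = "synthetic"
      )
    })
  })
}

# Separable 3D Gaussian smoothing with kernel radius 3 sigma.
smooth_3d <- function(arr, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  radius <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    out <- apply(m, 2, function(col) {
      padded <- c(rep(col[1], radius), col, rep(col[length(col)], radius))
      as.vector(stats::filter(padded, k, sides = 2))[(radius + 1):(radius + length(col))]
    })
    aperm(array(out, dim = d), order(perm))
  }
  for (ax in 1:3) arr <- smooth_axis(arr, ax)
  arr
}

#' Simulate one resting-state session with planted reactivation events
#'
#' Baseline frames are i.i.d. Gaussian noise. For each sentence, exactly
#' `spec$reactivation_events_per_sentence` distinct frames additionally carry
#' `amplitude * pattern`; the embedded frame indices are returned as a ground
#' truth log. Frames reserved as discardable dummies
#' (`spec$discard_frames` leading frames) never receive events, and frames
#' are never shared between sentences.
#'
#' @param reps List of [representation_map] objects sharing one mask.
#' @param spec A [synthetic_spec()].
#' @param amplitudes Numeric vector of per-sentence amplitudes, same length
#'   as `reps`.
#' @param seed Integer seed.
#' @param session Session label stored on the series.
#' @return A list with elements `series` (a [resting_series]) and `embed_log`
#'   (a tibble with columns `sentence_id`, `frame`).
#' @export
make_resting_series <- function(reps, spec, amplitudes, seed = NULL,
                                session = "rest") {
  stopifnot(length(reps) >= 1L)
  mask <- reps[[1]]$mask
  if (!all(vapply(reps, function(r) identical(r$mask, mask), logical(1)))) {
    abort("all representation maps must share one mask.")
  }
  if (length(amplitudes) != length(reps)) {
    abort("`amplitudes` must have one value per representation.")
  }
  n_frames <- spec$n_rest_frames
  events <- spec$reactivation_events_per_sentence
  eligible <- seq.int(spec$discard_frames + 1, n_frames)
  need <- events * length(reps)
  if (need > length(eligible)) {
    abort(sprintf(
      "embed budget exceeded: need %d frames, only %d available.",
      need, length(eligible)
    ))
  }
  v <- sum(mask)
  with_seed(seed, {
    data <- matrix(rnorm(n_frames * v, sd = spec$noise_sd), nrow = n_frames)
    chosen <- sample(eligible, need)
    frame_sets <- split(chosen, rep(seq_along(reps), each = events))
    for (s in seq_along(reps)) {
      add <- amplitudes[s] * reps[[s]]$values
      for (f in frame_sets[[s]]) {
        data[f, ] <- data[f, ] + add
      }
    }
    embed_log <- tibble::tibble(
      sentence_id = rep(
        vapply(reps, function(r) r$sentence_id, numeric(1)),
        each = events
      ),
      frame = unlist(frame_sets, use.names = FALSE)
    )
    list(
      series = resting_series(data, mask, session = session),
      embed_log = embed_log
    )
  })
}

#' Simulate block-design induced sessions
#'
#' Each session presents every sentence in one block, in a freshly randomized
#' order: `lead_scans` rest frames, then per sentence `rest_scans` rest frames
#' followed by `block_scans` stimulus frames, then `lead_scans` closing rest
#' frames. The BOLD signal is the HRF-convolved block boxcar times the
#' sentence amplitude times its unit-norm pattern, plus i.i.d. Gaussian noise.
#'
#' @inheritParams make_resting_series
#' @param amplitudes Per-sentence evoked amplitudes; defaults to
#'   `spec$induced_amplitude` for every sentence.
#' @param hrf HRF model passed to the convolution (`"spm"` or `"identity"`).
#' @return A list with `sessions` (list of frames-by-voxels matrices),
#'   `events` (tibble: `session`, `onset`, `duration`, `sentence_id`) and
#'   `n_frames` (frames per session).
#' @export
make_induced_sessions <- function(reps, spec, seed = NULL, amplitudes = NULL,
                                  hrf = "spm") {
  mask <- reps[[1]]$mask
  n_sent <- length(reps)
  amplitudes <- amplitudes %||% rep(spec$induced_amplitude, n_sent)
  stopifnot(length(amplitudes) == n_sent)
  tr <- spec$tr_seconds
  trial_scans <- spec$rest_scans + spec$block_scans
  n_frames <- 2 * spec$lead_scans + n_sent * trial_scans
  v <- sum(mask)
  ids <- vapply(reps, function(r) r$sentence_id, numeric(1))
  with_seed(seed, {
    sessions <- vector("list", spec$n_induced_sessions)
    events <- vector("list", spec$n_induced_sessions)
    for (s in seq_len(spec$n_induced_sessions)) {
      order_idx <- sample(n_sent)
      onsets <- (spec$lead_scans + (seq_len(n_sent) - 1) * trial_scans +
        spec$rest_scans) * tr
      duration <- spec$block_scans * tr
      data <- matrix(rnorm(n_frames * v, sd = spec$noise_sd), nrow = n_frames)
      for (k in seq_len(n_sent)) {
        j <- order_idx[k]
        reg <- convolve_boxcar(
          event_boxcar(onsets[k], duration, n_frames, tr), tr, hrf
        )
        data <- data + amplitudes[j] * outer(reg, reps[[j]]$values)
      }
      sessions[[s]] <- data
      events[[s]] <- tibble::tibble(
        session = s,
        onset = onsets,
        duration = duration,
        sentence_id = ids[order_idx]
      )
    }
    list(
      sessions = sessions,
      events = dplyr::bind_rows(events),
      n_frames = n_frames,
      mask = mask
    )
  })
}

#' Simulate a subject's sentence-to-prior association table
#'
#' Each posterior sentence appears exactly once; a random subset of
#' `n_associated` posterior sentences is linked to a prior sentence (priors
#' may be reused, as subjects were allowed to give overlapping answers), the
#' rest are `NA`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed.
#' @return Tibble with columns `posterior_id`, `prior_id` (NA = unassociated),
#'   `associated`.
#' @export
make_associations <- function(spec, seed = NULL) {
  with_seed(seed, {
    assoc_ids <- sort(sample(spec$n_posterior, spec$n_associated))
    prior_ids <- sample(spec$n_prior, spec$n_associated, replace = TRUE)
    tibble::tibble(
      posterior_id = seq_len(spec$n_posterior),
      prior_id = replace(
        rep(NA_integer_, spec$n_posterior), assoc_ids, prior_ids
      )
    ) |>
      dplyr::mutate(associated = !is.na(.data$prior_id))
  })
}

#' Simulate understanding ratings coupled to reactivation amplitude
#'
#' For associated sentences the rating is a monotone rescaling to the rating
#' interval of `rho * standardized(amplitude) + sqrt(1 - rho^2) * noise`;
#' for unassociated sentences the rating is independent of amplitude. Ratings
#' are clamped to the scale (a slider instrument cannot leave its range).
#'
#' @param amplitudes Numeric vector of per-sentence reactivation amplitudes.
#' @param association Tibble as returned by [make_associations()] (columns
#'   `posterior_id`, `associated`).
#' @param rho Latent amplitude-rating correlation, |rho| < 1.
#' @param scale Length-2 rating interval.
#' @param seed Integer seed.
#' @return Tibble with columns `sentence_id`, `rating`, `associated`.
#' @export
make_ratings <- function(amplitudes, association, rho = 0.4,
                         scale = c(0, 100), seed = NULL) {
  if (abs(rho) >= 1) {
    abort("`rho` must lie strictly inside (-1, 1).")
  }
  n <- length(amplitudes)
  stopifnot(nrow(association) == n)
  assoc <- association$associated
  with_seed(seed, {
    latent <- rnorm(n)
    if (any(assoc)) {
      a <- amplitudes[assoc]
      za <- if (sd(a) > 0) (a - mean(a)) / sd(a) else rep(0, length(a))
      latent[assoc] <- rho * za + sqrt(1 - rho^2) * latent[assoc]
    }
    mid <- mean(scale)
    spread <- diff(scale) * 0.15
    tibble::tibble(
      sentence_id = association$posterior_id,
      rating = clamp(mid + spread * latent, scale[1], scale[2]),
      associated = assoc
    )
  })
}

#' Simulate a full multi-subject cohort in memory
#'
#' Composes the generator: per subject, ground-truth posterior-sentence
#' patterns, per-sentence reactivation amplitudes, an association table,
#' ratings coupled to amplitude only for associated sentences, three resting
#' sessions (`day1`, `day2pre`, `day2post`, the last with the stabilization
#' multiplier applied), and block-design induced sessions from which t-maps
#' can be re-estimated. All ground truth (amplitudes, embed logs) is kept, so
#' downstream recovery can be tested.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `preplay_cohort`: `spec` plus `subjects`, a list
#'   with one entry per subject.
#' @examples
#' co <- simulate_cohort(synthetic_spec(
#'   n_subjects = 1, n_posterior = 4, n_associated = 3,
#'   roi_shape = c(4, 4, 4), n_rest_frames = 60,
#'   reactivation_events_per_sentence = 5, n_induced_sessions = 2
#' ))
#' names(co$subjects[[1]])
#' @export
simulate_cohort <- function(spec) {
  spec <- validate_synthetic_spec(spec)
  mask <- array(TRUE, dim = spec$roi_shape)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    s0 <- child_seed(spec$seed, i * 1000)
    reps <- make_representations(
      spec$n_posterior, mask, spec$smooth_fwhm,
      seed = child_seed(s0, 1)
    )
    amplitudes <- with_seed(
      child_seed(s0, 2),
      pmax(rnorm(spec$n_posterior, spec$amplitude_mean, spec$amplitude_sd), 0)
    )
    association <- make_associations(spec, seed = child_seed(s0, 3))
    ratings <- make_ratings(
      amplitudes, association, spec$rating_coupling_rho,
      spec$rating_scale,
      seed = child_seed(s0, 4)
    )
    rest <- list(
      day1 = make_resting_series(reps, spec, amplitudes,
        seed = child_seed(s0, 5), session = "day1"
      ),
      day2pre = make_resting_series(reps, spec, amplitudes,
        seed = child_seed(s0, 6), session = "day2pre"
      ),
      day2post = make_resting_series(
        reps, spec, amplitudes * spec$day2post_multiplier,
        seed = child_seed(s0, 7), session = "day2post"
      )
    )
    induced <- make_induced_sessions(reps, spec, seed = child_seed(s0, 8))
    list(
      id = i, mask = mask, representations = reps, amplitudes = amplitudes,
      association = association, ratings = ratings, rest = rest,
      induced = induced
    )
  })
  structure(list(spec = spec, subjects = subjects), class = "preplay_cohort")
}

#' @export
print.preplay_cohort <- function(x, ...) {
  cat(sprintf(
    "<preplay_cohort> %d subjects (seed %d)\n",
    length(x$subjects), x$spec$seed
  ))
  invisible(x)
}

#' Simulate per-subject intensity/rating tables directly
#'
#' A lightweight cohort at the statistic level: per subject, standard-normal
#' "intensity" values for `n_sentences` sentences and ratings generated by
#' [make_ratings()] with coupling `rho`. Used for calibration and power
#' studies of the group-level machinery, where simulating voxel data adds
#' nothing.
#'
#' @param n_subjects,n_sentences Cohort dimensions.
#' @param rho Planted intensity-rating coupling.
#' @param seed Integer seed.
#' @param scale Rating interval.
#' @return Tibble with columns `subject`, `sentence_id`, `intensity`,
#'   `rating`.
#' @export
simulate_rating_cohort <- function(n_subjects = 16, n_sentences = 11,
                                   rho = 0, seed = NULL, scale = c(0, 100)) {
  with_seed(seed, {
    purrr::map_dfr(seq_len(n_subjects), function(i) {
      intensity <- rnorm(n_sentences)
      assoc <- tibble::tibble(
        posterior_id = seq_len(n_sentences),
        associated = TRUE
      )
      ratings <- make_ratings(intensity, assoc, rho, scale, seed = NULL)
      tibble::tibble(
        subject = i,
        sentence_id = seq_len(n_sentences),
        intensity = intensity,
        rating = ratings$rating
      )
    })
  })
}
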
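test_that("synthetic_spec enforces its invariants", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(n_associated = 25), "n_associated")
  expect_error(synthetic_spec(rating_coupling_rho = 1), "rho")
  expect_error(synthetic_spec(n_subjects = 0), "positive")
  # embed budget: events x sentences must fit the non-reserved frames
  expect_error(
    synthetic_spec(reactivation_events_per_sentence = 15),
    "embed budget"
  )
})

test_that("make_representations yields unit-norm, reproducible patterns", {
  mask <- full_mask(c(5, 5, 4))
  reps <- make_representations(2, mask, seed = 1)
  expect_length(reps, 2)
  expect_length(reps[[1]]$values, 100)
  norms <- vapply(reps, function(r) sum(r$values^2), numeric(1))
  expect_equal(norms, c(1, 1), tolerance = 1e-12)
  reps2 <- make_representations(2, mask, seed = 1)
  expect_identical(reps[[1]]$values, reps2[[1]]$values)
  expect_error(make_representations(2, array(FALSE, c(3, 3, 3))), "empty")
})

test_that("distinct patterns are near-orthogonal (1/sqrt(V) scaling)", {
  mask <- full_mask(c(10, 10, 3)) # 300 voxels
  mean_abs <- vapply(1:10, function(s) {
    reps <- make_representations(20, mask, seed = s)
    m <- vapply(reps, `[[`, numeric(300), "values")
    cc <- cor(m)
    mean(abs(cc[upper.tri(cc)]))
  }, numeric(1))
  expect_lt(mean(mean_abs), 0.15)
})

test_that("resting series embeds the prescribed frames and logs them", {
  spec <- synthetic_spec(
    n_posterior = 10, n_associated = 5, n_rest_frames = 197,
    discard_frames = 0, reactivation_events_per_sentence = 15
  )
  mask <- full_mask()
  reps <- make_representations(10, mask, seed = 2)
  out <- make_resting_series(reps, spec, amplitudes = rep(50, 10), seed = 3)
  expect_equal(nrow(out$embed_log), 150) # 150 embedded, 47 baseline
  expect_equal(nrow(out$series$data), 197)
  expect_equal(anyDuplicated(out$embed_log$frame), 0)
  # amplitude >> noise: embedded frames correlate > 0.9 with their pattern
  for (s in c(1, 10)) {
    frames <- out$embed_log$frame[out$embed_log$sentence_id == s]
    rs <- apply(out$series$data[frames, ], 1, cor, y = reps[[s]]$values)
    expect_true(all(rs > 0.9))
  }
})

test_that("zero amplitudes give pure noise but a full embed log", {
  spec <- tiny_spec()
  mask <- full_mask()
  reps <- make_representations(spec$n_posterior, mask, seed = 4)
  out <- make_resting_series(reps, spec, amplitudes = rep(0, 10), seed = 5)
  noise_only <- make_resting_series(reps, spec, amplitudes = rep(0, 10), seed = 5)
  expect_identical(out$series$data, noise_only$series$data)
  expect_equal(
    nrow(out$embed_log),
    spec$n_posterior * spec$reactivation_events_per_sentence
  )
  # marginally standard-normal noise
  expect_lt(abs(mean(out$series$data)), 0.01)
  expect_equal(sd(out$series$data), spec$noise_sd, tolerance = 0.02)
})

test_that("resting series rejects an over-budget embed request", {
  spec <- tiny_spec()
  mask <- full_mask()
  reps <- make_representations(30, mask, seed = 1)
  expect_error(
    make_resting_series(reps, spec, amplitudes = rep(1, 30), seed = 1),
    "embed budget"
  )
})

test_that("reserved dummy frames never receive reactivation events", {
  spec <- tiny_spec()
  mask <- full_mask()
  reps <- make_representations(spec$n_posterior, mask, seed = 8)
  for (s in 1:5) {
    out <- make_resting_series(reps, spec, rep(10, spec$n_posterior), seed = s)
    expect_true(all(out$embed_log$frame > spec$discard_frames))
  }
})

test_that("induced sessions have block design and noiseless construction", {
  spec <- tiny_spec(noise_sd = 0)
  mask <- full_mask()
  reps <- make_representations(spec$n_posterior, mask, seed = 6)
  ind <- make_induced_sessions(reps, spec, seed = 7)
  # one event row per sentence per session
  expect_equal(nrow(ind$events), spec$n_posterior * spec$n_induced_sessions)
  expect_equal(
    ind$n_frames,
    2 * spec$lead_scans +
      spec$n_posterior * (spec$rest_scans + spec$block_scans)
  )
  # zero noise: each frame is exactly the regressor-weighted pattern sum
  ev1 <- ind$events[ind$events$session == 1, ]
  expected <- matrix(0, ind$n_frames, sum(mask))
  for (j in seq_len(nrow(ev1))) {
    box <- as.numeric(
      (seq_len(ind$n_frames) - 1) * spec$tr_seconds >= ev1$onset[j] &
        (seq_len(ind$n_frames) - 1) * spec$tr_seconds < ev1$onset[j] + ev1$duration[j]
    )
    reg <- convolve(box, rev(canonical_hrf(spec$tr_seconds)), type = "open")[
      seq_len(ind$n_frames)
    ]
    expected <- expected + spec$induced_amplitude *
      outer(reg, reps[[match(ev1$sentence_id[j], 1:10)]]$values)
  }
  expect_equal(ind$sessions[[1]], expected, tolerance = 1e-10)
})

test_that("associations cover every posterior sentence exactly once", {
  spec <- study_spec()
  for (s in 1:5) {
    a <- make_associations(spec, seed = s)
    expect_identical(a$posterior_id, 1:20)
    expect_equal(sum(a$associated), spec$n_associated)
    expect_true(all(a$prior_id[a$associated] %in% 1:10))
  }
})

test_that("ratings couple to amplitude only for associated sentences", {
  # strong coupling, many sentences: sample correlation approaches rho
  n <- 1000
  assoc <- tibble::tibble(posterior_id = 1:n, associated = TRUE)
  amps <- rnorm(n, 10, 3)
  rt <- make_ratings(amps, assoc, rho = 0.99, seed = 9)
  expect_gt(cor(amps, rt$rating), 0.9)
  expect_true(all(rt$rating >= 0 & rt$rating <= 100))
  # rho = 0: correlation within the null band
  rt0 <- make_ratings(amps, assoc, rho = 0, seed = 10)
  expect_lt(abs(cor(amps, rt0$rating)), 3 / sqrt(n))
  # unassociated sentences: rating independent of amplitude by construction
  assoc2 <- tibble::tibble(posterior_id = 1:n, associated = FALSE)
  rt2 <- make_ratings(amps, assoc2, rho = 0.99, seed = 11)
  expect_lt(abs(cor(amps, rt2$rating)), 4 / sqrt(n))
})

test_that("cohort simulation is deterministic given the spec seed", {
  spec <- tiny_spec()
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1$subjects[[2]]$rest$day2pre$series$data,
                   c2$subjects[[2]]$rest$day2pre$series$data)
  expect_identical(c1$subjects[[1]]$ratings, c2$subjects[[1]]$ratings)
  c3 <- simulate_cohort(tiny_spec(seed = 8L))
  expect_false(identical(c1$subjects[[1]]$ratings, c3$subjects[[1]]$ratings))
})

test_that("datasets round-trip through disk with identical checksums", {
  spec <- tiny_spec(n_subjects = 2)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  make_dataset(spec, dir1)
  make_dataset(spec, dir2)
  expect_length(list.dirs(dir1, recursive = FALSE), spec$n_subjects)
  f1 <- list.files(dir1, recursive = TRUE, full.names = TRUE)
  f2 <- list.files(dir2, recursive = TRUE, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # manifest round-trips to an equal spec
  co <- read_dataset(dir1)
  expect_equal(unclass(co$spec), unclass(spec))
  # voxel data survives (NIfTI stores double precision here)
  orig <- simulate_cohort(spec)
  expect_equal(
    co$subjects[[1]]$rest$day1$series$data,
    orig$subjects[[1]]$rest$day1$series$data,
    tolerance = 1e-6
  )
  expect_error(make_dataset(spec, "/proc/definitely/not/writable"), "cannot write")
})
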
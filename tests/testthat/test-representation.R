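test_that("design matrix has one task column per sentence plus session intercepts", {
  ev <- tibble::tibble(
    onset = seq(0, 90, by = 10)[1:10] + 6, duration = 6,
    sentence_id = 1:10, session = 1
  )
  d <- build_design_matrix(ev, n_frames = 93, tr = 3)
  expect_equal(ncol(d$X), 11)
  expect_equal(length(d$task_cols), 10)
  expect_equal(d$labels[11], "session_1")
  expect_equal(nrow(d$X), 93)
})

test_that("events outside the session are rejected", {
  ev <- tibble::tibble(onset = 100, duration = 6, sentence_id = 1, session = 1)
  expect_error(build_design_matrix(ev, n_frames = 30, tr = 3), "outside")
})

test_that("identity HRF reproduces the raw boxcar", {
  ev <- tibble::tibble(onset = 9, duration = 9, sentence_id = 1, session = 1)
  d <- build_design_matrix(ev, n_frames = 12, tr = 3, hrf = "identity")
  expect_equal(d$X[, 1], c(0, 0, 0, 1, 1, 1, 0, 0, 0, 0, 0, 0))
})

test_that("rank-deficient designs fail naming the collinear columns", {
  # two sentences presented at identical times -> identical regressors
  ev <- tibble::tibble(
    onset = c(6, 6), duration = 6, sentence_id = 1:2, session = 1
  )
  expect_error(
    build_design_matrix(ev, n_frames = 20, tr = 3),
    "rank deficient.*sentence"
  )
})

test_that("noiseless block data recovers beta = amplitude x pattern exactly", {
  spec <- tiny_spec(noise_sd = 0, n_induced_sessions = 2)
  mask <- full_mask()
  reps <- make_representations(spec$n_posterior, mask, seed = 12)
  ind <- make_induced_sessions(reps, spec, seed = 13)
  d <- build_design_matrix(ind$events, n_frames = ind$n_frames, tr = spec$tr_seconds)
  x <- d$X
  series <- do.call(rbind, ind$sessions)
  fit <- lm.fit(x, series)
  for (j in 1:3) {
    expect_equal(
      unname(fit$coefficients[j, ]),
      spec$induced_amplitude * reps[[j]]$values,
      tolerance = 1e-8
    )
  }
})

test_that("GLM t-maps agree with a normal-equations oracle", {
  set.seed(14)
  for (rep_i in 1:5) {
    n <- 18
    x <- cbind(rnorm(n), rnorm(n), 1)
    colnames(x) <- c("sentence_a", "sentence_b", "session_1")
    y <- matrix(rnorm(n * 5), n, 5)
    design <- structure(
      list(
        X = x, labels = colnames(x), task_cols = 1:2,
        sentence_ids = c("a", "b"), session_index = rep(1, n), tr = 1,
        hrf = "spm"
      ),
      class = "design_matrix"
    )
    mask <- array(TRUE, c(5, 1, 1))
    tmaps <- fit_glm_tmaps(y, design, mask)
    # brute-force normal equations
    xtx_inv <- solve(t(x) %*% x)
    beta <- xtx_inv %*% t(x) %*% y
    res <- y - x %*% beta
    s2 <- colSums(res^2) / (n - 3)
    for (j in 1:2) {
      t_oracle <- beta[j, ] / sqrt(s2 * xtx_inv[j, j])
      expect_equal(tmaps[[j]]$values, unname(t_oracle), tolerance = 1e-10)
    }
  }
})

test_that("t-maps are invariant to positive rescaling of the series", {
  spec <- tiny_spec()
  mask <- full_mask()
  reps <- make_representations(spec$n_posterior, mask, seed = 15)
  ind <- make_induced_sessions(reps, spec, seed = 16)
  d <- build_design_matrix(ind$events, n_frames = ind$n_frames, tr = spec$tr_seconds)
  t1 <- fit_glm_tmaps(ind$sessions, d, mask)
  t2 <- fit_glm_tmaps(lapply(ind$sessions, `*`, 37.5), d, mask)
  expect_equal(t1[[1]]$values, t2[[1]]$values, tolerance = 1e-9)
})

test_that("null-sentence t-values are centrally distributed", {
  # one sentence never carries signal: its t-map should be central t
  spec <- synthetic_spec(
    n_subjects = 1, n_prior = 4, n_posterior = 4, n_associated = 4,
    roi_shape = c(22, 22, 21), n_rest_frames = 50, discard_frames = 0,
    reactivation_events_per_sentence = 5, n_induced_sessions = 2,
    noise_sd = 1
  )
  mask <- full_mask(spec$roi_shape) # 10164 voxels
  reps <- make_representations(spec$n_posterior, mask, seed = 17)
  amps <- c(spec$induced_amplitude, spec$induced_amplitude, spec$induced_amplitude, 0)
  ind <- make_induced_sessions(reps, spec, seed = 18, amplitudes = amps)
  d <- build_design_matrix(ind$events, n_frames = ind$n_frames, tr = spec$tr_seconds)
  tmaps <- fit_glm_tmaps(ind$sessions, d, mask)
  tnull <- tmaps[[4]]$values
  expect_lt(abs(mean(tnull)), 0.05)
  expect_equal(sd(tnull), 1, tolerance = 0.05)
})

test_that("t-maps recover the true pattern at default SNR", {
  spec <- tiny_spec()
  mask <- full_mask()
  reps <- make_representations(spec$n_posterior, mask, seed = 19)
  ind <- make_induced_sessions(reps, spec, seed = 20)
  d <- build_design_matrix(ind$events, n_frames = ind$n_frames, tr = spec$tr_seconds)
  tmaps <- fit_glm_tmaps(ind$sessions, d, mask)
  cors <- vapply(seq_along(reps), function(j) {
    cor(tmaps[[j]]$values, reps[[j]]$values)
  }, numeric(1))
  expect_true(all(cors > 0.7))
})

test_that("the informative-voxel filter drops exactly the lowest-variance fraction", {
  mask <- array(TRUE, c(10, 10, 1))
  set.seed(21)
  tmaps <- lapply(1:8, function(s) {
    representation_map(s, rnorm(100), mask)
  })
  keep <- select_informative_voxels(tmaps, drop_fraction = 0.03)
  expect_equal(sum(!keep), 3)
  tmat <- do.call(rbind, lapply(tmaps, `[[`, "values"))
  v <- apply(tmat, 2, function(col) mean((col - mean(col))^2))
  expect_setequal(which(!keep), order(v)[1:3])
  # fraction 0 keeps everything
  expect_true(all(select_informative_voxels(tmaps, 0)))
})

test_that("a planted zero-variance voxel is always removed", {
  mask <- array(TRUE, c(10, 10, 1))
  for (s in 1:5) {
    set.seed(100 + s)
    tmaps <- lapply(1:6, function(j) {
      v <- rnorm(100)
      v[42] <- 1.234 # constant across sentences
      representation_map(j, v, mask)
    })
    keep <- select_informative_voxels(tmaps, 0.03)
    expect_false(keep[42])
  }
})

test_that("the filter ignores sentence order and all-tied variances drop nothing", {
  mask <- array(TRUE, c(4, 5, 5))
  set.seed(22)
  tmaps <- lapply(1:6, function(j) representation_map(j, rnorm(100), mask))
  k1 <- select_informative_voxels(tmaps, 0.03)
  k2 <- select_informative_voxels(rev(tmaps), 0.03)
  expect_identical(as.logical(k1), as.logical(k2))
  # identical variance profile: ties at the cutoff are kept, not dropped
  flat <- lapply(1:4, function(j) {
    representation_map(j, rep(c(-1, 1, -1, 1)[j], 100), mask)
  })
  expect_true(all(select_informative_voxels(flat, 0.03)))
})

test_that("apply_voxel_filter subsets values and shrinks the mask coherently", {
  mask <- array(TRUE, c(5, 5, 4))
  set.seed(23)
  tmaps <- lapply(1:5, function(j) representation_map(j, rnorm(100), mask))
  keep <- select_informative_voxels(tmaps, 0.1)
  filt <- apply_voxel_filter(tmaps, keep)
  expect_equal(sum(filt[[1]]$mask), sum(keep))
  expect_identical(filt[[2]]$values, tmaps[[2]]$values[keep])
})
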
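test_that("per-subject correlations recover perfect coupling and sample sizes", {
  tab <- tidyr::expand_grid(subject = 1:16, sentence_id = 1:11) |>
    dplyr::mutate(
      condition = "w_prior",
      intensity = rnorm(dplyr::n())
    )
  ratings <- dplyr::transmute(
    tab, subject = subject, sentence_id = sentence_id, rating = intensity
  )
  subs <- per_subject_correlation(tab, ratings, "w_prior")
  expect_equal(nrow(subs), 16)
  expect_true(all(subs$n == 11))
  expect_equal(subs$r, rep(1, 16), tolerance = 1e-12)
})

test_that("subjects with degenerate or scarce data are dropped with a warning", {
  tab <- tibble::tibble(
    subject = rep(1:2, c(6, 3)),
    sentence_id = c(1:6, 1:3),
    condition = "w_prior",
    intensity = rnorm(9)
  )
  ratings <- tibble::tibble(
    subject = tab$subject, sentence_id = tab$sentence_id,
    rating = c(rnorm(6), 1, 1, 1)
  )
  expect_warning(
    subs <- per_subject_correlation(tab, ratings, "w_prior"),
    "dropping"
  )
  expect_equal(subs$subject, 1)
  # zero-variance ratings: dropped too
  ratings2 <- dplyr::mutate(ratings, rating = dplyr::if_else(subject == 1, 5, rating))
  expect_warning(
    subs2 <- per_subject_correlation(tab, ratings2, "w_prior"),
    "dropping"
  )
  expect_equal(nrow(subs2), 0)
})

test_that("permuted ratings give per-subject correlations centered at zero", {
  set.seed(41)
  rs <- replicate(300, {
    x <- rnorm(11)
    y <- sample(rnorm(11))
    cor(x, y)
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("the weighted merge reproduces the hand-derived example", {
  m <- merge_correlations(data.frame(r = c(0.5, 0.0), n = c(13, 23)))
  expect_equal(m$zeta, 0.18310, tolerance = 1e-4)
  expect_equal(m$r_merged, 0.18108, tolerance = 1e-4)
  expect_equal(m$se, 1 / sqrt(30), tolerance = 1e-12)
  expect_equal(m$subjects$weight, c(1, 2) / 3, tolerance = 1e-12)
})

test_that("merge edge cases: single subject and equal correlations", {
  m1 <- merge_correlations(data.frame(r = 0.3, n = 20))
  expect_equal(m1$r_merged, 0.3, tolerance = 1e-12)
  expect_equal(m1$se, 1 / sqrt(17), tolerance = 1e-12)
  m2 <- merge_correlations(data.frame(r = c(0.2, 0.2), n = c(15, 15)))
  expect_equal(m2$r_merged, 0.2, tolerance = 1e-12)
})

test_that("merge matches the literal-formula oracle on 1000 random cohorts", {
  set.seed(42)
  for (i in 1:1000) {
    k <- sample(2:20, 1)
    r <- runif(k, -0.95, 0.95)
    n <- sample(5:40, k, replace = TRUE)
    m <- merge_correlations(data.frame(r = r, n = n))
    o <- merge_oracle(r, n)
    expect_equal(m$zeta, o$zeta, tolerance = 1e-10)
    expect_equal(m$r_merged, o$r_merged, tolerance = 1e-10)
    expect_equal(m$se, o$se, tolerance = 1e-10)
    expect_equal(sum(m$subjects$weight), 1, tolerance = 1e-12)
  }
})

test_that("merge agrees with an independent fixed-effect meta-analysis fit", {
  skip_if_not_installed("metafor")
  set.seed(43)
  r <- runif(8, -0.6, 0.8)
  n <- sample(8:30, 8, replace = TRUE)
  m <- merge_correlations(data.frame(r = r, n = n))
  fit <- metafor::rma(
    yi = atanh(r), vi = 1 / (n - 3), method = "FE"
  )
  expect_equal(m$zeta, as.numeric(fit$beta), tolerance = 1e-8)
  expect_equal(m$se, as.numeric(fit$se), tolerance = 1e-8)
})

test_that("merge rejects invalid sample sizes", {
  expect_error(merge_correlations(data.frame(r = 0.2, n = 3)), "exceed 3")
  expect_error(merge_correlations(data.frame(r = 1.4, n = 10)), "\\[-1, 1\\]")
})

test_that("the zero test converts z-scores to the right tail probabilities", {
  m <- merge_correlations(data.frame(r = 0, n = 20))
  expect_equal(test_merged_zero(m, "greater")$p_value, 0.5)
  # z = 1.6449 -> one-sided p = 0.05
  m2 <- merge_correlations(data.frame(r = tanh(qnorm(0.95) / sqrt(17)), n = 20))
  expect_equal(test_merged_zero(m2, "greater")$p_value, 0.05, tolerance = 1e-6)
  expect_equal(
    test_merged_zero(m2, "two.sided")$p_value, 0.10,
    tolerance = 1e-6
  )
})

test_that("null cohorts give uniform p-values", {
  set.seed(44)
  ps <- vapply(1:400, function(i) {
    co <- simulate_rating_cohort(8, 12, rho = 0)
    subs <- fast_subject_cor(co)
    test_merged_zero(merge_correlations(subs), "greater")$p_value
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("compare_merged is antisymmetric and null at equality", {
  m1 <- merge_correlations(data.frame(r = c(0.4, 0.2), n = c(12, 15)))
  m2 <- merge_correlations(data.frame(r = c(0.1, -0.2), n = c(14, 11)))
  eq <- compare_merged(m1, m1)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)
  ab <- compare_merged(m1, m2, "greater")
  ba <- compare_merged(m2, m1, "greater")
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p_value, 1 - ba$p_value, tolerance = 1e-12)
})

test_that("compare_merged has power against a planted condition difference", {
  set.seed(45)
  hits <- vapply(1:500, function(i) {
    co1 <- simulate_rating_cohort(16, 11, rho = 0.5)
    co0 <- simulate_rating_cohort(16, 11, rho = 0)
    m1 <- merge_correlations(fast_subject_cor(co1))
    m0 <- merge_correlations(fast_subject_cor(co0))
    compare_merged(m1, m0, "greater")$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.5)
})

test_that("the above/below split detects monotone coupling and honors policy", {
  tab <- tidyr::expand_grid(subject = 1:8, sentence_id = 1:10) |>
    dplyr::mutate(condition = "w_prior", intensity = rep(1:10, 8))
  ratings <- dplyr::transmute(
    tab, subject = subject, sentence_id = sentence_id,
    rating = 10 * intensity + rnorm(80, sd = 0.1)
  )
  st <- above_below_split(tab, ratings, "w_prior")
  expect_true(all(st$per_subject$mean_above > st$per_subject$mean_below))
  expect_lt(st$p_value, 0.001)
  expect_equal(st$df, 7)
  # constant-intensity subject is dropped
  tab2 <- dplyr::mutate(
    tab, intensity = dplyr::if_else(subject == 1, 5, intensity)
  )
  expect_warning(st2 <- above_below_split(tab2, ratings, "w_prior"), "empty side")
  expect_equal(nrow(st2$per_subject), 7)
})

test_that("the split statistic is near zero when ratings are independent", {
  set.seed(46)
  ts <- vapply(1:200, function(i) {
    tab <- tidyr::expand_grid(subject = 1:8, sentence_id = 1:10) |>
      dplyr::mutate(condition = "w_prior", intensity = rnorm(80))
    ratings <- tibble::tibble(
      subject = tab$subject, sentence_id = tab$sentence_id, rating = rnorm(80)
    )
    above_below_split(tab, ratings, "w_prior")$statistic
  }, numeric(1))
  expect_lt(abs(mean(ts)), 0.15)
})

test_that("Bonferroni multiplies and caps", {
  expect_equal(bonferroni(0.02, 2), 0.04)
  expect_equal(bonferroni(0.7, 2), 1)
  expect_equal(bonferroni(c(0.01, 0.4)), c(0.02, 0.8))
  expect_equal(bonferroni(0.03, 1), 0.03)
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
  # agrees with the standard adjustment
  p <- c(0.001, 0.02, 0.3)
  expect_equal(bonferroni(p), p.adjust(p, "bonferroni"))
})
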
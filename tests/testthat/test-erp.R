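test_that("class means and grand averages follow their definitions", {
  # all animate trials equal waveform A, all inanimate equal waveform B
  A <- matrix(1:6, 2, 3)
  B <- matrix(0, 2, 3)
  d <- manual_dataset(
    array(rep(A, each = 4), c(4, 2, 3)),
    array(rep(B, each = 4), c(4, 2, 3)))
  e <- compute_erps(d)
  for (s in 1:4)
    expect_equal(matrix(e$subject_means[s, 1, , ], 2, 3), A)
  expect_equal(e$grand_animate, A, ignore_attr = TRUE)
  expect_equal(e$grand_inanimate, B, ignore_attr = TRUE)
  # grand average is the unweighted mean of subject means
  d2 <- tiny_dataset(n_subjects = 4)
  e2 <- compute_erps(d2)
  expect_equal(e2$grand_animate,
               apply(e2$subject_means[, 1, , ], c(2, 3), mean),
               ignore_attr = TRUE)
  # linearity in the data
  d3 <- d2; d3$data <- 2 * d2$data
  e3 <- compute_erps(d3)
  expect_equal(e3$grand_animate, 2 * e2$grand_animate, tolerance = 1e-12)
})

test_that("a missing class for a subject is an error", {
  d <- tiny_dataset(n_subjects = 3)
  d$animacy_labels[2, ] <- -1
  expect_error(compute_erps(d), "S02 has no animate")
})

test_that("difference maps are antisymmetric in the class labels", {
  d <- tiny_dataset(n_subjects = 4)
  e <- compute_erps(d)
  dm <- erp_difference_map(e)
  expect_identical(dm$kind, "erp_difference")
  # identical class means give a zero map
  e0 <- e
  e0$subject_means[, 2, , ] <- e0$subject_means[, 1, , ]
  e0$grand_inanimate <- e0$grand_animate
  expect_true(all(erp_difference_map(e0)$values == 0))
  # swapping class labels negates the map
  d_swap <- d
  d_swap$animacy_labels <- -d$animacy_labels
  dm_swap <- erp_difference_map(compute_erps(d_swap))
  expect_equal(dm_swap$values, -dm$values, tolerance = 1e-12)
})

test_that("paired t maps reproduce the hand-computed statistic", {
  # one cell with subject differences (2, 0, 1, -1, 3):
  # t = mean / (sd / sqrt(5)) = 1 / (sqrt(2.5) / sqrt(5)) = sqrt(2)
  diffs <- c(2, 0, 1, -1, 3)
  ani <- array(0, c(5, 2, 3))
  ani[, 1, 2] <- diffs
  ina <- array(0, c(5, 2, 3))
  # break the zero variance elsewhere with tiny subject-specific noise
  set.seed(1)
  jitter <- array(rnorm(5 * 2 * 3, 0, 1e-6), c(5, 2, 3))
  d <- manual_dataset(ani + jitter, ina + jitter)
  tm <- paired_ttest_map(compute_erps(d))
  expect_equal(tm$t_map$values[1, 2], sqrt(2), tolerance = 1e-3)
  expect_equal(tm$threshold, 0.05 / 6)
  expect_equal(tm$df, 4)
})

test_that("identical class means give t = 0 and no significant cells", {
  d <- tiny_dataset(n_subjects = 4)
  e <- compute_erps(d)
  e$subject_means[, 2, , ] <- e$subject_means[, 1, , ]
  tm <- paired_ttest_map(e)
  expect_true(all(tm$t_map$values == 0))
  expect_false(any(tm$significant))
})

test_that("zero-variance cells with nonzero mean are flagged significant", {
  ani <- array(0, c(5, 2, 3)); ani[, 1, 1] <- 1  # constant difference 1
  ina <- array(0, c(5, 2, 3))
  d <- manual_dataset(ani, ina)
  tm <- paired_ttest_map(compute_erps(d))
  expect_identical(tm$t_map$values[1, 1], Inf)
  expect_true(tm$significant[1, 1])
  # identically zero cells stay non-significant
  expect_identical(tm$t_map$values[2, 2], 0)
  expect_false(tm$significant[2, 2])
})

test_that("t maps ignore subject-specific waveforms common to both classes", {
  d <- tiny_dataset(n_subjects = 5)
  tm1 <- paired_ttest_map(compute_erps(d))
  d2 <- d
  for (s in 1:5) {
    common <- matrix(rnorm(32 * 60, 0, 2), 32, 60)
    for (tr in seq_len(dim(d$data)[2]))
      d2$data[s, tr, , ] <- d2$data[s, tr, , ] + common
  }
  tm2 <- paired_ttest_map(compute_erps(d2))
  expect_equal(tm2$t_map$values, tm1$t_map$values, tolerance = 1e-8)
})

test_that("time-only scope averages the posterior channels and corrects by n_times", {
  d <- tiny_dataset(n_subjects = 5)
  tm <- paired_ttest_map(compute_erps(d), correction_scope = "time_only")
  expect_equal(dim(tm$t_map$values), c(1L, 60L))
  expect_equal(tm$threshold, 0.05 / 60)
  expect_match(tm$t_map$channel_names, "O1")
})
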
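test_that("degenerate noise gives exactly baseline inter-budding intervals", {
  p <- uncensored_params(firstgen_bti_multiplier = 1,
                         terminal_elongation_peak = 1,
                         desync_cv_growth_per_gen = 0,
                         lifespan_mean = 10, lifespan_sd = 0)
  ct <- sample_cell_truth(p, 0, rng_stream(1))
  expect_equal(length(ct$appear), 10L)
  expect_equal(diff(ct$appear), rep(90, 9))
  expect_equal(ct$appear[1], 90)  # first bud one baseline after capture
})

test_that("the first-generation multiplier scales only interval 1 -> 2", {
  p <- uncensored_params(firstgen_bti_multiplier = 1.09,
                         terminal_elongation_peak = 1,
                         desync_cv_growth_per_gen = 0,
                         lifespan_mean = 12, lifespan_sd = 0)
  ct <- sample_cell_truth(p, 0, rng_stream(3))
  iv <- diff(ct$appear)
  expect_equal(iv[1] / iv[2], 1.09)
  expect_equal(iv[-1], rep(90, length(iv) - 1L))
})

test_that("terminal elongation ramps linearly to its peak at the last interval", {
  p <- uncensored_params(firstgen_bti_multiplier = 1,
                         terminal_elongation_gens = 5L,
                         terminal_elongation_peak = 2,
                         desync_cv_growth_per_gen = 0,
                         lifespan_mean = 12, lifespan_sd = 0)
  iv <- diff(sample_cell_truth(p, 0, rng_stream(4))$appear)
  expect_equal(tail(iv, 5) / 90, c(1.2, 1.4, 1.6, 1.8, 2.0))
  expect_equal(iv[2], 90)
})

test_that("event times interleave legally for every sampled cell", {
  p <- uncensored_params()
  rng <- rng_stream(11)
  for (i in 1:50) {
    ct <- sample_cell_truth(p, 0, rng)
    expect_true(all(diff(ct$appear) > 0))
    expect_true(all(ct$dissect > ct$appear))
    expect_true(ct$capture_time <= ct$appear[1])
  }
})

test_that("lifespan sampling recovers the configured mean and SD", {
  p <- uncensored_params()
  rng <- rng_stream(97)
  n <- 10000L
  rls <- vapply(seq_len(n), function(i)
    sample_cell_truth(p, 0, rng)$target_generations, numeric(1))
  se_mean <- p$lifespan_sd / sqrt(n)
  expect_lt(abs(mean(rls) - p$lifespan_mean), 3 * se_mean)
  se_sd <- p$lifespan_sd / sqrt(2 * n)
  # integer rounding adds 1/12 to the variance; truncation at 1 removes less
  expect_lt(abs(sd(rls) - p$lifespan_sd), 3 * se_sd + 0.05)
})

test_that("capture delay shortens the generation target linearly, floored at 1", {
  p <- uncensored_params(daughter_penalty_per_hour = 0.5, lifespan_sd = 0,
                         lifespan_mean = 10)
  rng <- rng_stream(5)
  expect_equal(sample_cell_truth(p, 0, rng)$target_generations, 10L)
  expect_equal(sample_cell_truth(p, 600, rng)$target_generations, 5L)
  expect_equal(sample_cell_truth(p, 8000, rng)$target_generations, 1L)
})

test_that("events beyond the run are truncated and the cell flagged censored", {
  p <- quick_params(lifespan_mean = 40, lifespan_sd = 0, run_duration = 600)
  ct <- sample_cell_truth(p, 0, rng_stream(8))
  expect_true(ct$censored)
  expect_true(all(ct$appear < 600))
  expect_true(is.na(ct$death_time))
  expect_lt(length(ct$appear), 40L)
})

test_that("sampling requires an explicit rng stream", {
  p <- quick_params()
  expect_error(sample_cell_truth(p, 0), "rng stream")
  expect_error(sample_cell_truth(p, 0, rng = 42), "rng stream")
  expect_error(sample_cell_truth(p, 1e9, rng_stream(1)), "capture_time")
})

test_that("rng streams are reproducible and independent of global state", {
  a <- with_stream(rng_stream(123), runif(3))
  set.seed(999)
  before <- .Random.seed
  b <- with_stream(rng_stream(123), runif(3))
  expect_identical(a, b)
  expect_identical(before, .Random.seed)  # global state untouched
  expect_false(identical(with_stream(substream(1, "a"), runif(1)),
                         with_stream(substream(1, "b"), runif(1))))
})
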
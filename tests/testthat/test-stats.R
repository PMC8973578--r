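mk_matrix <- function(dn, dt, frames = seq_along(dn), capture = 0L,
                      interval = 10) {
  structure(list(cell_id = "m", capture_frame = as.integer(capture),
                 frame_interval = interval,
                 codes = data.frame(frame_index = as.integer(frames),
                                    delta_n = as.integer(dn),
                                    delta_t = as.integer(dt)),
                 termination = "death_called",
                 termination_frame = max(frames)),
            class = "digital_matrix")
}

mk_records <- function(rls, btis = NULL, capture_min = 0,
                       run_id = "run1", termination = "death_called") {
  n <- length(rls)
  data.frame(cell_id = sprintf("r%03d", seq_len(n)), run_id = run_id,
             capture_min = rep_len(capture_min, n), rls = rls,
             termination = rep_len(termination, n),
             bti0 = NA_real_) -> out
  out$btis <- if (is.null(btis))
    lapply(rls, function(k) rep(90, max(k - 1, 0))) else btis
  out
}

test_that("RLS sums the 1s of both digits", {
  expect_equal(rls_from_matrix(mk_matrix(rep(0L, 8), rep(0L, 8))), 0L)
  m <- mk_matrix(c(rep(1L, 20), rep(0L, 3)), c(rep(0L, 20), rep(1L, 3)),
                 frames = 1:23)
  expect_equal(rls_from_matrix(m), 23L)
})

test_that("the reconstructed 23-generation reference matrix yields RLS 23", {
  m <- representative_matrix()
  expect_equal(rls_from_matrix(m), 23L)
  expect_equal(max(to_oscillogram(m)$steps$cumulative_generations), 23L)
  expect_equal(length(btis_from_matrix(m)), 22L)
})

test_that("BTIs are frame differences between budding events times the interval", {
  m <- mk_matrix(c(1L, 1L), c(0L, 0L), frames = c(10L, 19L))
  expect_equal(btis_from_matrix(m), 90)
  m2 <- mk_matrix(rep(1L, 4), rep(0L, 4), frames = c(4L, 13L, 22L, 40L))
  expect_equal(btis_from_matrix(m2), c(90, 90, 180))
  expect_equal(btis_from_matrix(mk_matrix(1L, 0L, frames = 5L)), numeric(0))
  expect_error(btis_from_matrix(m, frame_interval = -1), "frame_interval")
})

test_that("lifespan records tie rls, btis and bti0 together", {
  m <- mk_matrix(c(1L, 1L, 0L, 1L), c(0L, 0L, 1L, 0L),
                 frames = c(3L, 12L, 20L, 30L))
  rec <- lifespan_records(list(m))
  expect_equal(rec$rls, 4L)
  expect_equal(lengths(rec$btis), 3L)
  expect_equal(rec$bti0, 30)  # capture frame 0 to first budding frame 3
  expect_equal(rec$btis[[1]], c(90, 80, 100))
})

test_that("viability is a non-increasing step function starting at 1", {
  v <- viability_curve(c(1, 2, 3))
  expect_equal(v$fraction_alive[v$generation == 0], 1)
  expect_equal(v$fraction_alive[v$generation == 2], 2 / 3)
  expect_true(all(diff(v$fraction_alive) <= 0))
  # all cells equal: flat at 1 over the whole domain 0..k (the drop to 0
  # happens beyond the last observed generation)
  vk <- viability_curve(rep(5L, 9))
  expect_equal(vk$generation, 0:5)
  expect_equal(vk$fraction_alive, rep(1, 6))
  expect_error(viability_curve(integer(0)), "RLS")
})

test_that("the viability tail sum equals the mean RLS exactly", {
  for (seed in c(1, 2)) {
    rls <- with_stream(rng_stream(seed), rpois(300, 20))
    v <- viability_curve(rls)
    expect_equal(sum(v$fraction_alive[v$generation >= 1]), mean(rls))
  }
})

test_that("cohort mean and SE follow the stated conventions", {
  ms <- cohort_mean_se(list(c(5, 5), c(5, 5), c(5, 5)))
  expect_equal(ms$mean, 5)
  expect_equal(ms$se, 0)
  runs <- list(c(1, 3), c(2, 4))  # pooled sd = sqrt(5/3)
  ms2 <- cohort_mean_se(runs)
  expect_equal(ms2$se_paper, sd(unlist(runs)) / sqrt(2))
  expect_equal(ms2$se_conventional, sd(unlist(runs)) / sqrt(4))
  expect_equal(cohort_mean_se(runs, "conventional")$se,
               ms2$se_conventional)
  expect_error(cohort_mean_se(list()), "non-empty")
})

test_that("capture-time binning and the linear fit behave at the edges", {
  rec <- mk_records(c(10, 12, 14), capture_min = c(10, 50, 100))
  bins <- bin_by_capture_time(rec, bin_width = 2)
  expect_equal(nrow(bins), 1L)  # all in [0, 2 h)
  expect_error(linear_fit(bins), "bins")
  rec2 <- mk_records(c(20, 18, 16, 14), capture_min = c(60, 180, 300, 420))
  bins2 <- bin_by_capture_time(rec2, bin_width = 2)
  expect_equal(bins2$n, rep(1, 4))
  fit <- linear_fit(bins2)
  expect_equal(unname(fit["slope"]), -1)
  expect_equal(unname(fit["intercept"]), 21)
})

test_that("a null daughter penalty gives a slope within noise of zero", {
  lay <- tiny_layout(rows = 6L, cols = 10L)
  p <- quick_params(daughter_penalty_per_hour = 0, lifespan_mean = 6,
                    lifespan_sd = 1, run_duration = 2000,
                    mother_loss_hazard = 0.002, extra_capture_hazard = 0)
  co <- simulate_cohort(lay, p, seed = 29, n_runs = 2)
  rec <- clean_records(co$records)
  fit <- linear_fit(bin_by_capture_time(rec, bin_width = 4))
  expect_lt(abs(fit["slope"]), 0.5)
})

test_that("birth-aligned profile recovers a constructed extension exactly", {
  btis <- rep(list(c(98.1, rep(90, 5))), 4)
  rec <- mk_records(rep(7L, 4), btis = btis)
  ba <- birth_aligned_bti(rec)
  expect_equal(ba$extension_pct, 9.0)
  flat <- mk_records(rep(7L, 4))
  expect_equal(birth_aligned_bti(flat)$extension_pct, 0)
  short <- mk_records(rep(3L, 4))
  expect_error(birth_aligned_bti(short), "generation")
})

test_that("death alignment indexes intervals backwards from the last event", {
  rec <- mk_records(4L, btis = list(c(90, 90, 180)))
  da <- death_aligned_bti(rec)
  expect_equal(da$mean_bti[da$offset == 1], 180)
  expect_equal(da$mean_bti[da$offset == 3], 90)
  flat <- mk_records(rep(8L, 6))
  daf <- death_aligned_bti(flat)
  expect_true(all(daf$mean_bti == 90))
})

test_that("the kymograph orders cells by RLS and labels 5-generation periods", {
  rec <- mk_records(7L)
  k <- kymograph_matrix(rec)
  expect_equal(ncol(k$bti), 6L)
  expect_equal(k$period, c(0L, 0L, 0L, 0L, 0L, 1L))
  rec2 <- mk_records(c(9L, 3L))
  k2 <- kymograph_matrix(rec2)
  expect_equal(k2$rls, c(3L, 9L))
  expect_equal(sum(is.na(k2$bti[1, ])), 6L)  # padding for the short cell
})

test_that("percent decrease matches direct arithmetic", {
  expect_equal(round(percent_decrease(24.29, 17.21), 2), 29.15)
  expect_equal(percent_decrease(10, 10), 0)
  expect_equal(percent_decrease(8, 6), 25)
  expect_error(percent_decrease(0, 5), "positive")
})

test_that("de-synchronization grows the across-cell BTI spread with age", {
  p <- uncensored_params(desync_cv_growth_per_gen = 0.02,
                         lifespan_mean = 25, lifespan_sd = 4)
  for (seed in c(3, 14)) {
    rt <- clean_roundtrip(120, p, seed = seed)
    rec <- lifespan_records(rt$matrices)
    k <- kymograph_matrix(clean_records(rec))
    sd5 <- sd(k$bti[, 5], na.rm = TRUE)
    sd15 <- sd(k$bti[, 15], na.rm = TRUE)
    expect_gt(sd15, sd5)
  }
})

test_that("cohort summary composes the pieces consistently", {
  lay <- tiny_layout(rows = 6L, cols = 10L)
  co <- simulate_cohort(lay, quick_params(lifespan_mean = 10,
                                          lifespan_sd = 2,
                                          run_duration = 2000),
                        seed = 41, n_runs = 2)
  s <- summarize_cohort(co$records)
  rec <- clean_records(co$records)
  expect_equal(s$n_cells, nrow(rec))
  expect_equal(sum(s$per_bin$n), s$n_cells)
  expect_equal(s$mean_rls, mean(rec$rls))
  expect_equal(sum(s$viability$fraction_alive[s$viability$generation >= 1]),
               s$mean_rls)
  expect_equal(nrow(s$kymograph$bti), s$n_cells)
})
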
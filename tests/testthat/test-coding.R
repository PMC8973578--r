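test_that("single transitions code the three canonical motifs", {
  mother <- objects_df("mother", 5)
  one_big <- rbind(mother, objects_df("bud", 3.8))
  one_small <- rbind(mother, objects_df("bud", 1.2))
  two <- rbind(mother, objects_df(c("bud", "bud"), c(3.5, 1.1)))
  # (i) removal then later appearance, with a bud-free frame in between
  c1 <- code_transition(one_big, mother)
  expect_equal(c(c1$delta_n, c1$delta_t), c(-1L, 0L))
  c2 <- code_transition(mother, one_small)
  expect_equal(c(c2$delta_n, c2$delta_t), c(1L, 0L))
  # (iii) same-interval handoff: equal counts, large size drop
  c3 <- code_transition(one_big, one_small, size_drop_threshold = 0.5)
  expect_equal(c(c3$delta_n, c3$delta_t), c(0L, 1L))
  # growth alone is not a handoff
  c4 <- code_transition(one_small, one_big)
  expect_equal(c(c4$delta_n, c4$delta_t), c(0L, 0L))
  # (ii) overlap: a second bud appears before the first is removed
  c5 <- code_transition(one_big, two)
  expect_equal(c(c5$delta_n, c5$delta_t), c(1L, 0L))
  # overlap resolution matches the surviving small bud, not the removed one
  two_late <- rbind(mother, objects_df(c("bud", "bud"), c(3.9, 1.5)))
  one_surv <- rbind(mother, objects_df("bud", 1.9))
  c6 <- code_transition(two_late, one_surv)
  expect_equal(c(c6$delta_n, c6$delta_t), c(-1L, 0L))
  # mother gone signals loss instead of a code
  expect_s3_class(code_transition(one_big, objects_df("bud", 3.9)),
                  "transition_signal")
  expect_error(code_transition(objects_df("bud", 3), mother), "mother")
})

test_that("a counted series yields the forced code sequence", {
  s <- make_series(c(0, 1, 1, 0, 1, 1, 0),
                   sizes = list(NULL, 1.2, 3.5, NULL, 1.2, 3.5, NULL))
  m <- encode_series(s, frame_interval = 10, death_gap = 1e9)
  expect_equal(m$codes$delta_n, c(1L, 0L, -1L, 1L, 0L, -1L))
  expect_equal(m$codes$delta_t, rep(0L, 6))
  expect_equal(rls_from_matrix(m), 2L)
  # count conservation: initial + sum(delta_n) = final bud count
  expect_equal(sum(m$codes$delta_n), 0L)
})

test_that("three buds or a second adult terminate the record as contaminated", {
  s3 <- make_series(c(0, 1, 3, 1), sizes = list(NULL, 2, c(1, 2, 3), 2))
  m <- encode_series(s3, frame_interval = 10)
  expect_equal(m$termination, "contaminated")
  expect_equal(m$termination_frame, 2L)
  expect_equal(nrow(m$codes), 1L)  # only the transition into frame 1
  s <- make_series(c(1, 1, 1))
  extra <- data.frame(cell_id = "cellA", frame_index = 2L, role = "mother",
                      size_um = 5)
  m2 <- encode_series(rbind(s, extra), frame_interval = 10)
  expect_equal(m2$termination, "contaminated")
  expect_equal(m2$termination_frame, 2L)
})

test_that("a bud at capture is generation 1 under the default policy only", {
  s <- make_series(c(1, 1, 0), sizes = list(3.0, 3.8, NULL))
  m_on <- encode_series(s, frame_interval = 10, death_gap = 1e9)
  expect_equal(m_on$codes$delta_n[1], 1L)
  expect_equal(m_on$codes$frame_index[1], 0L)
  expect_equal(rls_from_matrix(m_on), 1L)
  m_off <- encode_series(s, frame_interval = 10, death_gap = 1e9,
                         capture_bud_as_gen1 = FALSE)
  expect_equal(rls_from_matrix(m_off), 0L)
  expect_equal(nrow(m_off$codes), 2L)
})

test_that("termination separates loss, death, censoring and dead-then-lost", {
  # mother vanishes mid-life -> lost
  s <- make_series(c(0, 1, 1), sizes = list(NULL, 1.5, 2.5))
  m <- encode_series(s, frame_interval = 10, death_gap = 600, end_frame = 10)
  expect_equal(m$termination, "lost")
  expect_equal(m$termination_frame, 3L)
  # quiet long enough before series end -> death called
  s2 <- make_series(c(0, 1, 0, rep(0, 70)), sizes = list(NULL, 2, NULL))
  m2 <- encode_series(s2, frame_interval = 10, death_gap = 600)
  expect_equal(m2$termination, "death_called")
  # still budding at run end -> censored
  s3 <- make_series(c(0, 1, 1, 1), sizes = list(NULL, 1.5, 2.5, 3.5))
  m3 <- encode_series(s3, frame_interval = 10, death_gap = 600)
  expect_equal(m3$termination, "censored")
  # a mother dragged away long after its last budding event died first
  s4 <- make_series(c(0, 1, 0, rep(0, 70)), sizes = list(NULL, 2, NULL))
  m4 <- encode_series(s4, frame_interval = 10, death_gap = 600,
                      end_frame = 200)
  expect_equal(m4$termination, "death_called")
})

test_that("encoding is a pure function of the series and threshold", {
  p <- uncensored_params()
  rng <- rng_stream(33)
  ct <- sample_cell_truth(p, 0, rng)
  ct$trap_id <- 1L; ct$cell_id <- "x"
  obs <- render_observations(ct, p)
  m1 <- encode_series(obs, frame_interval = 10, end_frame = 899)
  m2 <- encode_series(obs, frame_interval = 10, end_frame = 899)
  expect_identical(m1, m2)
})

test_that("count conservation holds across random clean cells", {
  p <- uncensored_params(overlap_prob = 0.4, same_frame_handoff_prob = 0.3)
  rt <- clean_roundtrip(25, p, seed = 55)
  for (m in rt$matrices) {
    expect_true(all(cumsum(m$codes$delta_n) >= 0L))
    expect_equal(sum(m$codes$delta_n), 0L)
  }
})

test_that("delta_t fires only at true same-interval handoffs", {
  p <- uncensored_params(overlap_prob = 0.3, same_frame_handoff_prob = 0.25)
  rt <- clean_roundtrip(40, p, seed = 77)
  dt <- p$frame_interval
  for (i in seq_along(rt$matrices)) {
    m <- rt$matrices[[i]]
    ct <- rt$truths[[i]]
    flagged <- m$codes$frame_index[m$codes$delta_t == 1L]
    n <- length(ct$appear)
    truehand <- integer(0)
    if (n > 1L) {
      d <- ct$dissect[seq_len(n - 1L)]
      a <- ct$appear[-1L]
      # a handoff is observed iff no frame time lands in the bud-free gap
      # [dissect, next appearance): the old bud's last frame immediately
      # precedes the new bud's first frame
      same <- d < a & ceiling(d / dt) * dt >= a - 1e-9
      truehand <- as.integer(ceiling(a[same] / dt - 1e-9))
    }
    expect_equal(sort(flagged), sort(truehand))
  }
})

test_that("the oscillogram staircase ends at the matrix RLS", {
  m0 <- structure(list(cell_id = "z", capture_frame = 0L,
                       frame_interval = 10,
                       codes = data.frame(frame_index = c(5L, 14L, 23L),
                                          delta_n = c(1L, 1L, 1L),
                                          delta_t = c(0L, 0L, 0L)),
                       termination = "death_called",
                       termination_frame = 30L),
                  class = "digital_matrix")
  osc <- to_oscillogram(m0)
  expect_equal(osc$steps$frame_index, c(0L, 5L, 14L, 23L))
  expect_equal(osc$steps$cumulative_generations, 0:3)
  flat <- m0
  flat$codes$delta_n <- 0L
  expect_equal(max(to_oscillogram(flat)$steps$cumulative_generations), 0L)
  p <- uncensored_params()
  rt <- clean_roundtrip(10, p, seed = 9)
  for (m in rt$matrices) {
    lvl <- max(to_oscillogram(m)$steps$cumulative_generations)
    expect_equal(lvl, rls_from_matrix(m))
  }
})
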
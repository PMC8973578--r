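# Shared fixtures: compact parameter sets and hand-built observation series.

# small, fast experiment parameters for structural tests
quick_params <- function(...) {
  args <- list(...)
  base <- list(lifespan_mean = 8, lifespan_sd = 2, baseline_bti = 60,
               terminal_elongation_gens = 2L, run_duration = 1440,
               death_gap = 300)
  base[names(args)] <- args
  do.call(aging_params, base)
}

# long-run parameters under which no cell is censored (lifespan tail fits
# comfortably inside the run)
uncensored_params <- function(...) {
  args <- list(...)
  base <- list(run_duration = 9000, daughter_penalty_per_hour = 0)
  base[names(args)] <- args
  do.call(aging_params, base)
}

tiny_layout <- function(n_subarrays = 1L, rows = 4L, cols = 5L)
  build_layout(array_layout(n_subarrays = n_subarrays,
                            rows_per_subarray = rows,
                            cols_per_subarray = cols))

# observation series from a vector of per-frame bud counts; bud sizes are
# generated growing unless given explicitly as a list of size vectors
make_series <- function(counts, sizes = NULL, f0 = 0L,
                        cell_id = "cellA", mother = TRUE) {
  rows <- list()
  for (i in seq_along(counts)) {
    f <- f0 + i - 1L
    if (mother)
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = cell_id, frame_index = f, role = "mother",
                   size_um = 5)
    nb <- counts[i]
    if (nb > 0L) {
      s <- if (is.null(sizes)) seq(1.5, 3.5, length.out = nb)
           else sizes[[i]]
      rows[[length(rows) + 1L]] <-
        data.frame(cell_id = cell_id, frame_index = f, role = "bud",
                   size_um = s)
    }
  }
  do.call(rbind, rows)
}

objects_df <- function(roles, sizes)
  data.frame(role = roles, size_um = sizes)

# simulate n clean cells (no loss/contamination) captured at time 0 and
# return truths + encoded matrices
clean_roundtrip <- function(n, params, seed, ...) {
  rng <- rng_stream(seed)
  truths <- vector("list", n)
  mats <- vector("list", n)
  end_frame <- floor(params$run_duration / params$frame_interval) - 1L
  for (i in seq_len(n)) {
    ct <- sample_cell_truth(params, 0, rng)
    ct$trap_id <- 1L
    ct$cell_id <- sprintf("c%04d", i)
    truths[[i]] <- ct
    # age-grown interval noise can occasionally shrink a maturation below
    # one frame, which render_observations() flags; harmless here
    obs <- suppressWarnings(render_observations(ct, params))
    mats[[i]] <- encode_series(obs, frame_interval = params$frame_interval,
                               end_frame = end_frame, ...)
  }
  list(truths = truths, matrices = mats)
}
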
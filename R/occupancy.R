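# Core frame-by-frame simulation of the trap array: initial loading,
# self-filling of empty traps from upstream dissections, mother loss and
# extra-cell capture. Cell timelines are co-sampled at the moment of capture
# because refilling is driven by the dissections of already-captured cells.
simulate_traps <- function(layout, params, rng) {
  if (inherits(layout, "array_layout") || (is.list(layout) && !is.data.frame(layout)))
    layout <- build_layout(layout)
  stopifnot(is.data.frame(layout), inherits(params, "aging_params"))
  if (!inherits(rng, "rng_stream"))
    stop("an explicit rng stream is required (see rng_stream())")
  if (anyDuplicated(layout$trap_id))
    stop("duplicate trap ids in layout")
  p <- params
  dt <- p$frame_interval
  n_frames <- as.integer(floor(p$run_duration / dt))
  nT <- nrow(layout)
  rank1 <- layout$upstream_rank + 1L

  cells <- vector("list", 2L * nT + 16L)
  n_cells <- 0L
  cell_of <- rep(NA_integer_, nT)
  sched_trap <- vector("list", n_frames)
  sched_cell <- vector("list", n_frames)
  cap_trap <- integer(0)
  cap_time <- numeric(0)

  add_cell <- function(ti, t_cap) {
    truth <- sample_cell_truth(p, t_cap, rng)
    n_cells <<- n_cells + 1L
    if (n_cells > length(cells)) length(cells) <<- 2L * n_cells
    truth$trap_id <- layout$trap_id[ti]
    truth$cell_id <- sprintf("c%05d", n_cells)
    cells[[n_cells]] <<- truth
    cell_of[ti] <<- n_cells
    cap_trap <<- c(cap_trap, ti)
    cap_time <<- c(cap_time, t_cap)
    dfr <- as.integer(ceiling(truth$dissect / dt))  # event in ((f-1)dt, f*dt]
    dfr <- dfr[truth$dissect <= p$run_duration & dfr < n_frames & dfr >= 1L]
    for (f in dfr) {
      sched_trap[[f]] <<- c(sched_trap[[f]], ti)
      sched_cell[[f]] <<- c(sched_cell[[f]], n_cells)
    }
    invisible(NULL)
  }

  occ_frac <- numeric(n_frames)
  init <- with_stream(rng, stats::runif(nT)) < p$initial_occupancy
  for (ti in which(init)) add_cell(ti, 0)
  occ_frac[1L] <- mean(!is.na(cell_of))

  for (f in seq_len(n_frames - 1L)) {
    t <- f * dt
    empty_at_start <- is.na(cell_of)

    # dissections landing in this frame, from cells still in their trap
    st <- sched_trap[[f]]
    sc <- sched_cell[[f]]
    diss_ranks <- integer(0)
    if (length(st)) {
      keep <- !is.na(cell_of[st]) & cell_of[st] == sc
      diss_ranks <- sort(rank1[st[keep]])
    }

    occ_idx <- which(!is.na(cell_of))
    if (p$mother_loss_hazard > 0 && length(occ_idx)) {
      lost <- occ_idx[with_stream(rng, stats::runif(length(occ_idx))) <
                        p$mother_loss_hazard]
      for (ti in lost) {
        cells[[cell_of[ti]]]$lost_time <- t
        cell_of[ti] <- NA_integer_
      }
    }
    occ_idx <- which(!is.na(cell_of))
    if (p$extra_capture_hazard > 0 && length(occ_idx)) {
      hit <- occ_idx[with_stream(rng, stats::runif(length(occ_idx))) <
                       p$extra_capture_hazard]
      for (ti in hit) {
        ci <- cell_of[ti]
        if (is.na(cells[[ci]]$contaminated_time))
          cells[[ci]]$contaminated_time <- t
      }
    }

    # self-filling of traps that entered this frame empty
    cand <- which(empty_at_start & is.na(cell_of))
    if (length(cand) && length(diss_ranks) && p$refill_coupling > 0) {
      k <- findInterval(rank1[cand] - 0.5, diss_ranks)
      pf <- 1 - (1 - p$refill_coupling)^k
      fill <- cand[with_stream(rng, stats::runif(length(cand))) < pf]
      for (ti in fill) add_cell(ti, t)
    }
    occ_frac[f + 1L] <- mean(!is.na(cell_of))
  }

  cells <- cells[seq_len(n_cells)]
  list(cells = cells,
       capture_log = data.frame(
         cell_id = vapply(cells, function(x) x$cell_id, character(1)),
         trap_id = layout$trap_id[cap_trap],
         capture_min = cap_time),
       occupancy = data.frame(frame = seq_len(n_frames) - 1L,
                              time_min = (seq_len(n_frames) - 1L) * dt,
                              occupied_fraction = occ_frac))
}

#' Simulate trap-array occupancy dynamics
#'
#' At time 0 each trap fills independently with probability
#' `initial_occupancy`. At every subsequent frame an empty trap fills with
#' probability `1 - (1 - refill_coupling)^k`, where k counts the daughter
#' dissections occurring that frame in occupied traps upstream of it
#' (self-filling). Occupied traps lose their mother with per-frame hazard
#' `mother_loss_hazard` (the trap then empties and may refill) and capture
#' an extra cell with hazard `extra_capture_hazard`.
#'
#' @param layout A trap table from [build_layout()] (or an `array_layout`).
#' @param params An [aging_params()].
#' @param rng An [rng_stream()].
#' @return List with `capture_log` (cell_id, trap_id, capture_min) and
#'   `occupancy` (frame, time_min, occupied_fraction).
#' @export
simulate_occupancy <- function(layout, params, rng) {
  sim <- simulate_traps(layout, params, rng)
  sim[c("capture_log", "occupancy")]
}
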
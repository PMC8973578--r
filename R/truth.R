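#' Sample the ground-truth event timeline of one trapped cell
#'
#' Draws a complete per-cell timeline: a target generation count from the
#' configured lifespan distribution (reduced linearly by the capture delay,
#' floored at 1 generation), bud-appearance times whose inter-budding
#' intervals carry the first-generation extension, the terminal elongation
#' ramp and multiplicative noise whose coefficient of variation grows with
#' replicative age, and a dissection time for every bud. For each interval
#' the relation between the previous dissection and the next appearance is
#' drawn among the three observable motifs: an observable bud-free gap
#' (default), an overlap in which the next bud appears before the previous
#' daughter detaches (`overlap_prob`), or a same-interval handoff in which
#' dissection and the next appearance fall between two consecutive frames
#' (`same_frame_handoff_prob`). Events after `run_duration` are truncated
#' and the cell flagged censored.
#'
#' @param params An [aging_params()].
#' @param capture_time Capture time in minutes, within `[0, run_duration)`.
#' @param rng An [rng_stream()]; required, there is no hidden global state.
#' @return An object of class `cell_truth`: a list with `capture_time`,
#'   vectors `appear` / `dissect` (one entry per generation observed before
#'   run end), `death_time` (NA when censored), `lost_time`,
#'   `contaminated_time`, `target_generations` and `censored`.
#' @export
sample_cell_truth <- function(params, capture_time, rng) {
  if (!inherits(params, "aging_params")) stop("'params' must be aging_params")
  if (missing(rng) || !inherits(rng, "rng_stream"))
    stop("sample_cell_truth() requires an explicit rng stream; ",
         "create one with rng_stream(seed)")
  if (!is.numeric(capture_time) || length(capture_time) != 1L ||
      capture_time < 0 || capture_time >= params$run_duration)
    stop("'capture_time' must lie within [0, run_duration)")
  p <- params
  dt <- p$frame_interval
  with_stream(rng, {
    target <- switch(p$lifespan_family,
      gaussian = stats::rnorm(1L, p$lifespan_mean, p$lifespan_sd),
      gamma = if (p$lifespan_sd == 0) p$lifespan_mean else
        stats::rgamma(1L, shape = (p$lifespan_mean / p$lifespan_sd)^2,
                      rate = p$lifespan_mean / p$lifespan_sd^2))
    target <- target - p$daughter_penalty_per_hour * capture_time / 60
    n <- max(1L, as.integer(round(target)))

    # inter-budding intervals I_g for g = 1 .. n-1 (budding g -> budding g+1)
    g <- seq_len(max(n - 1L, 0L))
    fac <- rep(1, length(g))
    fac[g == 1L] <- p$firstgen_bti_multiplier
    L <- p$terminal_elongation_gens
    d <- n - g  # generations before death; d = 1 is the final interval
    ter <- L > 0 & d <= L
    fac[ter] <- fac[ter] *
      (1 + (p$terminal_elongation_peak - 1) * (L + 1 - d[ter]) / L)
    cv <- p$desync_cv_growth_per_gen * g
    noise <- rep(1, length(g))
    pos <- cv > 0
    if (any(pos)) {
      sig <- sqrt(log(1 + cv[pos]^2))
      noise[pos] <- stats::rlnorm(sum(pos), meanlog = -sig^2 / 2, sdlog = sig)
    }
    intervals <- p$baseline_bti * fac * noise
    appear <- capture_time + cumsum(c(p$baseline_bti, intervals))

    dissect <- numeric(n)
    if (n > 1L) {
      u <- stats::runif(n - 1L)
      a <- appear[seq_len(n - 1L)]
      nx <- appear[-1L]
      # motif (i): observable gap of ~1.5 frames before the next appearance
      diss <- pmax(a + 0.3 * dt, nx - 1.5 * dt)
      # motif (ii): overlap — previous bud outlives the next appearance
      ii <- u < p$overlap_prob
      diss[ii] <- nx[ii] + 1.2 * dt
      # motif (iii): dissection and next appearance inside one frame window
      iii <- !ii & u < p$overlap_prob + p$same_frame_handoff_prob
      if (any(iii)) {
        k <- floor(nx[iii] / dt) * dt
        frac <- nx[iii] - k
        diss[iii] <- ifelse(frac > 0.1 * dt, k + 0.5 * frac,
                            nx[iii] - 0.4 * dt)
        diss[iii] <- pmax(diss[iii], a[iii] + 0.1 * dt)
      }
      dissect[seq_len(n - 1L)] <- diss
    }
    dissect[n] <- appear[n] + max(0.3 * dt, p$baseline_bti - 1.5 * dt)

    keep <- appear < p$run_duration
    censored <- !all(keep) || dissect[n] > p$run_duration
    appear <- appear[keep]
    dissect <- dissect[keep]
    structure(list(trap_id = NA_integer_, cell_id = NA_character_,
                   capture_time = capture_time, appear = appear,
                   dissect = dissect,
                   death_time = if (censored) NA_real_ else dissect[length(dissect)],
                   lost_time = NA_real_, contaminated_time = NA_real_,
                   target_generations = n, censored = censored),
              class = "cell_truth")
  })
}

#' Number of budding events observable before run end
#'
#' For an uncensored cell this equals the true replicative lifespan (the
#' target generation count); for a censored cell it is the number of buds
#' that appeared before the recording ended.
#'
#' @param truth A `cell_truth`.
#' @param run_duration Run length in minutes (defaults to all events).
#' @return Integer count of bud appearances before `run_duration`.
#' @export
observed_generations <- function(truth, run_duration = Inf) {
  stopifnot(inherits(truth, "cell_truth"))
  end <- min(run_duration,
             if (is.na(truth$lost_time)) Inf else truth$lost_time)
  sum(truth$appear < end)
}

#' Flatten a list of cell truths into the long truth table
#'
#' @param cells List of `cell_truth` objects.
#' @return A data.frame with one row per generation event: `trap_id`,
#'   `cell_id`, `capture_min`, `generation`, `appear_min`, `dissect_min`,
#'   `death_min`, `lost_min`, `contaminated_min`.
#' @export
truth_table <- function(cells) {
  rows <- lapply(cells, function(ct) {
    ng <- length(ct$appear)
    if (ng == 0L) {
      data.frame(trap_id = ct$trap_id, cell_id = ct$cell_id,
                 capture_min = ct$capture_time, generation = NA_integer_,
                 appear_min = NA_real_, dissect_min = NA_real_,
                 death_min = ct$death_time, lost_min = ct$lost_time,
                 contaminated_min = ct$contaminated_time)
    } else {
      data.frame(trap_id = ct$trap_id, cell_id = ct$cell_id,
                 capture_min = ct$capture_time, generation = seq_len(ng),
                 appear_min = ct$appear, dissect_min = ct$dissect,
                 death_min = ct$death_time, lost_min = ct$lost_time,
                 contaminated_min = ct$contaminated_time)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
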
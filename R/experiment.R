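#' Simulate a complete trap-array aging experiment
#'
#' Runs the occupancy simulation, co-samples a ground-truth timeline for
#' every captured cell, and renders the frame-sampled observation table the
#' event coder consumes. The result is deterministic given
#' `(layout, params, seed)`.
#'
#' @param layout A trap table from [build_layout()] or an [array_layout()].
#' @param params An [aging_params()].
#' @param seed Explicit integer seed; fanned out to a named substream.
#' @param growth_model Optional bud growth model (see [render_observations()]).
#' @return An object of class `trap_experiment`: list with `observations`
#'   (long object table), `truth` (long event table), `capture_log`,
#'   `occupancy`, `cells` (list of `cell_truth`) and `manifest`.
#' @export
simulate_experiment <- function(layout, params = aging_params(), seed,
                                growth_model = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    stop("an explicit integer seed is required")
  if (inherits(layout, "array_layout") ||
      (is.list(layout) && !is.data.frame(layout)))
    layout <- build_layout(layout)
  rng <- substream(seed, "population")
  sim <- simulate_traps(layout, params, rng)
  obs <- do.call(rbind, lapply(sim$cells, render_observations,
                               params = params, growth_model = growth_model))
  rownames(obs) <- NULL
  manifest <- list(
    seed = as.integer(seed),
    package = "traplife",
    package_version = as.character(utils::packageVersion("traplife")),
    n_traps = nrow(layout),
    n_frames = nrow(sim$occupancy),
    frame_interval = params$frame_interval,
    params = unclass(params),
    n_cells = length(sim$cells),
    n_lost = sum(vapply(sim$cells, function(x) !is.na(x$lost_time), logical(1))),
    n_contaminated = sum(vapply(sim$cells,
                                function(x) !is.na(x$contaminated_time),
                                logical(1))))
  structure(list(observations = obs, truth = truth_table(sim$cells),
                 capture_log = sim$capture_log, occupancy = sim$occupancy,
                 cells = sim$cells, manifest = manifest),
            class = "trap_experiment")
}

#' @export
print.trap_experiment <- function(x, ...) {
  m <- x$manifest
  cat("Trap-array aging experiment (seed ", m$seed, ")\n", sep = "")
  cat("  traps: ", m$n_traps, ", frames: ", m$n_frames,
      " (", m$frame_interval, " min interval)\n", sep = "")
  cat("  cells captured: ", m$n_cells, " (", m$n_lost, " lost, ",
      m$n_contaminated, " contaminated)\n", sep = "")
  cat("  final occupancy: ",
      round(100 * x$occupancy$occupied_fraction[nrow(x$occupancy)], 1),
      "%\n", sep = "")
  invisible(x)
}
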
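#' Encode a simulated experiment into lifespan records
#'
#' Convenience pipeline step: runs the two-digit coder over every cell of a
#' [simulate_experiment()] result, using the run's full imaging window so
#' mother loss, death calling and censoring are assessed correctly, and
#' returns the per-cell lifespan records.
#'
#' @param experiment A `trap_experiment`.
#' @param run_id Run identifier stamped on the records.
#' @param ... Further arguments to [encode_series()] (threshold, death gap,
#'   policies).
#' @return A [lifespan_records()] data frame.
#' @export
encode_experiment <- function(experiment, run_id = "run1", ...) {
  stopifnot(inherits(experiment, "trap_experiment"))
  end_frame <- experiment$manifest$n_frames - 1L
  mats <- encode_observations(experiment$observations,
                              frame_interval = experiment$manifest$frame_interval,
                              end_frame = end_frame, ...)
  lifespan_records(mats, run_id = run_id)
}

#' Simulate and encode a multi-run cohort
#'
#' Simulates `n_runs` independent trap-array experiments (each with its own
#' seed substream), encodes them, and row-binds the lifespan records with
#' run identifiers. This mirrors the standard protocol of pooling several
#' independent chip runs into one cohort.
#'
#' @param layout Trap table or [array_layout()] for each run.
#' @param params An [aging_params()].
#' @param seed Master integer seed.
#' @param n_runs Number of independent runs.
#' @param ... Further arguments to [encode_series()].
#' @return List `records` (pooled lifespan records) and `experiments`
#'   (list of `trap_experiment`).
#' @export
simulate_cohort <- function(layout = array_layout(n_subarrays = 1L),
                            params = aging_params(), seed, n_runs = 3L,
                            ...) {
  if (missing(seed)) stop("an explicit integer seed is required")
  if (inherits(layout, "array_layout") ||
      (is.list(layout) && !is.data.frame(layout)))
    layout <- build_layout(layout)
  exps <- lapply(seq_len(n_runs), function(r)
    simulate_experiment(layout, params, seed = derive_seed(seed,
                                                           paste0("run", r))))
  recs <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    rec <- encode_experiment(exps[[r]], run_id = paste0("run", r), ...)
    rec$cell_id <- paste0("run", r, "_", rec$cell_id)
    rec
  }))
  rownames(recs) <- NULL
  list(records = recs, experiments = exps)
}
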
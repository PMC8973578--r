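#' Aging-experiment parameters
#'
#' Parameters of the synthetic trap-array aging experiment: the replicative
#' lifespan distribution, budding-time-interval (BTI) structure, occupancy
#' dynamics and imaging schedule. All times are minutes from the start of the
#' experiment; frame f corresponds to time `f * frame_interval`.
#'
#' Defaults reproduce the study conditions the generator emulates:
#' a 60-h run imaged every 10 min, 70.5% initial occupancy, mean lifespan
#' 24.29 generations, a 9% first-generation BTI extension, and a terminal
#' BTI elongation ramp over the last 5 generations. The per-cell lifespan
#' standard deviation defaults to 6.32 generations, the pooled dispersion
#' implied by a reported 24.29 +/- 3.65 under the between-run standard-error
#' convention SE = SD/sqrt(runs) with 3 runs.
#'
#' @param lifespan_mean,lifespan_sd Mean and SD of the lifespan distribution
#'   (generations).
#' @param lifespan_family Distribution family for the generation target:
#'   `"gaussian"` (rounded, truncated at 1) or `"gamma"` (matched moments).
#' @param baseline_bti Baseline inter-budding interval (min).
#' @param firstgen_bti_multiplier Multiplier on the first inter-budding
#'   interval (dimensionless; 1.09 = 9% extension).
#' @param terminal_elongation_gens,terminal_elongation_peak Number of final
#'   generations over which BTIs ramp up linearly, and the peak multiplier
#'   reached at the last interval.
#' @param desync_cv_growth_per_gen Growth of the inter-cell BTI coefficient
#'   of variation per generation (dimensionless).
#' @param overlap_prob Probability that the next bud appears before the
#'   previous daughter dissects (a frame can then show two buds).
#' @param same_frame_handoff_prob Probability that a dissection and the next
#'   bud appearance fall inside the same inter-frame interval.
#' @param initial_occupancy Probability that a trap is filled at time 0.
#' @param refill_coupling Per-frame fill probability coupling of an empty
#'   trap to each dissection occurring upstream of it.
#' @param mother_loss_hazard Per-frame probability that an occupied trap
#'   loses its mother (dragged away).
#' @param extra_capture_hazard Per-frame probability that an occupied trap
#'   captures an extra cell (contaminating the record).
#' @param daughter_penalty_per_hour Generations of lifespan lost per hour of
#'   capture delay (daughters of old mothers inherit shortened lifespans).
#' @param run_duration Total run length (min).
#' @param frame_interval Imaging interval (min).
#' @param death_gap Budding-free interval before series end that calls death
#'   (min).
#' @return An object of class `aging_params`.
#' @export
aging_params <- function(lifespan_mean = 24.29, lifespan_sd = 6.32,
                         lifespan_family = c("gaussian", "gamma"),
                         baseline_bti = 90, firstgen_bti_multiplier = 1.09,
                         terminal_elongation_gens = 5L,
                         terminal_elongation_peak = 2.0,
                         desync_cv_growth_per_gen = 0.01,
                         overlap_prob = 0.2, same_frame_handoff_prob = 0.1,
                         initial_occupancy = 0.705, refill_coupling = 0.025,
                         mother_loss_hazard = 3e-4,
                         extra_capture_hazard = 3e-4,
                         daughter_penalty_per_hour = 0.22,
                         run_duration = 3600, frame_interval = 10,
                         death_gap = 600) {
  p <- list(lifespan_mean = lifespan_mean, lifespan_sd = lifespan_sd,
            lifespan_family = match.arg(lifespan_family),
            baseline_bti = baseline_bti,
            firstgen_bti_multiplier = firstgen_bti_multiplier,
            terminal_elongation_gens = terminal_elongation_gens,
            terminal_elongation_peak = terminal_elongation_peak,
            desync_cv_growth_per_gen = desync_cv_growth_per_gen,
            overlap_prob = overlap_prob,
            same_frame_handoff_prob = same_frame_handoff_prob,
            initial_occupancy = initial_occupancy,
            refill_coupling = refill_coupling,
            mother_loss_hazard = mother_loss_hazard,
            extra_capture_hazard = extra_capture_hazard,
            daughter_penalty_per_hour = daughter_penalty_per_hour,
            run_duration = run_duration, frame_interval = frame_interval,
            death_gap = death_gap)
  validate_aging_params(p)
  structure(p, class = "aging_params")
}

validate_aging_params <- function(p) {
  num1 <- function(f) {
    v <- p[[f]]
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v))
      stop("field '", f, "' must be a single finite number", call. = FALSE)
    v
  }
  probs <- c("overlap_prob", "same_frame_handoff_prob", "initial_occupancy",
             "refill_coupling", "mother_loss_hazard", "extra_capture_hazard")
  for (f in probs) {
    v <- num1(f)
    if (v < 0 || v > 1)
      stop("field '", f, "' must be a probability in [0, 1]", call. = FALSE)
  }
  for (f in c("lifespan_mean", "baseline_bti", "frame_interval",
              "run_duration", "firstgen_bti_multiplier",
              "terminal_elongation_peak", "death_gap")) {
    if (num1(f) <= 0)
      stop("field '", f, "' must be strictly positive", call. = FALSE)
  }
  for (f in c("lifespan_sd", "desync_cv_growth_per_gen",
              "daughter_penalty_per_hour")) {
    if (num1(f) < 0)
      stop("field '", f, "' must be non-negative", call. = FALSE)
  }
  v <- num1("terminal_elongation_gens")
  if (v < 0 || v != round(v))
    stop("field 'terminal_elongation_gens' must be a non-negative count",
         call. = FALSE)
  if (p$baseline_bti <= p$frame_interval)
    stop("field 'baseline_bti' must exceed 'frame_interval' so budding ",
         "events are resolvable at the sampling rate", call. = FALSE)
  if (p$overlap_prob + p$same_frame_handoff_prob > 1)
    stop("'overlap_prob' + 'same_frame_handoff_prob' must not exceed 1",
         call. = FALSE)
  invisible(p)
}

#' Named trap-geometry hazard profiles
#'
#' Synthetic presets expressing how the bowl length of the trap trades
#' mother retention against extra-cell capture: short bowls (4 um) drop
#' mothers more often, long bowls (6 um) admit extra cells. The numerical
#' hazards are presets mirroring that qualitative trend, not measured rates.
#'
#' @param name One of `"bowl4"`, `"bowl5"`, `"bowl6"`.
#' @param params An `aging_params` to modify (default [aging_params()]).
#' @return `params` with `mother_loss_hazard` and `extra_capture_hazard` set.
#' @export
trap_profile <- function(name = c("bowl5", "bowl4", "bowl6"),
                         params = aging_params()) {
  name <- match.arg(name)
  h <- switch(name,
    bowl4 = c(loss = 1.5e-3, extra = 1e-4),
    bowl5 = c(loss = 3e-4, extra = 3e-4),
    bowl6 = c(loss = 1e-4, extra = 1.5e-3))
  params$mother_loss_hazard <- unname(h["loss"])
  params$extra_capture_hazard <- unname(h["extra"])
  validate_aging_params(params)
  params
}
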
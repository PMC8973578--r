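#' Linear bud-growth model
#'
#' Default observation model for bud size: a bud grows linearly from 1 um at
#' appearance to 4 um at dissection.
#'
#' @param t Frame time(s) in minutes.
#' @param appear,dissect Appearance and dissection time of the bud (min).
#' @return Bud size(s) in um.
#' @export
linear_growth <- function(t, appear, dissect) {
  span <- pmax(dissect - appear, 1e-9)
  1 + 3 * pmin(pmax((t - appear) / span, 0), 1)
}

#' Render the frame-sampled observations of one cell
#'
#' Samples a cell's ground-truth timeline at the imaging interval and emits
#' the object table the event coder consumes: one row per visible object per
#' frame. The mother (5 um) is rendered in every frame until it is lost; a
#' bud is visible in frame f exactly when `appear <= t(f) < dissect`, with
#' size given by `growth_model`; after a contamination event an additional
#' adult-size object is rendered in every frame. Sizes are deterministic
#' given the event times, so downstream size-drop inference is exactly
#' testable.
#'
#' @param truth A [sample_cell_truth()] result.
#' @param params The [aging_params()] used (supplies `frame_interval` and
#'   `run_duration`).
#' @param growth_model Function `(t, appear, dissect) -> size_um`
#'   (default [linear_growth()]).
#' @param mother_size_um Rendered mother size (um).
#' @return A data.frame with columns `trap_id`, `cell_id`, `frame_index`,
#'   `role` (`"mother"`/`"bud"`), `size_um`. Frame indices are global
#'   (frame f is at time `f * frame_interval`).
#' @export
render_observations <- function(truth, params, growth_model = NULL,
                                mother_size_um = 5) {
  stopifnot(inherits(truth, "cell_truth"), inherits(params, "aging_params"))
  if (is.null(growth_model)) growth_model <- linear_growth
  dt <- params$frame_interval
  if (length(truth$appear) &&
      any(truth$dissect - truth$appear <= dt))
    warning("bud maturation no longer than the frame interval; ",
            "same-interval handoff detection may be unreliable")
  end_time <- min(params$run_duration,
                  if (is.na(truth$lost_time)) Inf else truth$lost_time)
  f0 <- as.integer(round(truth$capture_time / dt))
  fend <- as.integer(ceiling(end_time / dt) - 1)
  if (fend < f0) {
    return(data.frame(trap_id = integer(0), cell_id = character(0),
                      frame_index = integer(0), role = character(0),
                      size_um = numeric(0)))
  }
  frames <- f0:fend

  out_f <- frames
  out_role <- rep("mother", length(frames))
  out_size <- rep(mother_size_um, length(frames))

  ng <- length(truth$appear)
  if (ng > 0L) {
    fa <- pmax(as.integer(ceiling(truth$appear / dt)), f0)
    fl <- pmin(as.integer(ceiling(pmin(truth$dissect, end_time) / dt) - 1), fend)
    vis <- fl >= fa
    if (any(vis)) {
      reps <- (fl - fa + 1L)[vis]
      bud_f <- unlist(mapply(seq.int, fa[vis], fl[vis], SIMPLIFY = FALSE),
                      use.names = FALSE)
      ap <- rep(truth$appear[vis], reps)
      di <- rep(truth$dissect[vis], reps)
      out_f <- c(out_f, bud_f)
      out_role <- c(out_role, rep("bud", length(bud_f)))
      out_size <- c(out_size, growth_model(bud_f * dt, ap, di))
    }
  }

  if (!is.na(truth$contaminated_time) && truth$contaminated_time < end_time) {
    fc <- max(as.integer(ceiling(truth$contaminated_time / dt)), f0)
    if (fc <= fend) {
      cf <- fc:fend
      out_f <- c(out_f, cf)
      out_role <- c(out_role, rep("mother", length(cf)))
      out_size <- c(out_size, rep(mother_size_um, length(cf)))
    }
  }

  ord <- order(out_f, out_role, out_size)
  data.frame(trap_id = rep(truth$trap_id, length(out_f)),
             cell_id = rep(truth$cell_id, length(out_f)),
             frame_index = out_f[ord], role = out_role[ord],
             size_um = out_size[ord])
}
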
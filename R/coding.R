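# Sequential two-digit event coding: each transition between consecutive
# frames is summarized by (delta_n, delta_t). delta_n is the net change in
# visible bud count (+1 new bud, -1 daughter dissected, 0 no change);
# delta_t = 1 flags a same-interval handoff, i.e. a dissection and the next
# bud appearance falling between the same pair of frames, inferred from a
# large fractional size drop of the matched bud. The replicative lifespan is
# the total number of 1s among delta_n plus 1s among delta_t.

# TRUE when a bud matched across the two frames shrank by more than `thr`
# (fraction of its previous size). Buds are matched by nearest size, from
# the largest down; when counts differ the smaller side is matched into the
# larger (survivors keep the older bud's identity).
pair_drop <- function(prev_s, cur_s, thr) {
  if (!length(prev_s) || !length(cur_s)) return(FALSE)
  drop <- FALSE
  if (length(cur_s) <= length(prev_s)) {
    avail <- prev_s
    for (cs in sort(cur_s, decreasing = TRUE)) {
      i <- which.min(abs(avail - cs))
      if ((avail[i] - cs) / avail[i] > thr) drop <- TRUE
      avail <- avail[-i]
    }
  } else {
    avail <- cur_s
    for (ps in sort(prev_s, decreasing = TRUE)) {
      i <- which.min(abs(avail - ps))
      if ((ps - avail[i]) / ps > thr) drop <- TRUE
      avail <- avail[-i]
    }
  }
  drop
}

#' Code one frame transition
#'
#' Compares the visible objects of two consecutive frames of the same trap
#' and returns the two-digit code. `delta_n` is the current bud count minus
#' the previous bud count (clamped to -2..2); `delta_t = 1` when the bud
#' counts are equal and positive but the matched bud's size dropped by more
#' than `size_drop_threshold`, indicating that the old bud was removed and a
#' new one appeared within the same inter-frame interval. If the mother is
#' absent from the current frame a mother-loss signal is returned instead of
#' a code.
#'
#' @param prev_objects,cur_objects Data frames with columns `role`
#'   (`"mother"`/`"bud"`) and `size_um` describing the visible objects.
#' @param size_drop_threshold Fractional size decrease that calls a handoff.
#' @return A list of class `two_digit_code` with `delta_n` and `delta_t`,
#'   or a `transition_signal` with `event = "mother_lost"`.
#' @export
code_transition <- function(prev_objects, cur_objects,
                            size_drop_threshold = 0.5) {
  for (o in list(prev_objects, cur_objects))
    if (!is.data.frame(o) || !all(c("role", "size_um") %in% names(o)))
      stop("objects must be data frames with 'role' and 'size_um'")
  if (!any(prev_objects$role == "mother"))
    stop("mother absent in previous frame; transition undefined")
  if (!any(cur_objects$role == "mother"))
    return(structure(list(event = "mother_lost"), class = "transition_signal"))
  pb <- prev_objects$size_um[prev_objects$role == "bud"]
  cb <- cur_objects$size_um[cur_objects$role == "bud"]
  dn <- length(cb) - length(pb)
  if (abs(dn) > 2L) dn <- sign(dn) * 2L
  dt <- 0L
  if (length(pb) > 0L && length(cb) > 0L &&
      pair_drop(pb, cb, size_drop_threshold)) {
    dt <- 1L
    if (length(pb) != length(cb))
      warning("compound transition: net bud-count change with an inferred ",
              "handoff; coding as net delta_n with delta_t = 1")
  }
  structure(list(frame_index = NA_integer_, delta_n = as.integer(dn),
                 delta_t = dt), class = "two_digit_code")
}

#' Encode an observation series into a digital matrix
#'
#' Applies the sequential two-digit coding to a single cell's frame-sampled
#' object table, producing one code per consecutive frame transition. The
#' series terminates as `lost` when the mother vanishes mid-life (if a full
#' death gap of budding-free time preceded the disappearance the record is
#' complete and terminates `death_called` instead), as `contaminated` at the
#' first frame showing three or more buds or a second adult-size object, as
#' `death_called` when no budding event occurred within `death_gap` minutes
#' before the series end, and as `censored` otherwise. A bud already visible
#' in the capture frame is counted as generation 1 through a synthetic
#' leading (1, 0) code when `capture_bud_as_gen1` is TRUE.
#'
#' @param series Data frame with columns `frame_index`, `role`, `size_um`
#'   (one cell; a `cell_id` column is carried through if present).
#' @param frame_interval Minutes between frames.
#' @param size_drop_threshold Fractional size decrease that calls a handoff.
#' @param death_gap Budding-free minutes before series end that call death.
#' @param adult_min_um Minimum size treated as an adult cell when screening
#'   for extra captures.
#' @param capture_bud_as_gen1 Count a bud present at capture as generation 1.
#' @param end_frame Last imaged frame (defaults to the last frame in
#'   `series`; pass the run's final frame so that mother loss and censoring
#'   are assessed against the full imaging window).
#' @return An object of class `digital_matrix`: `cell_id`, `capture_frame`,
#'   `frame_interval`, `codes` (data.frame `frame_index`, `delta_n`,
#'   `delta_t`), `termination`, `termination_frame`.
#' @export
encode_series <- function(series, frame_interval = 10,
                          size_drop_threshold = 0.5, death_gap = 600,
                          adult_min_um = 4.5, capture_bud_as_gen1 = TRUE,
                          end_frame = NULL) {
  if (!is.data.frame(series) || nrow(series) == 0L)
    stop("'series' must be a non-empty data frame of observations")
  need <- c("frame_index", "role", "size_um")
  if (!all(need %in% names(series)))
    stop("'series' must have columns ", paste(need, collapse = ", "))
  if (any(series$frame_index != round(series$frame_index)))
    stop("malformed series: frame indices must be consecutive integers")
  cell_id <- if ("cell_id" %in% names(series)) as.character(series$cell_id[1L])
             else NA_character_
  f0 <- min(series$frame_index)
  fend <- if (is.null(end_frame)) max(series$frame_index)
          else as.integer(end_frame)
  frames <- f0:fend
  nf <- length(frames)
  fi <- series$frame_index - f0 + 1L
  ok <- fi >= 1L & fi <= nf
  fi <- fi[ok]
  role <- series$role[ok]
  size <- series$size_um[ok]

  is_bud <- role == "bud"
  n_bud <- tabulate(fi[is_bud], nbins = nf)
  n_mother <- tabulate(fi[role == "mother"], nbins = nf)
  n_adult <- tabulate(fi[role == "mother" | size >= adult_min_um], nbins = nf)

  # single-bud sizes, vectorized; multi-bud frames handled individually
  s1 <- rep(NA_real_, nf)
  bud_fi <- fi[is_bud]
  bud_s <- size[is_bud]
  one <- n_bud[bud_fi] == 1L
  s1[bud_fi[one]] <- bud_s[one]
  sizes_at <- function(i) {
    if (n_bud[i] == 0L) numeric(0)
    else if (n_bud[i] == 1L) s1[i]
    else bud_s[bud_fi == i]
  }

  first_true <- function(x) if (any(x)) which(x)[1L] else nf + 1L
  lf <- first_true(n_mother == 0L)
  cf <- first_true(n_bud >= 3L | n_adult >= 2L)
  m_last <- min(lf, cf, nf + 1L) - 1L
  if (m_last < 1L)
    stop("series has no usable frames before termination")

  dn <- integer(0)
  dtv <- integer(0)
  code_frames <- integer(0)
  if (m_last >= 2L) {
    prevc <- n_bud[seq_len(m_last - 1L)]
    curc <- n_bud[2:m_last]
    dn <- curc - prevc
    over <- abs(dn) > 2L
    if (any(over)) {
      warning("bud-count change beyond +/-2 in one interval; clamping")
      dn[over] <- sign(dn[over]) * 2L
    }
    dtv <- integer(length(dn))
    eq1 <- which(prevc == 1L & curc == 1L)
    if (length(eq1)) {
      dr <- (s1[eq1] - s1[eq1 + 1L]) / s1[eq1] > size_drop_threshold
      dtv[eq1[dr]] <- 1L
    }
    hard <- which((prevc >= 2L | curc >= 2L) & prevc > 0L & curc > 0L)
    for (i in hard) {
      if (pair_drop(sizes_at(i), sizes_at(i + 1L), size_drop_threshold)) {
        dtv[i] <- 1L
        if (prevc[i] != curc[i])
          warning("compound transition: net bud-count change with an ",
                  "inferred handoff at frame ", frames[i + 1L])
      }
    }
    code_frames <- frames[2:m_last]
  }

  if (capture_bud_as_gen1 && n_bud[1L] > 0L) {
    dn <- c(min(n_bud[1L], 2L), dn)
    dtv <- c(0L, dtv)
    code_frames <- c(f0, code_frames)
  }

  budding <- code_frames[dn == 1L | dtv == 1L]
  last_bud_t <- if (length(budding)) max(budding) * frame_interval
                else f0 * frame_interval
  if (lf <= nf && lf <= cf) {
    t_gone <- frames[lf] * frame_interval
    termination <- if (t_gone - last_bud_t >= death_gap) "death_called"
                   else "lost"
    term_frame <- frames[lf]
  } else if (cf <= nf) {
    termination <- "contaminated"
    term_frame <- frames[cf]
  } else {
    t_end <- frames[m_last] * frame_interval
    termination <- if (t_end - last_bud_t >= death_gap) "death_called"
                   else "censored"
    term_frame <- frames[m_last]
  }

  structure(list(cell_id = cell_id, capture_frame = f0,
                 frame_interval = frame_interval,
                 codes = data.frame(frame_index = as.integer(code_frames),
                                    delta_n = as.integer(dn),
                                    delta_t = as.integer(dtv)),
                 termination = termination,
                 termination_frame = as.integer(term_frame)),
            class = "digital_matrix")
}

#' Encode every cell of an observation table
#'
#' @param obs Long observation table (`trap_id`, `cell_id`, `frame_index`,
#'   `role`, `size_um`).
#' @param frame_interval Minutes between frames.
#' @param end_frame Last imaged frame of the run (passed to
#'   [encode_series()]).
#' @param ... Further arguments to [encode_series()].
#' @return Named list of `digital_matrix` objects, one per cell.
#' @export
encode_observations <- function(obs, frame_interval = 10, end_frame = NULL,
                                ...) {
  stopifnot(is.data.frame(obs), "cell_id" %in% names(obs))
  lapply(split(obs, obs$cell_id), encode_series,
         frame_interval = frame_interval, end_frame = end_frame, ...)
}

#' Termination sidecar of a set of digital matrices
#'
#' @param matrices List of `digital_matrix` objects.
#' @return Data frame `cell_id`, `capture_frame`, `frame_interval`,
#'   `termination`, `termination_frame`.
#' @export
terminations <- function(matrices) {
  out <- do.call(rbind, lapply(matrices, function(m)
    data.frame(cell_id = m$cell_id, capture_frame = m$capture_frame,
               frame_interval = m$frame_interval,
               termination = m$termination,
               termination_frame = m$termination_frame)))
  rownames(out) <- NULL
  out
}

#' Oscillogram of a digital matrix
#'
#' The cumulative-generation staircase: starting at 0 at the capture frame,
#' the level increments by one at every budding event (each `delta_n = 1`
#' and each `delta_t = 1`). Its final level equals the replicative lifespan
#' computed from the same matrix.
#'
#' @param matrix A `digital_matrix`.
#' @return An object of class `oscillogram`: `cell_id` and `steps`
#'   (data.frame `frame_index`, `cumulative_generations`).
#' @export
to_oscillogram <- function(matrix) {
  stopifnot(inherits(matrix, "digital_matrix"))
  cd <- matrix$codes
  events <- (cd$delta_n == 1L) + (cd$delta_t == 1L)
  idx <- which(events > 0L)
  steps <- data.frame(
    frame_index = c(matrix$capture_frame, rep(cd$frame_index[idx],
                                              events[idx])),
    cumulative_generations = c(0L, seq_len(sum(events))))
  structure(list(cell_id = matrix$cell_id, steps = steps),
            class = "oscillogram")
}

#' @export
print.digital_matrix <- function(x, ...) {
  cat("Digital matrix for cell ", x$cell_id, " (capture frame ",
      x$capture_frame, ")\n", sep = "")
  cat("  codes: ", nrow(x$codes), " transitions, RLS = ",
      sum(x$codes$delta_n == 1L) + sum(x$codes$delta_t == 1L),
      ", termination: ", x$termination, "\n", sep = "")
  invisible(x)
}
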
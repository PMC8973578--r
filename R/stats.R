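#' Replicative lifespan from a digital matrix
#'
#' The RLS is the total number of 1s among the delta-n digits plus the
#' number of 1s among the delta-t digits: every new bud and every
#' same-interval handoff counts one generation.
#'
#' @param matrix A `digital_matrix`.
#' @return Integer number of generations.
#' @export
rls_from_matrix <- function(matrix) {
  stopifnot(inherits(matrix, "digital_matrix"))
  sum(matrix$codes$delta_n == 1L) + sum(matrix$codes$delta_t == 1L)
}

#' Budding-event frames of a digital matrix
#'
#' Frames at which a budding event was recorded (`delta_n = 1` or
#' `delta_t = 1`), with multiplicity for compound codes.
#'
#' @param matrix A `digital_matrix`.
#' @return Sorted integer vector of frame indices.
#' @export
budding_frames <- function(matrix) {
  stopifnot(inherits(matrix, "digital_matrix"))
  cd <- matrix$codes
  sort(c(cd$frame_index[cd$delta_n == 1L], cd$frame_index[cd$delta_t == 1L]))
}

#' Budding time intervals from a digital matrix
#'
#' BTI_g is the difference between the frame numbers of budding events g+1
#' and g, multiplied by the frame interval.
#'
#' @param matrix A `digital_matrix`.
#' @param frame_interval Minutes per frame (defaults to the matrix's own).
#' @return Numeric vector of minutes, length `max(RLS - 1, 0)`.
#' @export
btis_from_matrix <- function(matrix, frame_interval = NULL) {
  stopifnot(inherits(matrix, "digital_matrix"))
  if (is.null(frame_interval)) frame_interval <- matrix$frame_interval
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("'frame_interval' must be positive")
  bf <- budding_frames(matrix)
  if (length(bf) < 2L) return(numeric(0))
  diff(bf) * frame_interval
}

#' Per-cell lifespan records from digital matrices
#'
#' @param matrices List of `digital_matrix` objects.
#' @param run_id Identifier of the experimental run.
#' @return Data frame with one row per cell: `cell_id`, `run_id`,
#'   `capture_min`, `rls`, `termination`, `bti0` (capture to first budding,
#'   min) and a list column `btis` of inter-budding intervals.
#' @export
lifespan_records <- function(matrices, run_id = "run1") {
  rows <- lapply(matrices, function(m) {
    bf <- budding_frames(m)
    dt <- m$frame_interval
    data.frame(cell_id = m$cell_id, run_id = run_id,
               capture_min = m$capture_frame * dt,
               rls = length(bf), termination = m$termination,
               bti0 = if (length(bf)) (bf[1L] - m$capture_frame) * dt
                      else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$btis <- lapply(matrices, function(m) btis_from_matrix(m))
  out
}

#' Filter lifespan records by termination policy
#'
#' Cells terminated as lost or contaminated are excluded from cohort
#' statistics by default, as are censored cells (still budding at run end);
#' flags allow sensitivity analyses with them included.
#'
#' @param records A [lifespan_records()] data frame.
#' @param include_censored,include_lost,include_contaminated Inclusion flags.
#' @return The filtered records.
#' @export
clean_records <- function(records, include_censored = FALSE,
                          include_lost = FALSE,
                          include_contaminated = FALSE) {
  keep <- records$termination == "death_called"
  if (include_censored) keep <- keep | records$termination == "censored"
  if (include_lost) keep <- keep | records$termination == "lost"
  if (include_contaminated)
    keep <- keep | records$termination == "contaminated"
  records[keep, , drop = FALSE]
}

#' Viability curve of a cohort
#'
#' Fraction of cells still alive (RLS >= g) at each generation g, starting
#' at 1 for generation 0. Its discrete tail sum over g >= 1 equals the mean
#' RLS of the same cells.
#'
#' @param rls_values Integer vector of lifespans.
#' @return Data frame `generation`, `fraction_alive`.
#' @export
viability_curve <- function(rls_values) {
  if (length(rls_values) == 0L || any(is.na(rls_values)))
    stop("at least one non-missing RLS value is required")
  gens <- 0:max(rls_values)
  frac <- vapply(gens, function(g) mean(rls_values >= g), numeric(1))
  data.frame(generation = gens, fraction_alive = frac)
}

#' Cohort mean RLS and standard error
#'
#' The mean is the grand mean over all cells. Under the `"paper"` (default)
#' convention the standard error is the pooled standard deviation divided by
#' the square root of the number of independent runs; under
#' `"conventional"` it is the pooled SD divided by the square root of the
#' number of cells. Both are returned.
#'
#' @param per_run_rls List of numeric vectors, one per independent run.
#' @param se_definition `"paper"` or `"conventional"`.
#' @return List `mean`, `se`, `se_definition`, `se_paper`,
#'   `se_conventional`, `sd`, `n_cells`, `n_runs`.
#' @export
cohort_mean_se <- function(per_run_rls,
                           se_definition = c("paper", "conventional")) {
  se_definition <- match.arg(se_definition)
  if (!is.list(per_run_rls) || length(per_run_rls) == 0L)
    stop("'per_run_rls' must be a non-empty list of runs")
  pooled <- unlist(per_run_rls, use.names = FALSE)
  if (length(pooled) == 0L) stop("no cells in any run")
  sdev <- stats::sd(pooled)
  n_runs <- length(per_run_rls)
  se_paper <- sdev / sqrt(n_runs)
  se_conv <- sdev / sqrt(length(pooled))
  list(mean = mean(pooled),
       se = if (se_definition == "paper") se_paper else se_conv,
       se_definition = se_definition, se_paper = se_paper,
       se_conventional = se_conv, sd = sdev,
       n_cells = length(pooled), n_runs = n_runs)
}

#' Bin lifespans by capture time
#'
#' Groups cells by the time their mother was captured, in bins of
#' `bin_width` hours, and reports the per-bin mean RLS. Empty bins are
#' skipped.
#'
#' @param records A [lifespan_records()] data frame.
#' @param bin_width Bin width in hours.
#' @return Data frame `bin_start_h`, `bin_end_h`, `midpoint_h`, `n`,
#'   `mean_rls`.
#' @export
bin_by_capture_time <- function(records, bin_width = 2) {
  stopifnot(is.data.frame(records), "capture_min" %in% names(records),
            bin_width > 0)
  if (nrow(records) == 0L) stop("no records to bin")
  h <- records$capture_min / 60
  idx <- floor(h / bin_width)
  agg <- tapply(records$rls, idx, function(x) c(n = length(x),
                                                mean = mean(x)))
  bins <- as.numeric(names(agg))
  out <- data.frame(bin_start_h = bins * bin_width,
                    bin_end_h = (bins + 1) * bin_width,
                    midpoint_h = (bins + 0.5) * bin_width,
                    n = vapply(agg, `[[`, numeric(1), "n"),
                    mean_rls = vapply(agg, `[[`, numeric(1), "mean"))
  rownames(out) <- NULL
  out[order(out$bin_start_h), , drop = FALSE]
}

#' Linear regression of binned mean RLS on capture time
#'
#' Ordinary least squares on (bin midpoint, bin mean RLS) pairs, as plotted
#' in capture-time analyses; slope is in generations per hour.
#'
#' @param per_bin Output of [bin_by_capture_time()].
#' @return Named numeric vector `c(slope, intercept)`.
#' @export
linear_fit <- function(per_bin) {
  stopifnot(is.data.frame(per_bin))
  if (nrow(per_bin) < 2L)
    stop("linear fit requires at least 2 non-empty capture-time bins")
  fit <- stats::lm(mean_rls ~ midpoint_h, data = per_bin)
  co <- stats::coef(fit)
  c(slope = unname(co["midpoint_h"]), intercept = unname(co["(Intercept)"]))
}

# mean BTI at generation g across cells (btis is a list column)
profile_by_generation <- function(btis) {
  maxg <- max(lengths(btis), 0L)
  if (maxg == 0L) return(data.frame(generation = integer(0),
                                    mean_bti = numeric(0), n = integer(0)))
  gens <- seq_len(maxg)
  vals <- lapply(gens, function(g) {
    v <- vapply(btis, function(b) if (length(b) >= g) b[g] else NA_real_,
                numeric(1))
    v[!is.na(v)]
  })
  data.frame(generation = gens,
             mean_bti = vapply(vals, mean, numeric(1)),
             n = lengths(vals))
}

#' Birth-aligned BTI profile and first-generation extension
#'
#' Mean budding time interval per generation index (generation g is the
#' interval between budding events g and g+1), aligned to birth, plus the
#' first-generation extension: the percent by which the mean first-
#' generation BTI exceeds the mean over the comparison generations
#' (default 2..6).
#'
#' @param records A [lifespan_records()] data frame; callers select the
#'   cohort (e.g. newborn cells captured without a bud).
#' @param compare_gens Generations the first generation is compared with.
#' @return List `profile` (data.frame `generation`, `mean_bti`, `n`) and
#'   `extension_pct`.
#' @export
birth_aligned_bti <- function(records, compare_gens = 2:6) {
  stopifnot(is.data.frame(records), "btis" %in% names(records))
  need <- max(compare_gens)
  if (!any(lengths(records$btis) >= need))
    stop("no cell lived long enough (need BTIs through generation ", need,
         ")")
  prof <- profile_by_generation(records$btis)
  ext <- 100 * (prof$mean_bti[prof$generation == 1L] /
                  mean(prof$mean_bti[prof$generation %in% compare_gens]) - 1)
  list(profile = prof, extension_pct = unname(ext))
}

#' Death-aligned BTI profile
#'
#' Mean budding time interval as a function of generations before death:
#' offset 1 is the final inter-budding interval of each cell, offset 2 the
#' one before it, and so on.
#'
#' @param records A [lifespan_records()] data frame.
#' @return Data frame `offset`, `mean_bti`, `n`.
#' @export
death_aligned_bti <- function(records) {
  stopifnot(is.data.frame(records), "btis" %in% names(records))
  btis <- records$btis[lengths(records$btis) >= 1L]
  maxo <- max(lengths(btis), 0L)
  if (maxo == 0L) return(data.frame(offset = integer(0),
                                    mean_bti = numeric(0), n = integer(0)))
  offs <- seq_len(maxo)
  vals <- lapply(offs, function(o) {
    v <- vapply(btis, function(b) {
      m <- length(b)
      if (m >= o) b[m - o + 1L] else NA_real_
    }, numeric(1))
    v[!is.na(v)]
  })
  data.frame(offset = offs, mean_bti = vapply(vals, mean, numeric(1)),
             n = lengths(vals))
}

#' Kymograph matrix of BTIs
#'
#' Cells ordered by RLS (ascending; ties by cell id) in rows, generations in
#' columns, BTI values in minutes with NA padding, plus the 5-generation
#' period label of each column used for cyclic colouring.
#'
#' @param records A [lifespan_records()] data frame.
#' @return List `bti` (matrix, rownames = cell ids), `period`
#'   (integer labels `floor((g-1)/5) %% 5`), `rls` (row order lifespans).
#' @export
kymograph_matrix <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  ord <- order(records$rls, records$cell_id)
  rec <- records[ord, , drop = FALSE]
  maxg <- max(lengths(rec$btis), 1L)
  mat <- t(vapply(rec$btis, function(b) c(b, rep(NA_real_, maxg - length(b))),
                  numeric(maxg)))
  if (maxg == 1L) mat <- matrix(mat, ncol = 1L)
  rownames(mat) <- rec$cell_id
  colnames(mat) <- paste0("g", seq_len(maxg))
  list(bti = mat, period = (floor((seq_len(maxg) - 1L) / 5L)) %% 5L,
       rls = rec$rls)
}

#' Percent decrease of a later mean relative to a reference mean
#'
#' @param reference_mean Reference (earlier) mean; must be positive.
#' @param later_mean Later mean.
#' @return `100 * (reference_mean - later_mean) / reference_mean`.
#' @export
percent_decrease <- function(reference_mean, later_mean) {
  if (!is.numeric(reference_mean) || reference_mean <= 0)
    stop("'reference_mean' must be positive")
  100 * (reference_mean - later_mean) / reference_mean
}

#' Cohort summary of an encoded experiment
#'
#' Assembles the cohort-level statistics: viability curve, mean RLS with
#' both standard-error conventions, capture-time-binned means with a linear
#' fit, birth- and death-aligned BTI profiles with the first-generation
#' extension, and the kymograph matrix.
#'
#' @param records A [lifespan_records()] data frame (possibly spanning
#'   several runs via `run_id`).
#' @param bin_width Capture-time bin width in hours.
#' @param compare_gens Comparison window for the first-generation extension.
#' @param se_definition `"paper"` or `"conventional"` (see
#'   [cohort_mean_se()]).
#' @param include_censored Include censored cells in the statistics.
#' @return An object of class `cohort_summary`.
#' @export
summarize_cohort <- function(records, bin_width = 2, compare_gens = 2:6,
                             se_definition = "paper",
                             include_censored = FALSE) {
  rec <- clean_records(records, include_censored = include_censored)
  if (nrow(rec) == 0L) stop("no cells left after termination filtering")
  per_run <- split(rec$rls, rec$run_id)
  ms <- cohort_mean_se(per_run, se_definition = se_definition)
  per_bin <- bin_by_capture_time(rec, bin_width = bin_width)
  regression <- tryCatch(linear_fit(per_bin),
                         error = function(e) c(slope = NA_real_,
                                               intercept = NA_real_))
  aligned <- tryCatch(birth_aligned_bti(rec, compare_gens = compare_gens),
                      error = function(e)
                        list(profile = profile_by_generation(rec$btis),
                             extension_pct = NA_real_))
  structure(list(n_cells = nrow(rec), n_runs = length(per_run),
                 viability = viability_curve(rec$rls),
                 mean_rls = ms$mean, se_rls = ms$se,
                 se_definition = ms$se_definition, se_paper = ms$se_paper,
                 se_conventional = ms$se_conventional, sd_rls = ms$sd,
                 per_bin = per_bin, regression = regression,
                 birth_aligned_bti = aligned$profile,
                 firstgen_extension_pct = aligned$extension_pct,
                 death_aligned_bti = death_aligned_bti(rec),
                 kymograph = kymograph_matrix(rec)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary: ", x$n_cells, " cells in ", x$n_runs, " run(s)\n",
      sep = "")
  cat(sprintf("  mean RLS %.2f +/- %.2f (%s SE; conventional %.2f)\n",
              x$mean_rls, x$se_rls, x$se_definition, x$se_conventional))
  if (!is.na(x$regression["slope"]))
    cat(sprintf("  capture-time slope %.3f generations/h\n",
                x$regression["slope"]))
  if (!is.na(x$firstgen_extension_pct))
    cat(sprintf("  first-generation BTI extension %.2f%%\n",
                x$firstgen_extension_pct))
  invisible(x)
}
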
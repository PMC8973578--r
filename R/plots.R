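#' Plot a viability curve
#'
#' @param viability Data frame `generation`, `fraction_alive`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot_viability <- function(viability, ...) {
  graphics::plot(viability$generation, viability$fraction_alive, type = "s",
                 xlab = "Generations", ylab = "Fraction alive",
                 ylim = c(0, 1), ...)
}

#' Plot capture-time-binned mean RLS with its linear fit
#'
#' @param per_bin Output of [bin_by_capture_time()].
#' @param regression Named vector `c(slope, intercept)` or NULL.
#' @export
plot_binned_rls <- function(per_bin, regression = NULL) {
  graphics::plot(per_bin$midpoint_h, per_bin$mean_rls, pch = 19,
                 xlab = "Capture time (h)", ylab = "Mean RLS (generations)")
  if (!is.null(regression) && !any(is.na(regression)))
    graphics::abline(a = regression["intercept"], b = regression["slope"],
                     col = "darkblue", lwd = 2)
}

#' Plot birth- and death-aligned BTI profiles
#'
#' @param birth Data frame `generation`, `mean_bti`.
#' @param death Data frame `offset`, `mean_bti`.
#' @export
plot_bti_profiles <- function(birth, death) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(birth$generation, birth$mean_bti, type = "b", pch = 19,
                 xlab = "Generation (from birth)", ylab = "Mean BTI (min)")
  graphics::plot(death$offset, death$mean_bti, type = "b", pch = 19,
                 xlim = rev(range(death$offset)),
                 xlab = "Generations before death", ylab = "Mean BTI (min)")
}

#' Plot a BTI kymograph
#'
#' Cells (ordered by RLS) in rows, generations in columns; BTI rendered as
#' colour intensity cycling through five hues every five generations.
#'
#' @param kymo Output of [kymograph_matrix()].
#' @export
plot_kymograph <- function(kymo) {
  mat <- kymo$bti
  maxg <- ncol(mat)
  n <- nrow(mat)
  hues <- c("#1b9e77", "#d95f02", "#7570b3", "#e7298a", "#66a61e")
  rng <- range(mat, na.rm = TRUE)
  graphics::plot(NA, xlim = c(0.5, maxg + 0.5), ylim = c(0.5, n + 0.5),
                 xlab = "Generation", ylab = "Cells (ordered by RLS)",
                 yaxs = "i", xaxs = "i")
  for (g in seq_len(maxg)) {
    v <- mat[, g]
    ok <- which(!is.na(v))
    if (!length(ok)) next
    base <- hues[kymo$period[g] + 1L]
    alpha <- 0.25 + 0.75 * (v[ok] - rng[1]) / max(rng[2] - rng[1], 1e-9)
    graphics::rect(g - 0.5, ok - 0.5, g + 0.5, ok + 0.5, border = NA,
                   col = vapply(alpha, function(a)
                     grDevices::adjustcolor(base, alpha.f = a),
                     character(1)))
  }
}

#' Write the standard report figures
#'
#' Emits the four figures of a cohort analysis (viability curve, binned RLS
#' with fit, aligned BTI profiles, kymograph) as PDFs in `outdir`.
#'
#' @param summary A [summarize_cohort()] result.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
report_figures <- function(summary, outdir) {
  stopifnot(inherits(summary, "cohort_summary"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(name, code) {
    f <- file.path(outdir, name)
    grDevices::pdf(f, width = 7, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    force(code)
    files <<- c(files, f)
  }
  emit("viability.pdf", plot_viability(summary$viability))
  emit("rls_by_capture.pdf",
       plot_binned_rls(summary$per_bin, summary$regression))
  emit("bti_profiles.pdf",
       plot_bti_profiles(summary$birth_aligned_bti,
                         summary$death_aligned_bti))
  emit("kymograph.pdf", plot_kymograph(summary$kymograph))
  invisible(files)
}
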
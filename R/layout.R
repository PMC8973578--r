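#' Trap-array layout description
#'
#' Geometric description of the "leaky bowl" trap lattice. Defaults describe
#' the full chip: 5 subarrays of 10 rows x 22 columns (1100 traps), 34 um
#' row spacing, 30 um column spacing, alternating columns offset by 17 um so
#' each trap faces the gap between its upstream neighbours, and a 100 um gap
#' between subarrays. Each trap has a 15 x 7 x 8 um outer profile with an
#' 8-um-wide, 5-um-long bowl opening upstream and a 3-um-wide, 2-um-long
#' orifice downstream.
#'
#' @param n_subarrays,rows_per_subarray,cols_per_subarray Array counts.
#' @param row_spacing,col_spacing Distances between adjacent rows/columns (um).
#' @param row_misalignment Offset of alternating columns (um).
#' @param subarray_gap Gap between subarrays (um).
#' @param trap_outer_length,trap_outer_width,trap_height Outer trap profile (um).
#' @param bowl_opening_width,bowl_length Bowl opening dimensions (um).
#' @param orifice_width,orifice_length Downstream orifice dimensions (um).
#' @return An object of class `array_layout`.
#' @examples
#' lay <- array_layout()
#' nrow(build_layout(lay))  # 1100
#' @export
array_layout <- function(n_subarrays = 5L, rows_per_subarray = 10L,
                         cols_per_subarray = 22L, row_spacing = 34,
                         col_spacing = 30, row_misalignment = 17,
                         subarray_gap = 100, trap_outer_length = 15,
                         trap_outer_width = 7, trap_height = 8,
                         bowl_opening_width = 8, bowl_length = 5,
                         orifice_width = 3, orifice_length = 2) {
  lay <- list(n_subarrays = n_subarrays, rows_per_subarray = rows_per_subarray,
              cols_per_subarray = cols_per_subarray, row_spacing = row_spacing,
              col_spacing = col_spacing, row_misalignment = row_misalignment,
              subarray_gap = subarray_gap, trap_outer_length = trap_outer_length,
              trap_outer_width = trap_outer_width, trap_height = trap_height,
              bowl_opening_width = bowl_opening_width, bowl_length = bowl_length,
              orifice_width = orifice_width, orifice_length = orifice_length)
  validate_array_layout(lay)
  structure(lay, class = "array_layout")
}

validate_array_layout <- function(lay) {
  counts <- c("n_subarrays", "rows_per_subarray", "cols_per_subarray")
  for (f in counts) {
    v <- lay[[f]]
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v < 1 ||
        v != round(v))
      stop("field '", f, "' must be a positive integer count", call. = FALSE)
  }
  lengths <- setdiff(names(lay), c(counts, "row_misalignment"))
  for (f in lengths) {
    v <- lay[[f]]
    if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v <= 0)
      stop("field '", f, "' must be a strictly positive length", call. = FALSE)
  }
  v <- lay$row_misalignment
  if (length(v) != 1L || !is.numeric(v) || !is.finite(v) || v < 0)
    stop("field 'row_misalignment' must be a non-negative length", call. = FALSE)
  if (lay$bowl_opening_width <= lay$orifice_width)
    stop("field 'bowl_opening_width' must exceed 'orifice_width'", call. = FALSE)
  invisible(lay)
}

#' Build the trap table for a layout
#'
#' Expands an [array_layout()] into one record per trap with its grid
#' coordinates, physical position and upstream rank. Flow runs along
#' increasing column index, so lower columns are more upstream; the upstream
#' rank is a total order over traps (0 = most upstream) with ties broken by
#' row, then subarray. Alternating columns are shifted by `row_misalignment`
#' so traps face the inter-trap gaps of the neighbouring column.
#'
#' @param layout An `array_layout` (default: the full-chip geometry).
#' @return A data.frame with columns `trap_id`, `subarray`, `row`, `col`,
#'   `x_um`, `y_um`, `upstream_rank`.
#' @export
build_layout <- function(layout = array_layout()) {
  if (!inherits(layout, "array_layout")) {
    if (is.list(layout)) layout <- do.call(array_layout, layout)
    else stop("'layout' must be an array_layout")
  }
  validate_array_layout(layout)
  S <- as.integer(layout$n_subarrays)
  R <- as.integer(layout$rows_per_subarray)
  C <- as.integer(layout$cols_per_subarray)
  n <- S * R * C
  subarray <- rep(seq_len(S), each = R * C)
  row <- rep(rep(seq_len(R), each = C), times = S)
  col <- rep(seq_len(C), times = S * R)
  x <- (col - 1L) * layout$col_spacing
  sub_pitch <- R * layout$row_spacing + layout$subarray_gap
  y <- (row - 1L) * layout$row_spacing +
    ((col - 1L) %% 2L) * layout$row_misalignment +
    (subarray - 1L) * sub_pitch
  rank <- integer(n)
  rank[order(col, row, subarray)] <- seq_len(n) - 1L
  data.frame(trap_id = seq_len(n), subarray = subarray, row = row, col = col,
             x_um = x, y_um = y, upstream_rank = rank)
}
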
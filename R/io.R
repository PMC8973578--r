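# File formats: comma-separated, header row, UTF-8, '.' decimal separator,
# missing values as empty fields; configs and cohort summaries as YAML;
# run manifests as JSON.

write_csv_plain <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

read_csv_plain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default analysis policies
#'
#' @return Named list of the policy switches of the pipeline: whether a bud
#'   present at capture counts as generation 1, whether censored cells enter
#'   cohort statistics, the standard-error definition, the size-drop
#'   threshold of the handoff test and the death gap in minutes.
#' @export
default_policies <- function() {
  list(capture_bud_as_gen1 = TRUE, include_censored = FALSE,
       se_definition = "paper", size_drop_threshold = 0.5, death_gap = 600)
}

#' Load and validate a run configuration
#'
#' A configuration is a YAML document with keys `layout`, `params`, `seed`,
#' `policies` and `outdir`. Unknown keys anywhere are rejected; field
#' invariants are enforced by [array_layout()] and [aging_params()], whose
#' errors name the offending field.
#'
#' @param path Path of the YAML config.
#' @return A list of class `run_config` with elements `layout`
#'   (`array_layout`), `params` (`aging_params`), `seed`, `policies`,
#'   `outdir`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || !is.list(raw)) stop("malformed config: empty document")
  known <- c("layout", "params", "seed", "policies", "outdir")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  lay_args <- raw$layout
  if (!is.null(lay_args)) {
    bad <- setdiff(names(lay_args), names(formals(array_layout)))
    if (length(bad))
      stop("unknown layout field(s): ", paste(bad, collapse = ", "))
  }
  par_args <- raw$params
  if (!is.null(par_args)) {
    bad <- setdiff(names(par_args), names(formals(aging_params)))
    if (length(bad))
      stop("unknown params field(s): ", paste(bad, collapse = ", "))
  }
  pol <- default_policies()
  if (!is.null(raw$policies)) {
    bad <- setdiff(names(raw$policies), names(pol))
    if (length(bad))
      stop("unknown policy field(s): ", paste(bad, collapse = ", "))
    pol[names(raw$policies)] <- raw$policies
  }
  seed <- raw$seed
  if (is.null(seed)) seed <- 1L
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("field 'seed' must be a single integer")
  structure(list(layout = do.call(array_layout, as.list(lay_args)),
                 params = do.call(aging_params, as.list(par_args)),
                 seed = as.integer(seed), policies = pol,
                 outdir = raw$outdir %||% "."),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes a [load_config()]-compatible YAML document; save followed by load
#' round-trips the configuration.
#'
#' @param config A `run_config` (or compatible list).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(is.list(config))
  doc <- list(layout = unclass(config$layout),
              params = unclass(config$params),
              seed = as.integer(config$seed),
              policies = config$policies,
              outdir = config$outdir %||% ".")
  yaml::write_yaml(doc, path)
  invisible(path)
}

# md5 of the canonical YAML serialization of a config
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  unname(tools::md5sum(tmp))
}

#' @rdname table_io
#' @export
write_observations <- function(obs, path) write_csv_plain(obs, path)

#' @rdname table_io
#' @export
read_observations <- function(path) read_csv_plain(path)

#' @rdname table_io
#' @export
write_truth <- function(truth, path) write_csv_plain(truth, path)

#' Table input/output
#'
#' Readers and writers for the pipeline's delimited-text tables:
#' observations (one row per visible object per frame), ground-truth event
#' tables, digital-matrix code tables with their termination sidecar, and
#' per-cell lifespan records (wide table plus a long BTI table).
#'
#' @param obs,truth,matrices,records Objects to write.
#' @param path,codes_path,sidecar_path,records_path,bti_path File paths.
#' @name table_io
#' @return Readers return the parsed object; writers return the path(s)
#'   invisibly.
#' @export
read_truth <- function(path) read_csv_plain(path)

#' @rdname table_io
#' @export
write_matrices <- function(matrices, codes_path, sidecar_path) {
  codes <- do.call(rbind, lapply(matrices, function(m) {
    if (nrow(m$codes) == 0L) return(NULL)
    data.frame(cell_id = m$cell_id, frame_index = m$codes$frame_index,
               delta_n = m$codes$delta_n, delta_t = m$codes$delta_t)
  }))
  if (is.null(codes))
    codes <- data.frame(cell_id = character(0), frame_index = integer(0),
                        delta_n = integer(0), delta_t = integer(0))
  write_csv_plain(codes, codes_path)
  write_csv_plain(terminations(matrices), sidecar_path)
  invisible(c(codes_path, sidecar_path))
}

#' @rdname table_io
#' @export
read_matrices <- function(codes_path, sidecar_path) {
  codes <- read_csv_plain(codes_path)
  side <- read_csv_plain(sidecar_path)
  mats <- lapply(seq_len(nrow(side)), function(i) {
    s <- side[i, ]
    cd <- codes[codes$cell_id == s$cell_id, c("frame_index", "delta_n",
                                              "delta_t")]
    rownames(cd) <- NULL
    structure(list(cell_id = as.character(s$cell_id),
                   capture_frame = as.integer(s$capture_frame),
                   frame_interval = as.numeric(s$frame_interval),
                   codes = cd, termination = as.character(s$termination),
                   termination_frame = as.integer(s$termination_frame)),
              class = "digital_matrix")
  })
  names(mats) <- side$cell_id
  mats
}

#' @rdname table_io
#' @export
write_records <- function(records, records_path, bti_path) {
  flat <- records[, setdiff(names(records), "btis"), drop = FALSE]
  write_csv_plain(flat, records_path)
  long <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    b <- records$btis[[i]]
    if (!length(b)) return(NULL)
    data.frame(cell_id = records$cell_id[i], generation = seq_along(b),
               bti_min = b)
  }))
  if (is.null(long))
    long <- data.frame(cell_id = character(0), generation = integer(0),
                       bti_min = numeric(0))
  write_csv_plain(long, bti_path)
  invisible(c(records_path, bti_path))
}

#' @rdname table_io
#' @export
read_records <- function(records_path, bti_path) {
  flat <- read_csv_plain(records_path)
  long <- read_csv_plain(bti_path)
  flat$btis <- lapply(flat$cell_id, function(id) {
    b <- long[long$cell_id == id, , drop = FALSE]
    b$bti_min[order(b$generation)]
  })
  flat
}

#' Write a run manifest
#'
#' JSON document recording the seed, parameters, layout counts, the config
#' hash and summary counts, so that a run can be reproduced exactly.
#'
#' @param manifest Manifest list (e.g. from a `trap_experiment`).
#' @param path Output path.
#' @param config Optional `run_config`; when given its hash is recorded.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, config = NULL) {
  if (!is.null(config)) manifest$config_md5 <- config_hash(config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a cohort summary as YAML
#'
#' @param summary A `cohort_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  doc <- list(n_cells = summary$n_cells, n_runs = summary$n_runs,
              mean_rls = summary$mean_rls, se_rls = summary$se_rls,
              se_definition = summary$se_definition,
              se_paper = summary$se_paper,
              se_conventional = summary$se_conventional,
              sd_rls = summary$sd_rls,
              regression = as.list(summary$regression),
              firstgen_extension_pct = summary$firstgen_extension_pct,
              viability = as.list(summary$viability),
              per_bin = as.list(summary$per_bin),
              birth_aligned_bti = as.list(summary$birth_aligned_bti),
              death_aligned_bti = as.list(summary$death_aligned_bti))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Synthetic reconstruction of a 23-generation digital matrix
#'
#' Loads the digital matrix shipped with the package in
#' `extdata/representative_matrix_synthetic.csv`: a synthetic, hand-built
#' code sequence for a cell that completes 23 generations over roughly 37
#' hours, with the canonical event motifs (bud-free gaps, one overlap and
#' one same-interval handoff) and terminal BTI elongation. It is a
#' constructed reference object for demonstrating and testing the coding
#' arithmetic, not recorded data.
#'
#' @return A `digital_matrix`.
#' @export
representative_matrix <- function() {
  codes <- system.file("extdata", "representative_matrix_synthetic.csv",
                       package = "traplife", mustWork = TRUE)
  side <- system.file("extdata",
                      "representative_matrix_synthetic_sidecar.csv",
                      package = "traplife", mustWork = TRUE)
  read_matrices(codes, side)[[1L]]
}
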
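# Plain-text and binary-container IO for the pipeline's artefacts.

#' Write / read a node x node matrix as CSV with node ids as header
#'
#' @param mat numeric matrix with node-id dimnames.
#' @param path file path.
#' @return `read_matrix_csv` returns the matrix with dimnames restored.
#' @export
write_matrix_csv <- function(mat, path) {
  utils::write.csv(as.data.frame(mat), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  as.matrix(d)
}

#' Write / read a cohort roster as CSV
#'
#' @param design a [make_design()] roster.
#' @param path file path.
#' @export
write_design_csv <- function(design, path) {
  utils::write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$group <- factor(d$group, levels = c("control", "bd"))
  d$sex <- factor(d$sex, levels = c("F", "M"))
  attr(d, "sessions") <- c("pre", "post")
  class(d) <- c("cohort_design", "data.frame")
  d
}

#' Save / load a trial set as a chunked binary container
#'
#' The array is stored as little-endian doubles (one chunk per trial) next
#' to a JSON sidecar holding the dimensions, sampling rate, node ids and
#' other metadata.
#'
#' @param trials a [trial_set()].
#' @param dir directory to create the container in (`data.bin` +
#'   `meta.json`).
#' @return `read_trial_set` returns the reconstructed [trial_set()].
#' @export
write_trial_set <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(dim = dim(trials$data), fs = trials$fs,
               subject_id = trials$subject_id, session = trials$session,
               band = if (is.null(trials$band)) NULL else unclass(trials$band),
               kind = trials$kind, node_ids = trials$node_ids,
               storage = "float64-little-endian, trial-major chunks")
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  con <- file(file.path(dir, "data.bin"), "wb")
  on.exit(close(con))
  for (k in seq_len(dim(trials$data)[1])) {
    writeBin(as.numeric(trials$data[k, , ]), con, size = 8, endian = "little")
  }
  invisible(dir)
}

#' @rdname write_trial_set
#' @export
read_trial_set <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  dm <- as.integer(meta$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  on.exit(close(con))
  data <- array(0, dim = dm)
  for (k in seq_len(dm[1])) {
    data[k, , ] <- readBin(con, "numeric", n = dm[2] * dm[3], size = 8,
                           endian = "little")
  }
  band <- if (is.null(meta$band)) NULL else {
    band_spec(meta$band$name, meta$band$f_lo, meta$band$f_hi)
  }
  trial_set(data, fs = meta$fs, subject_id = meta$subject_id,
            session = meta$session, band = band, kind = meta$kind,
            node_ids = meta$node_ids)
}

#' Write / read a run configuration as YAML
#'
#' Band edges, thresholds, permutation counts and seeds round-trip through
#' the YAML representation unchanged.
#'
#' @param config a [run_config()] list.
#' @param path file path.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}
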
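# Manifest-driven ingestion of heterogeneous repository traces.
#
# Public fall repositories store traces as delimited text with wildly
# different dialects, units (ADC counts, g, m/s^2) and labelling schemes.
# A dataset manifest declares, once per repository, how to turn those files
# into canonical inertial traces: delimiter, which columns are the x/y/z
# axes, the multiplicative raw -> m/s^2 unit scale, the nominal sampling
# rate, and filename rules assigning the ADL/FALL label. No resampling is
# ever applied: samples pass through in file order at the nominal rate.

#' Construct a dataset manifest programmatically
#'
#' @param dataset_id short identifier for the repository.
#' @param fs_nominal nominal sampling rate in Hz (> 0). Jittery recordings
#'   are still treated as sampled at this constant nominal rate; timestamps
#'   in the files are ignored.
#' @param unit_scale multiplicative factor converting stored raw values to
#'   m/s^2 (> 0); e.g. `9.80665` for files stored in g.
#' @param axis_columns length-3 named list/vector (`x`, `y`, `z`) giving the
#'   file columns holding each axis, as column names or 1-based indices.
#' @param label_rule named list mapping regular expressions (matched against
#'   the trace file's basename) to `"ADL"`/`"FALL"`. Every trace must resolve
#'   to exactly one label.
#' @param trace_glob wildcard pattern selecting trace files, relative to
#'   `dir`.
#' @param delimiter field separator: `","`, `";"`, `"\t"`, or `"whitespace"`.
#' @param header whether trace files carry a header row.
#' @param dir directory the glob is resolved against.
#' @return an object of class `dataset_manifest`.
#' @seealso [read_manifest()], [read_trace()], [read_dataset()]
#' @export
dataset_manifest <- function(dataset_id, fs_nominal, unit_scale = 1.0,
                             axis_columns = list(x = "ax", y = "ay", z = "az"),
                             label_rule = list("^ADL" = "ADL", "^FALL" = "FALL"),
                             trace_glob = "*.csv", delimiter = ",",
                             header = TRUE, dir = ".") {
  m <- structure(list(dataset_id = as.character(dataset_id),
                      fs_nominal = fs_nominal, unit_scale = unit_scale,
                      axis_columns = as.list(axis_columns),
                      label_rule = as.list(label_rule),
                      trace_glob = as.character(trace_glob),
                      delimiter = as.character(delimiter),
                      header = isTRUE(header), dir = as.character(dir)),
                 class = "dataset_manifest")
  validate_manifest(m)
}

validate_manifest <- function(m) {
  required <- c("dataset_id", "fs_nominal", "unit_scale", "axis_columns",
                "label_rule", "trace_glob")
  for (f in required)
    if (is.null(m[[f]]))
      stop_fallcnn(sprintf("manifest is missing required field `%s`", f),
                   "fallcnn_manifest_error")
  if (!is.numeric(m$fs_nominal) || length(m$fs_nominal) != 1L ||
      !is.finite(m$fs_nominal) || m$fs_nominal <= 0)
    stop_fallcnn("manifest field `fs_nominal` must be a positive rate in Hz",
                 "fallcnn_manifest_error")
  if (!is.numeric(m$unit_scale) || length(m$unit_scale) != 1L ||
      !is.finite(m$unit_scale) || m$unit_scale <= 0)
    stop_fallcnn("manifest field `unit_scale` must be a positive factor",
                 "fallcnn_manifest_error")
  ax <- m$axis_columns
  if (length(ax) != 3L || !all(c("x", "y", "z") %in% names(ax)))
    stop_fallcnn("manifest field `axis_columns` must name columns x, y and z",
                 "fallcnn_manifest_error")
  if (anyDuplicated(unlist(ax, use.names = FALSE)))
    stop_fallcnn("manifest field `axis_columns` must name three distinct columns",
                 "fallcnn_manifest_error")
  lr <- m$label_rule
  if (length(lr) == 0L || is.null(names(lr)) || any(!nzchar(names(lr))))
    stop_fallcnn("manifest field `label_rule` must map patterns to labels",
                 "fallcnn_manifest_error")
  bad <- !unlist(lr, use.names = FALSE) %in% c("ADL", "FALL")
  if (any(bad))
    stop_fallcnn("manifest `label_rule` labels must be \"ADL\" or \"FALL\"",
                 "fallcnn_manifest_error")
  m$delimiter <- m$delimiter %||% ","
  m$header <- m$header %||% TRUE
  m$dir <- m$dir %||% "."
  m
}

#' Read and validate a dataset manifest file
#'
#' Manifests are YAML (`.yml`/`.yaml`) or JSON documents with the fields of
#' [dataset_manifest()]. Relative `trace_glob` patterns resolve against the
#' manifest's own directory.
#'
#' @param path path to the manifest file.
#' @return a validated `dataset_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_fallcnn(sprintf("manifest file not found: %s", path),
                 "fallcnn_manifest_error")
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$dir <- dirname(path)
  m <- structure(raw[c("dataset_id", "fs_nominal", "unit_scale",
                       "axis_columns", "label_rule", "trace_glob",
                       "delimiter", "header", "dir")],
                 class = "dataset_manifest")
  names(m) <- c("dataset_id", "fs_nominal", "unit_scale", "axis_columns",
                "label_rule", "trace_glob", "delimiter", "header", "dir")
  m$axis_columns <- as.list(m$axis_columns)
  m$label_rule <- as.list(m$label_rule)
  validate_manifest(m)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %s: fs %g Hz, unit_scale %g, glob '%s'\n",
              x$dataset_id, x$fs_nominal, x$unit_scale, x$trace_glob))
  invisible(x)
}

#' Resolve the ADL/FALL label of a trace file under a manifest
#'
#' Applies the manifest's `label_rule` patterns to the file's basename.
#' Exactly one label must result; conflicting matches are an error, and a
#' file matching no rule falls back to its JSON sidecar (if one exists).
#'
#' @param manifest a `dataset_manifest`.
#' @param path trace file path.
#' @return `"ADL"` or `"FALL"`.
#' @export
resolve_label <- function(manifest, path) {
  base <- basename(path)
  pats <- names(manifest$label_rule)
  hit <- vapply(pats, function(p) grepl(p, base), logical(1))
  labs <- unique(unlist(manifest$label_rule[hit], use.names = FALSE))
  if (length(labs) > 1L)
    stop_fallcnn(sprintf("label rules assign conflicting labels to '%s'", base),
                 "fallcnn_label_error")
  if (length(labs) == 1L) return(labs)
  side <- sidecar_path(path)
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    if (!is.null(meta$label) && meta$label %in% c("ADL", "FALL"))
      return(meta$label)
  }
  stop_fallcnn(sprintf("no label rule matches trace file '%s'", base),
               "fallcnn_label_error")
}

sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

manifest_sep <- function(manifest) {
  if (identical(manifest$delimiter, "whitespace")) "" else manifest$delimiter
}

#' Read one delimited trace file into a canonical inertial trace
#'
#' Values are taken in file order, multiplied by the manifest's `unit_scale`
#' to obtain m/s^2, and stamped with the manifest's nominal sampling rate.
#' No resampling, filtering or detrending is performed.
#'
#' @param path trace file path.
#' @param manifest the `dataset_manifest` describing the file dialect.
#' @return an [inertial_trace].
#' @export
read_trace <- function(path, manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  if (!file.exists(path))
    stop_fallcnn(sprintf("trace file not found: %s", path), "fallcnn_io_error")
  df <- tryCatch(
    utils::read.table(path, sep = manifest_sep(manifest),
                      header = manifest$header, colClasses = "character",
                      comment.char = "", strip.white = TRUE,
                      stringsAsFactors = FALSE),
    error = function(e)
      stop_fallcnn(sprintf("cannot parse '%s': %s", path, conditionMessage(e)),
                   "fallcnn_io_error"))
  if (nrow(df) == 0L)
    stop_fallcnn(sprintf("trace file '%s' contains no samples", path),
                 "fallcnn_empty_trace")
  cols <- lapply(manifest$axis_columns[c("x", "y", "z")], function(col) {
    col_id <- if (is.character(col) && !col %in% names(df) &&
                  !is.na(suppressWarnings(as.integer(col)))) as.integer(col)
              else col
    if (is.numeric(col_id)) {
      if (col_id < 1 || col_id > ncol(df))
        stop_fallcnn(sprintf("column index %d out of range in '%s' (%d columns)",
                             col_id, path, ncol(df)), "fallcnn_format_error")
      df[[col_id]]
    } else {
      if (!col_id %in% names(df))
        stop_fallcnn(sprintf("column '%s' missing from '%s'", col_id, path),
                     "fallcnn_format_error")
      df[[col_id]]
    }
  })
  mat <- vapply(cols, function(v) {
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(num))
    if (length(bad) > 0L)
      stop_fallcnn(sprintf("non-numeric cell in '%s' at data row %d ('%s')",
                           path, bad[1], v[bad[1]]), "fallcnn_parse_error")
    num
  }, numeric(nrow(df)))
  if (nrow(df) == 1L) mat <- matrix(mat, nrow = 1L)
  meta <- list()
  side <- sidecar_path(path)
  if (file.exists(side)) meta <- jsonlite::fromJSON(side)
  inertial_trace(mat * manifest$unit_scale, fs = manifest$fs_nominal,
                 label = resolve_label(manifest, path),
                 subject_id = meta$subject_id %||% "",
                 activity_code = meta$activity_code %||% "",
                 dataset_id = manifest$dataset_id)
}

#' Write a trace to the canonical on-disk form
#'
#' Writes a comma-delimited file with header `ax,ay,az` (m/s^2, 12
#' significant digits) plus a JSON sidecar `<stem>.meta.json` holding the
#' label, sampling rate and provenance strings. Reading the file back with
#' an identity manifest (`unit_scale = 1`) reproduces the trace to text
#' round-trip precision.
#'
#' @param trace an [inertial_trace].
#' @param path output file path (conventionally `.csv`).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "inertial_trace"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  rows <- sprintf("%.12g,%.12g,%.12g",
                  trace$samples[, 1], trace$samples[, 2], trace$samples[, 3])
  writeLines(c("ax,ay,az", rows), con = con, sep = "\n")
  jsonlite::write_json(
    list(dataset_id = trace$dataset_id, subject_id = trace$subject_id,
         activity_code = trace$activity_code, label = trace$label,
         fs = trace$fs),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read every trace a manifest resolves
#'
#' @param manifest a `dataset_manifest` (typically from [read_manifest()]).
#' @return list of [inertial_trace] objects, in sorted file order.
#' @export
read_dataset <- function(manifest) {
  stopifnot(inherits(manifest, "dataset_manifest"))
  files <- sort(Sys.glob(file.path(manifest$dir, manifest$trace_glob)))
  files <- files[!grepl("\\.meta\\.json$", files)]
  if (length(files) == 0L)
    stop_fallcnn(sprintf("manifest glob '%s' matches no files under '%s'",
                         manifest$trace_glob, manifest$dir),
                 "fallcnn_io_error")
  lapply(files, read_trace, manifest = manifest)
}
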
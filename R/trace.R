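#' Canonical representation of one recorded movement
#'
#' An inertial trace holds the triaxial acceleration samples of a single
#' recorded movement (one ADL or one fall), already converted to m/s^2,
#' together with its sampling rate and label. It is the unit of data every
#' other function in the package consumes.
#'
#' @param samples numeric matrix with N >= 1 rows and 3 columns
#'   (x, y, z acceleration in m/s^2); all values must be finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @param label `"ADL"` or `"FALL"`.
#' @param subject_id,activity_code,dataset_id opaque provenance strings.
#' @param segments optional named list of index ranges annotating generated
#'   traces (used by the synthetic generator to mark free-fall/impact spans).
#' @return an object of class `inertial_trace`: a list with elements
#'   `samples`, `fs`, `label`, `subject_id`, `activity_code`, `dataset_id`.
#' @examples
#' tr <- inertial_trace(matrix(c(0, 0, 9.81), 1, 3), fs = 200, label = "ADL")
#' n_samples(tr)
#' @export
inertial_trace <- function(samples, fs, label,
                           subject_id = "", activity_code = "",
                           dataset_id = "", segments = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || ncol(samples) != 3L || nrow(samples) < 1L)
    stop_fallcnn("`samples` must be a numeric matrix with >= 1 rows and 3 columns",
                 "fallcnn_invalid_trace")
  if (!all(is.finite(samples)))
    stop_fallcnn("trace contains non-finite acceleration values",
                 "fallcnn_invalid_trace")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_fallcnn("`fs` must be a positive sampling rate in Hz",
                 "fallcnn_invalid_trace")
  label <- as.character(label)
  if (length(label) != 1L || !label %in% c("ADL", "FALL"))
    stop_fallcnn("`label` must be exactly one of \"ADL\" or \"FALL\"",
                 "fallcnn_invalid_trace")
  colnames(samples) <- c("ax", "ay", "az")
  structure(list(samples = samples, fs = as.numeric(fs), label = label,
                 subject_id = as.character(subject_id),
                 activity_code = as.character(activity_code),
                 dataset_id = as.character(dataset_id),
                 segments = segments),
            class = "inertial_trace")
}

#' Number of samples in a trace
#' @param trace an [inertial_trace].
#' @return integer sample count N.
#' @export
n_samples <- function(trace) {
  stopifnot(inherits(trace, "inertial_trace"))
  nrow(trace$samples)
}

#' @export
print.inertial_trace <- function(x, ...) {
  cat(sprintf("<inertial_trace> %s: %d samples @ %g Hz (%.2f s)%s\n",
              x$label, n_samples(x), x$fs, n_samples(x) / x$fs,
              if (nzchar(x$dataset_id)) paste0(" [", x$dataset_id, "]") else ""))
  invisible(x)
}

# factor with the fixed global class order; FALL is the positive class.
trace_labels <- function(traces) {
  factor(vapply(traces, `[[`, character(1), "label"),
         levels = c("ADL", "FALL"))
}
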
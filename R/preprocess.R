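# Observation-window extraction.
#
# The classifier never sees a whole trace: each movement is reduced to a
# fixed-duration window centered on the global peak of the acceleration
# magnitude, on the premise that if the movement contains a fall, the fall
# happened around that peak (free-fall dip, impact spike, orientation
# change all lie within a few seconds of it).

#' Signal magnitude vector (SMV) of a trace
#'
#' Per-sample Euclidean norm of the three acceleration components,
#' `sqrt(ax^2 + ay^2 + az^2)`, in m/s^2.
#'
#' @param trace an [inertial_trace], or an N x 3 numeric matrix.
#' @return numeric vector of length N, all elements >= 0.
#' @examples
#' compute_smv(matrix(c(3, 4, 0), 1, 3))  # 5
#' @export
compute_smv <- function(trace) {
  samples <- if (inherits(trace, "inertial_trace")) trace$samples
             else as.matrix(trace)
  stopifnot(is.numeric(samples), ncol(samples) == 3L)
  sqrt(rowSums(samples^2))
}

#' Locate the acceleration peak of an SMV series
#'
#' @param smv non-empty numeric vector of magnitudes.
#' @return list with `index` (1-based position of the maximum; ties broken
#'   by the earliest index) and `value` (the maximum itself).
#' @export
locate_peak <- function(smv) {
  if (length(smv) == 0L)
    stop_fallcnn("cannot locate the peak of an empty magnitude series",
                 "fallcnn_empty_trace")
  if (!all(is.finite(smv)))
    stop_fallcnn("magnitude series contains non-finite values",
                 "fallcnn_invalid_trace")
  i <- which.max(smv)  # earliest index on ties
  list(index = as.integer(i), value = smv[i])
}

#' Feature count of an observation window
#'
#' Per-axis sample count is `2 * floor(half_width_s * fs) + 1` (symmetric,
#' peak-inclusive); the TRIAXIAL variant concatenates three axis blocks. At
#' 200 Hz with a +/-2.5 s half-width this gives 1001 (SMV) and 3003
#' (TRIAXIAL) input features.
#'
#' @param half_width_s window half-width in seconds.
#' @param fs sampling rate in Hz.
#' @param variant `"SMV"` or `"TRIAXIAL"`.
#' @return integer feature count.
#' @export
window_width <- function(half_width_s, fs, variant = c("SMV", "TRIAXIAL")) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(half_width_s), half_width_s > 0, is.numeric(fs), fs > 0)
  n <- 2L * as.integer(floor(half_width_s * fs)) + 1L
  if (variant == "TRIAXIAL") 3L * n else n
}

#' Extract the peak-centered observation window from a trace
#'
#' Centers a window of `2 * floor(half_width_s * fs) + 1` samples per axis on
#' the SMV peak of the trace. When the centered span would overrun either
#' trace boundary, the edge sample is replicated to fill the window (zero
#' filling would mimic a free-fall signature). The SMV variant carries the
#' magnitude series; the TRIAXIAL variant concatenates the three per-axis
#' segments as contiguous blocks `[x | y | z]`.
#'
#' @param trace an [inertial_trace].
#' @param half_width_s half-width in seconds; the benchmark protocol uses
#'   0.5, 1.0, 1.5 and 2.5 s but any positive value is accepted.
#' @param variant `"SMV"` or `"TRIAXIAL"`.
#' @return an object of class `observation_window`: list with `values`,
#'   `variant`, `half_width_s`, `fs`, `peak_index` (1-based), `width`
#'   (total feature count) and `n_per_axis`.
#' @section Errors: if the per-axis window is longer than the trace the
#'   configuration is inapplicable and an error of class
#'   `fallcnn_window_too_long` is raised; the benchmark runner converts it
#'   into a skipped grid cell.
#' @export
extract_window <- function(trace, half_width_s, variant = c("SMV", "TRIAXIAL")) {
  stopifnot(inherits(trace, "inertial_trace"))
  variant <- match.arg(variant)
  n_axis <- 2L * as.integer(floor(half_width_s * trace$fs)) + 1L
  N <- n_samples(trace)
  if (n_axis > N)
    stop_fallcnn(sprintf(
      "window of %d samples (half-width %g s at %g Hz) exceeds trace length %d",
      n_axis, half_width_s, trace$fs, N), "fallcnn_window_too_long")
  smv <- compute_smv(trace)
  peak <- locate_peak(smv)
  h <- (n_axis - 1L) %/% 2L
  idx <- pmin(pmax(seq.int(peak$index - h, peak$index + h), 1L), N)
  values <- switch(variant,
    SMV = smv[idx],
    TRIAXIAL = c(trace$samples[idx, 1], trace$samples[idx, 2],
                 trace$samples[idx, 3]))
  structure(list(values = values, variant = variant,
                 half_width_s = half_width_s, fs = trace$fs,
                 peak_index = peak$index, width = length(values),
                 n_per_axis = n_axis),
            class = "observation_window")
}

#' @export
print.observation_window <- function(x, ...) {
  cat(sprintf("<observation_window> %s: %d features (+/-%g s @ %g Hz, peak at %d)\n",
              x$variant, x$width, x$half_width_s, x$fs, x$peak_index))
  invisible(x)
}

#' Build the window matrix of a trace collection
#'
#' Extracts the same window configuration from every trace and stacks the
#' results as classifier input. All traces must share one sampling rate
#' (traces are never resampled, so mixed rates give mixed widths).
#'
#' @param traces list of [inertial_trace] objects with identical `fs`.
#' @inheritParams extract_window
#' @return list with `x` (n_traces x width numeric matrix), `labels`
#'   (factor with levels ADL, FALL), `width`, `variant`, `half_width_s`,
#'   `fs`.
#' @export
windows_from_traces <- function(traces, half_width_s,
                                variant = c("SMV", "TRIAXIAL")) {
  variant <- match.arg(variant)
  stopifnot(length(traces) >= 1L)
  fs <- unique(vapply(traces, `[[`, numeric(1), "fs"))
  if (length(fs) != 1L)
    stop_fallcnn("all traces must share one sampling rate; split by dataset first",
                 "fallcnn_invalid_trace")
  wins <- lapply(traces, extract_window, half_width_s = half_width_s,
                 variant = variant)
  x <- do.call(rbind, lapply(wins, `[[`, "values"))
  list(x = x, labels = trace_labels(traces), width = ncol(x),
       variant = variant, half_width_s = half_width_s, fs = fs)
}
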
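# Synthetic accelerometer traces.
#
# Emulates the statistical structure the detector relies on, so the whole
# pipeline is testable without downloading any public repository:
#  - ADLs: periodic locomotion (gait) around 1 g, or a smooth
#    postural-transition bump; magnitude stays well away from both the
#    free-fall floor and fall-impact levels.
#  - Falls: walking prefix, a free-fall dip (magnitude near zero), a sharp
#    impact spike that is the trace's global magnitude maximum, and a
#    post-impact rest phase at 1 g with a rotated static orientation.
# Gaussian noise, independent per axis, is added throughout.

#' Configuration of the synthetic trace generator
#'
#' Defaults emulate a SisFall-like waist-worn recording: 200 Hz sampling,
#' 12 s movements, impacts averaging 4 g against an ADL regime that never
#' exceeds ~2 g, free-fall dipping to 0.2 g for 0.4 s, 2 Hz gait, and
#' 0.05 g sensor noise. `hard = TRUE` narrows the class margin (impact
#' 1.8 g, noise 0.15 g) to exercise imperfect-classifier code paths.
#'
#' @param fs sampling rate in Hz.
#' @param duration_s trace duration in seconds; fall traces need at least
#'   `2 * 2.5 + freefall_duration_s + 0.2` s so every benchmark window size
#'   applies.
#' @param n_adl,n_fall trace counts per class for [generate_dataset()].
#' @param impact_peak_g mean impact magnitude (g).
#' @param freefall_floor_g mean magnitude during free fall (g); < 1.
#' @param freefall_duration_s free-fall duration (s).
#' @param gait_frequency_hz locomotion periodicity (Hz).
#' @param noise_sd_g per-axis additive Gaussian noise SD (g).
#' @param seed master seed; per-trace seeds are derived from it.
#' @param hard narrow the class margins (see above).
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(fs = 200, duration_s = 12, n_adl = 60L,
                             n_fall = 40L, impact_peak_g = 4.0,
                             freefall_floor_g = 0.2,
                             freefall_duration_s = 0.4,
                             gait_frequency_hz = 2.0, noise_sd_g = 0.05,
                             seed = 1L, hard = FALSE) {
  if (isTRUE(hard)) {
    if (missing(impact_peak_g)) impact_peak_g <- 1.8
    if (missing(noise_sd_g)) noise_sd_g <- 0.15
  }
  if (!(impact_peak_g > 1 && 1 > freefall_floor_g && freefall_floor_g >= 0))
    stop_fallcnn("need impact_peak_g > 1 > freefall_floor_g >= 0",
                 "fallcnn_config_error")
  if (fs <= 0 || duration_s <= 0 || freefall_duration_s <= 0 ||
      gait_frequency_hz <= 0)
    stop_fallcnn("rates and durations must be positive", "fallcnn_config_error")
  if (n_adl < 0L || n_fall < 0L)
    stop_fallcnn("class counts must be >= 0", "fallcnn_config_error")
  structure(list(fs = fs, duration_s = duration_s,
                 n_adl = as.integer(n_adl), n_fall = as.integer(n_fall),
                 impact_peak_g = impact_peak_g,
                 freefall_floor_g = freefall_floor_g,
                 freefall_duration_s = freefall_duration_s,
                 gait_frequency_hz = gait_frequency_hz,
                 noise_sd_g = noise_sd_g, seed = as.integer(seed),
                 hard = isTRUE(hard)),
            class = "synthetic_config")
}

# Random unit vector near the +z axis (sensor roughly upright on the waist).
random_orientation <- function(tilt_sd = 0.15) {
  v <- c(stats::rnorm(2, 0, tilt_sd), 1)
  v / sqrt(sum(v^2))
}

# Rotate unit vector u by `angle` radians about a random axis (Rodrigues).
rotate_orientation <- function(u, angle) {
  k <- stats::rnorm(3)
  k <- k - sum(k * u) * u          # axis orthogonal to u for a full swing
  k <- k / sqrt(sum(k^2))
  u * cos(angle) + pracma_cross(k, u) * sin(angle)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Gait segment: gravity along u modulated by a fundamental + first harmonic,
# plus a small perpendicular sway. Returns an n x 3 matrix in m/s^2 (no noise).
gait_segment <- function(n, fs, u, gait_hz, amplitude, phase) {
  t <- (seq_len(n) - 1) / fs
  mod <- 1 + amplitude * sin(2 * pi * gait_hz * t + phase) +
    0.3 * amplitude * sin(4 * pi * gait_hz * t + 2 * phase)
  perp <- rotate_orientation(u, pi / 2)
  sway <- 0.4 * amplitude * sin(2 * pi * gait_hz * t + phase + pi / 3)
  GRAVITY * (outer(mod, u) + outer(sway, perp))
}

#' Generate one synthetic ADL trace
#'
#' Either periodic walking at the configured gait frequency or a
#' postural-transition bump, superposed on 1 g gravity with per-axis noise.
#' The magnitude stays inside (0.3 g, 0.75 * impact_peak_g) and no 0.2 s
#' stretch dips below 0.5 g, so ADLs never carry a free-fall signature.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer seed for this trace.
#' @param kind `"auto"` (random mix), `"walk"` or `"transition"`.
#' @return an [inertial_trace] with label ADL.
#' @export
generate_adl_trace <- function(cfg, seed = cfg$seed, kind = c("auto", "walk", "transition")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  kind <- match.arg(kind)
  with_seed(seed, {
    n <- max(2L, round(cfg$duration_s * cfg$fs))
    t <- (seq_len(n) - 1) / cfg$fs
    u <- random_orientation()
    if (kind == "auto") kind <- if (stats::runif(1) < 0.7) "walk" else "transition"
    base <- if (kind == "walk") {
      gait_segment(n, cfg$fs, u, cfg$gait_frequency_hz,
                   amplitude = stats::runif(1, 0.2, 0.35),
                   phase = stats::runif(1, 0, 2 * pi))
    } else {
      d <- random_orientation(0.8)
      t0 <- stats::runif(1, 0.25, 0.75) * cfg$duration_s
      bump <- stats::runif(1, 0.3, 0.6) * exp(-(t - t0)^2 / (2 * 0.35^2))
      GRAVITY * (outer(rep(1, n), u) + outer(bump, d))
    }
    noise <- matrix(stats::rnorm(3L * n, 0, cfg$noise_sd_g * GRAVITY), n, 3)
    inertial_trace(base + noise, fs = cfg$fs, label = "ADL",
                   activity_code = toupper(kind), dataset_id = "synthetic")
  })
}

#' Generate one synthetic fall trace
#'
#' Walking prefix, a free-fall dip of `freefall_duration_s` whose magnitude
#' hovers near `freefall_floor_g`, an impact spike scaled so the trace's
#' global magnitude maximum lies inside it, and post-impact rest at 1 g
#' with a rotated orientation. The drawn impact magnitude is Normal around
#' `impact_peak_g` (SD 10%, truncated at +/-3 SD) and never below 1.06x the
#' largest magnitude elsewhere in the trace.
#'
#' @inheritParams generate_adl_trace
#' @return an [inertial_trace] with label FALL; `$segments` records the
#'   1-based index ranges of the `freefall` and `impact` phases.
#' @export
generate_fall_trace <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "synthetic_config"))
  min_dur <- 2 * 2.5 + cfg$freefall_duration_s + 0.2
  if (cfg$duration_s < min_dur)
    stop_fallcnn(sprintf(
      "fall traces need duration_s >= %.2f s so every window size applies", min_dur),
      "fallcnn_config_error")
  with_seed(seed, {
    fs <- cfg$fs
    n <- round(cfg$duration_s * fs)
    n_ff <- max(2L, round(cfg$freefall_duration_s * fs))
    n_imp <- max(3L, round(0.15 * fs))
    i_ff <- round(0.45 * n)                       # free fall starts mid-trace
    i_imp <- i_ff + n_ff
    i_rest <- i_imp + n_imp
    n_rest <- n - i_rest + 1L

    u1 <- random_orientation()
    u2 <- rotate_orientation(u1, stats::runif(1, pi / 3, 2 * pi / 3))

    prefix <- gait_segment(i_ff - 1L, fs, u1, cfg$gait_frequency_hz,
                           amplitude = stats::runif(1, 0.15, 0.3),
                           phase = stats::runif(1, 0, 2 * pi))
    freefall <- GRAVITY * cfg$freefall_floor_g * outer(rep(1, n_ff), u1)
    rest <- GRAVITY * outer(rep(1, n_rest), u2)

    base <- rbind(prefix, freefall, matrix(0, n_imp, 3), rest)
    acc <- base + matrix(stats::rnorm(3L * n, 0, cfg$noise_sd_g * GRAVITY), n, 3)

    # impact: half-sine burst along a random direction, rescaled so its
    # magnitude peak is exactly the drawn value and tops the whole trace
    d <- random_orientation(1.5)
    env <- sin(pi * seq_len(n_imp) / (n_imp + 1))
    imp_rows <- i_imp:(i_imp + n_imp - 1L)
    acc[imp_rows, ] <- acc[imp_rows, ] + GRAVITY * cfg$impact_peak_g * outer(env, d)
    peak_g <- cfg$impact_peak_g +
      min(max(stats::rnorm(1, 0, 0.1 * cfg$impact_peak_g),
              -0.3 * cfg$impact_peak_g), 0.3 * cfg$impact_peak_g)
    smv_out <- compute_smv(acc[-imp_rows, , drop = FALSE])
    peak_g <- max(peak_g, 1.06 * max(smv_out) / GRAVITY)
    smv_imp <- compute_smv(acc[imp_rows, , drop = FALSE])
    acc[imp_rows, ] <- acc[imp_rows, ] * (GRAVITY * peak_g / max(smv_imp))

    inertial_trace(acc, fs = fs, label = "FALL", activity_code = "FALL",
                   dataset_id = "synthetic",
                   segments = list(freefall = c(i_ff, i_imp - 1L),
                                   impact = c(i_imp, i_imp + n_imp - 1L)))
  })
}

#' Generate a labeled collection of synthetic traces
#'
#' Produces `n_adl + n_fall` traces with per-trace seeds derived from
#' `cfg$seed`, so each trace is individually reproducible.
#'
#' @param cfg a [synthetic_config()].
#' @return list of [inertial_trace] objects (ADLs first, then falls).
#' @export
generate_traces <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  adl <- lapply(seq_len(cfg$n_adl), function(i)
    generate_adl_trace(cfg, seed = derive_seed(cfg$seed, "adl", i)))
  fall <- lapply(seq_len(cfg$n_fall), function(i)
    generate_fall_trace(cfg, seed = derive_seed(cfg$seed, "fall", i)))
  c(adl, fall)
}

#' Write a synthetic dataset to disk with its manifest
#'
#' Writes canonical CSV trace files (`ADL_###.csv`, `FALL_###.csv`) plus
#' JSON sidecars and a YAML manifest (`manifest.yaml`) whose label rule
#' keys off the filename prefix. Regeneration with the same configuration
#' is byte-identical.
#'
#' @param cfg a [synthetic_config()]; `n_adl + n_fall` must be >= 10.
#' @param out_dir output directory (created if missing).
#' @param dataset_id identifier stored in the manifest and traces.
#' @return the `dataset_manifest`, invisibly; its `dir` points at `out_dir`.
#' @export
generate_dataset <- function(cfg, out_dir, dataset_id = "synthetic") {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$n_adl + cfg$n_fall < 10L)
    stop_fallcnn("a dataset needs at least 10 traces", "fallcnn_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  traces <- generate_traces(cfg)
  labs <- vapply(traces, `[[`, character(1), "label")
  counts <- c(ADL = 0L, FALL = 0L)
  for (i in seq_along(traces)) {
    counts[labs[i]] <- counts[labs[i]] + 1L
    tr <- traces[[i]]
    tr$dataset_id <- dataset_id
    tr$subject_id <- sprintf("S%03d", i)
    write_trace(tr, file.path(out_dir, sprintf("%s_%03d.csv", labs[i],
                                               counts[labs[i]])))
  }
  manifest <- dataset_manifest(dataset_id = dataset_id, fs_nominal = cfg$fs,
                               unit_scale = 1.0,
                               axis_columns = list(x = "ax", y = "ay", z = "az"),
                               label_rule = list("^ADL_" = "ADL",
                                                 "^FALL_" = "FALL"),
                               trace_glob = "*.csv", delimiter = ",",
                               header = TRUE, dir = out_dir)
  yaml::write_yaml(manifest[c("dataset_id", "fs_nominal", "unit_scale",
                              "axis_columns", "label_rule", "trace_glob",
                              "delimiter", "header")],
                   file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
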
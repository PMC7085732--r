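# Synthetic trace generator: label-signal consistency and reproducibility.

g_units <- function(smv) smv / GRAVITY

test_that("fall traces carry the fall phenomenology in order", {
  cfg <- synthetic_config(seed = 7)
  tr <- generate_fall_trace(cfg, seed = 7)
  smv <- compute_smv(tr)
  seg <- tr$segments
  # global SMV maximum lies inside the impact segment and exceeds 3 g
  peak <- which.max(smv)
  expect_gte(peak, seg$impact[1])
  expect_lte(peak, seg$impact[2])
  expect_gt(g_units(max(smv)), 3)
  # free-fall dip: segment mean below 0.5 g
  ff <- seg$freefall[1]:seg$freefall[2]
  expect_lt(g_units(mean(smv[ff])), 0.5)
  # post-impact rest at ~1 g with a different orientation than the prefix
  rest <- (seg$impact[2] + 1):n_samples(tr)
  expect_lt(abs(g_units(mean(smv[rest])) - 1), 0.15)
  pre_dir <- colMeans(tr$samples[1:(seg$freefall[1] - 1), ])
  rest_dir <- colMeans(tr$samples[rest, ])
  cosang <- sum(pre_dir * rest_dir) /
    sqrt(sum(pre_dir^2) * sum(rest_dir^2))
  expect_lt(cosang, 0.9)
  # determinism
  expect_identical(tr, generate_fall_trace(cfg, seed = 7))
})

test_that("ADL traces stay clear of fall signatures", {
  cfg <- synthetic_config(seed = 7)
  tr <- generate_adl_trace(cfg, seed = 7)
  smv <- compute_smv(tr)
  expect_lt(g_units(max(smv)), 3)
  # no 0.2 s stretch with mean SMV below 0.5 g
  k <- round(0.2 * cfg$fs)
  roll <- stats::filter(smv, rep(1 / k, k), sides = 1)
  expect_gt(g_units(min(roll, na.rm = TRUE)), 0.5)
  expect_identical(tr, generate_adl_trace(cfg, seed = 7))
})

test_that("noiseless walking is periodic at the gait frequency", {
  cfg <- synthetic_config(fs = 100, duration_s = 8, noise_sd_g = 1e-9,
                          gait_frequency_hz = 2, seed = 3)
  tr <- generate_adl_trace(cfg, seed = 3, kind = "walk")
  smv <- compute_smv(tr) - mean(compute_smv(tr))
  ac <- stats::acf(smv, lag.max = 80, plot = FALSE)$acf[-1]
  period <- cfg$fs / cfg$gait_frequency_hz  # 50 samples
  # first prominent autocorrelation peak at one gait period (+/- 1 sample);
  # restrict to lags beyond the first harmonic's half-period
  lag_range <- 30:80
  peak_lag <- lag_range[which.max(ac[lag_range])]
  expect_lte(abs(peak_lag - period), 1)
})

test_that("label-signal consistency holds across many generated traces", {
  cfg <- synthetic_config(fs = 50, duration_s = 6, n_adl = 500, n_fall = 500,
                          seed = 99)
  k <- round(0.2 * cfg$fs)
  for (i in seq_len(cfg$n_fall)) {
    tr <- generate_fall_trace(cfg, seed = derive_seed(99, "fall", i))
    smv <- compute_smv(tr)
    peak <- which.max(smv)
    expect_true(peak >= tr$segments$impact[1] && peak <= tr$segments$impact[2],
                label = sprintf("fall %d peak inside impact", i))
  }
  for (i in seq_len(cfg$n_adl)) {
    tr <- generate_adl_trace(cfg, seed = derive_seed(99, "adl", i))
    roll <- stats::filter(compute_smv(tr), rep(1 / k, k), sides = 1)
    expect_gt(min(roll, na.rm = TRUE) / GRAVITY, 0.5)
  }
})

test_that("impact magnitudes concentrate around the configured mean", {
  cfg <- synthetic_config(fs = 50, duration_s = 6, seed = 5)
  peaks <- vapply(seq_len(500), function(i) {
    max(compute_smv(generate_fall_trace(cfg, seed = derive_seed(5, "f", i)))) /
      GRAVITY
  }, numeric(1))
  expect_lt(abs(mean(peaks) - cfg$impact_peak_g) / cfg$impact_peak_g, 0.1)
})

test_that("generate_dataset writes exact counts and reproduces byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- synthetic_config(fs = 50, duration_s = 6, n_adl = 6, n_fall = 6,
                          seed = 11)
  m1 <- generate_dataset(cfg, dir1)
  m2 <- generate_dataset(cfg, dir2)
  csvs <- sort(basename(Sys.glob(file.path(dir1, "*.csv"))))
  expect_length(csvs, 12L)
  expect_equal(sum(startsWith(csvs, "ADL")), 6L)
  traces <- read_dataset(m1)
  expect_equal(as.integer(table(sapply(traces, `[[`, "label"))), c(6L, 6L))
  for (f in csvs)
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     label = paste("byte-identical", f))
  expect_fallcnn_error(
    generate_dataset(synthetic_config(n_adl = 4, n_fall = 4), dir1),
    "fallcnn_config_error")
})

test_that("generator validates its physical parameters", {
  expect_fallcnn_error(synthetic_config(impact_peak_g = 0.9),
                       "fallcnn_config_error")
  expect_fallcnn_error(synthetic_config(freefall_floor_g = 1.2),
                       "fallcnn_config_error")
  expect_fallcnn_error(
    generate_fall_trace(synthetic_config(duration_s = 3)),
    "fallcnn_config_error", "duration")
  # hard mode narrows the margins
  hard <- synthetic_config(hard = TRUE)
  expect_equal(hard$impact_peak_g, 1.8)
  expect_equal(hard$noise_sd_g, 0.15)
})
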
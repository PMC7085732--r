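# Shared fixtures, built in code at test time.

# A trace with a known flat-gravity baseline and a single spike, short
# enough to exercise boundary/skip behaviour. Values in m/s^2.
flat_trace_with_spike <- function(n, fs, spike_at = NULL, spike_g = 4,
                                  label = "FALL") {
  acc <- cbind(rep(0, n), rep(0, n), rep(GRAVITY, n))
  if (!is.null(spike_at)) acc[spike_at, 3] <- spike_g * GRAVITY
  inertial_trace(acc, fs = fs, label = label)
}

# Strongly separable toy windows of a given width: FALL rows carry a
# localized +30 m/s^2 bump on a ~1 g noisy baseline.
toy_windows <- function(n, width = 125, seed = 9) {
  fallcnn:::with_seed(seed, {
    y <- rep(c("ADL", "FALL"), length.out = n)
    x <- t(vapply(seq_len(n), function(i) {
      base <- stats::rnorm(width, 9.8, 0.5)
      if (y[i] == "FALL") {
        at <- sample.int(width - 8L, 1L)
        base[at:(at + 6L)] <- base[at:(at + 6L)] + 30
      }
      base
    }, numeric(width)))
    list(x = x, labels = factor(y, levels = c("ADL", "FALL")))
  })
}

# Write a minimal hand-made dataset (flat ADLs, spiked FALLs) of short
# traces to `dir` with a manifest; returns the manifest.
write_short_dataset <- function(dir, n_per_class = 6, n_samples = 280,
                                fs = 200) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(n_per_class)) {
    adl <- flat_trace_with_spike(n_samples, fs, spike_at = NULL, label = "ADL")
    adl$samples <- adl$samples + (i / 100)  # make traces distinct
    write_trace(adl, file.path(dir, sprintf("ADL_%03d.csv", i)))
    fall <- flat_trace_with_spike(n_samples, fs,
                                  spike_at = n_samples %/% 2 + i,
                                  label = "FALL")
    write_trace(fall, file.path(dir, sprintf("FALL_%03d.csv", i)))
  }
  dataset_manifest(dataset_id = "short", fs_nominal = fs, unit_scale = 1,
                   axis_columns = list(x = "ax", y = "ay", z = "az"),
                   label_rule = list("^ADL_" = "ADL", "^FALL_" = "FALL"),
                   trace_glob = "*.csv", dir = dir)
}

# Fast-but-real training configuration for unit tests that only check
# plumbing (not learning): one epoch.
quick_tc <- function(seed = 1) {
  train_config(max_epochs = 2L, minibatch_size = 16L, seed = seed)
}

expect_fallcnn_error <- function(expr, class, pattern = NULL) {
  err <- tryCatch({ expr; NULL }, condition = function(e) e)
  expect_true(inherits(err, class),
              label = sprintf("expected condition of class %s", class))
  if (!is.null(pattern)) expect_match(conditionMessage(err), pattern)
}
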
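# Per-dataset benchmark protocol: for every (dataset, window half-width,
# input variant) cell, windows are extracted at the dataset's own sampling
# rate (never resampled, so the network input width differs per dataset), a
# fresh network is built at that width, trained on a stratified 60/20/20
# split, and evaluated on the held-out test subset.

BENCH_HALF_WIDTHS <- c(0.5, 1.0, 1.5, 2.5)
BENCH_VARIANTS <- c("SMV", "TRIAXIAL")

#' Run the multi-dataset x window-size x variant benchmark
#'
#' Each cell uses an independent seed derived from
#' `(seed, dataset_id, half_width, variant)`, so any cell is reproducible in
#' isolation. A cell is SKIPPED when its configuration is inapplicable:
#' the window is longer than some trace of the dataset
#' (`window_too_long`), or narrower than the network's minimum input width
#' (`input_too_narrow`). Any other per-cell failure is recorded as ERROR and
#' does not abort the remaining cells.
#'
#' @param manifests list of `dataset_manifest` objects or manifest file
#'   paths; each must resolve at least 5 traces per class.
#' @param seed master integer seed.
#' @param out_dir optional directory; when given, one CSV per variant
#'   (rows = datasets, column groups = half-widths x Se/Sp/Acc) and a JSON
#'   log of skips, errors and per-cell seeds are written.
#' @param half_widths window half-widths in seconds.
#' @param variants input variants to benchmark.
#' @param net_config a [network_config()].
#' @param tc a [train_config()]; its seed is replaced per cell.
#' @param repeats trainings averaged per cell (default 1, matching a
#'   single-run-per-cell protocol).
#' @param verbose emit JSON progress logs.
#' @return a `benchmark_grid`: data.frame with one row per cell
#'   (`dataset_id`, `half_width_s`, `variant`, `status`, `input_width`,
#'   `sensitivity`, `specificity`, `accuracy`, confusion counts, subset
#'   sizes, `cell_seed`, `reason`), with the per-cell log as attribute
#'   `"log"`.
#' @export
run_benchmark <- function(manifests, seed, out_dir = NULL,
                          half_widths = BENCH_HALF_WIDTHS,
                          variants = BENCH_VARIANTS,
                          net_config = network_config(), tc = train_config(),
                          repeats = 1L, verbose = FALSE) {
  if (inherits(manifests, "dataset_manifest")) manifests <- list(manifests)
  manifests <- lapply(manifests, function(m)
    if (inherits(m, "dataset_manifest")) m else read_manifest(m))
  rows <- list()
  logs <- list()
  for (m in manifests) {
    traces <- tryCatch(read_dataset(m), error = function(e) e)
    for (hw in half_widths) for (variant in variants) {
      cell_seed <- derive_seed(seed, m$dataset_id, hw, variant)
      log_json(verbose, "cell", dataset = m$dataset_id, half_width = hw,
               variant = variant, seed = cell_seed)
      row <- data.frame(dataset_id = m$dataset_id, half_width_s = hw,
                        variant = variant, status = "OK",
                        input_width = window_width(hw, m$fs_nominal, variant),
                        sensitivity = NA_real_, specificity = NA_real_,
                        accuracy = NA_real_, TP = NA_integer_, TN = NA_integer_,
                        FP = NA_integer_, FN = NA_integer_,
                        n_train = NA_integer_, n_val = NA_integer_,
                        n_test = NA_integer_, best_epoch = NA_integer_,
                        cell_seed = cell_seed, reason = "",
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        if (inherits(traces, "error")) stop(traces)
        run_benchmark_cell(traces, hw, variant, cell_seed, net_config, tc,
                           repeats)
      }, fallcnn_window_too_long = function(e)
        list(status = "SKIPPED", reason = "window_too_long",
             message = conditionMessage(e)),
      fallcnn_config_error = function(e) {
        if (grepl("too narrow", conditionMessage(e)))
          list(status = "SKIPPED", reason = "input_too_narrow",
               message = conditionMessage(e))
        else list(status = "ERROR", reason = "error",
                  message = conditionMessage(e))
      }, error = function(e)
        list(status = "ERROR", reason = "error",
             message = conditionMessage(e)))
      if (identical(res$status %||% "OK", "OK")) {
        row$sensitivity <- res$metrics$sensitivity
        row$specificity <- res$metrics$specificity
        row$accuracy <- res$metrics$accuracy
        row[c("TP", "TN", "FP", "FN")] <- res$counts[c("TP", "TN", "FP", "FN")]
        row[c("n_train", "n_val", "n_test")] <- res$sizes
        row$best_epoch <- res$best_epoch
      } else {
        row$status <- res$status
        row$reason <- res$reason
      }
      rows[[length(rows) + 1L]] <- row
      logs[[length(logs) + 1L]] <- list(dataset_id = m$dataset_id,
                                        half_width_s = hw, variant = variant,
                                        cell_seed = cell_seed,
                                        status = row$status,
                                        reason = row$reason,
                                        message = res$message %||% "")
    }
  }
  grid <- do.call(rbind, rows)
  class(grid) <- c("benchmark_grid", "data.frame")
  attr(grid, "log") <- logs
  if (!is.null(out_dir)) write_benchmark_outputs(grid, logs, out_dir)
  grid
}

run_benchmark_cell <- function(traces, hw, variant, cell_seed, net_config,
                               tc, repeats) {
  labels <- trace_labels(traces)
  counts <- table(labels)
  if (any(counts < 5L))
    stop_fallcnn("dataset must contain at least 5 traces per class",
                 "fallcnn_split_error")
  wins <- windows_from_traces(traces, hw, variant)  # may signal window_too_long
  metrics_acc <- NULL
  counts_last <- NULL
  best_epoch <- NA_integer_
  sizes <- NULL
  for (r in seq_len(repeats)) {
    rseed <- if (repeats == 1L) cell_seed else derive_seed(cell_seed, "rep", r)
    split <- split_dataset(labels, rseed)
    model <- build_network(wins$width, net_config, seed = rseed)
    tc_cell <- tc
    tc_cell$seed <- rseed
    model <- train_network(model,
                           wins$x[split$train, , drop = FALSE],
                           wins$labels[split$train],
                           wins$x[split$val, , drop = FALSE],
                           wins$labels[split$val], tc_cell)
    ev <- evaluate_model(model, wins$x[split$test, , drop = FALSE],
                         wins$labels[split$test])
    metrics_acc <- rbind(metrics_acc,
                         unlist(ev$metrics[c("sensitivity", "specificity",
                                             "accuracy")]))
    counts_last <- ev$counts
    best_epoch <- model$best_epoch
    sizes <- c(length(split$train), length(split$val), length(split$test))
  }
  mm <- colMeans(metrics_acc)
  list(status = "OK",
       metrics = list(sensitivity = mm[["sensitivity"]],
                      specificity = mm[["specificity"]],
                      accuracy = mm[["accuracy"]]),
       counts = counts_last, best_epoch = best_epoch, sizes = sizes)
}

# One CSV per variant in the rows-by-datasets, half-width-grouped layout,
# plus a JSON log of per-cell seeds, skips and errors.
write_benchmark_outputs <- function(grid, logs, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (variant in unique(grid$variant)) {
    g <- grid[grid$variant == variant, , drop = FALSE]
    datasets <- unique(g$dataset_id)
    hws <- sort(unique(g$half_width_s))
    out <- data.frame(dataset = datasets, stringsAsFactors = FALSE)
    for (hw in hws) {
      for (metric in c("sensitivity", "specificity", "accuracy")) {
        colname <- sprintf("%s_hw%g", c(sensitivity = "Se", specificity = "Sp",
                                        accuracy = "Acc")[[metric]], hw)
        out[[colname]] <- vapply(datasets, function(d) {
          r <- g[g$dataset_id == d & g$half_width_s == hw, ]
          if (nrow(r) != 1L || r$status != "OK") r$status[1] %||% ""
          else sprintf("%.2f", r[[metric]])
        }, character(1))
      }
    }
    utils::write.csv(out,
                     file.path(out_dir, sprintf("benchmark_%s.csv",
                                                tolower(variant))),
                     row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(logs, file.path(out_dir, "benchmark_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}
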
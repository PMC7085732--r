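# Internal helpers shared across modules.

#' Standard gravity in m/s^2
#'
#' Conversion constant between the g units used by the synthetic generator
#' configuration and the canonical m/s^2 unit of [inertial_trace] samples.
#' @export
GRAVITY <- 9.80665

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so library calls never clobber user RNG.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a reproducible child seed from a master seed and string context
#'
#' Polynomial string hash folded with the master seed, reduced modulo a
#' 31-bit prime so the result is always a valid R integer seed. Used to give
#' every benchmark cell and every synthetic trace an independent but
#' reproducible RNG stream.
#'
#' @param seed master integer seed.
#' @param ... character/numeric components identifying the sub-task
#'   (e.g. dataset id, half-width, variant).
#' @return a positive integer seed < 2^31.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483629
  key <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                      character(1)), collapse = "/")
  h <- as.double(as.integer(seed) %% m)
  for (cp in utf8ToInt(key)) h <- (h * 131 + cp) %% m
  as.integer(h + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Abort with a classed condition so callers can discriminate error types.
stop_fallcnn <- function(msg, class) {
  stop(structure(class = c(class, "fallcnn_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Line-delimited JSON logging (stderr); silent unless verbose.
log_json <- function(verbose, event, ...) {
  if (!isTRUE(verbose)) return(invisible(NULL))
  rec <- c(list(ts = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
                event = event), list(...))
  message(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  invisible(NULL)
}
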
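#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Emit a pipeline log line unless logging is suppressed.
ss_log <- function(..., verbose = getOption("survscreen.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[survscreen] ", ...)
  invisible(NULL)
}

# Derive a per-stage seed substream from one master seed, so any stage can be
# re-run in isolation. Kept below .Machine$integer.max.
substream <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  offsets <- c(
    simulate = 11L, integrate = 23L, diagnose = 37L, de = 51L,
    screen = 67L, stabilize = 83L, rank = 97L, risk = 113L,
    threshold = 131L, panels = 149L
  )
  off <- offsets[[stage]]
  as.integer((abs(as.numeric(seed)) * 1009 + off * 9973) %% 2147483647)
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < min) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  }
  as.numeric(x)
}

check_nonneg <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative value", name), call. = FALSE)
  }
  as.numeric(x)
}
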
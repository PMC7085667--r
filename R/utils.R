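# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG seed
#'
#' Runs `code` with the random number generator seeded at `seed`, then restores
#' the caller's RNG state, so library functions can be deterministic without
#' clobbering the global stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Canonical number -> text used by every CSV writer so that write/load
# round-trips are exact: %.17g preserves doubles bit-for-bit.
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}

# Parse "HH:MM" or "HH:MM:SS" clock times to fractional hours in [0, 24).
parse_clock <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (!length(parts) %in% c(2L, 3L) || anyNA(suppressWarnings(as.numeric(parts)))) {
    stop("invalid clock time: '", x, "' (expected HH:MM or HH:MM:SS)", call. = FALSE)
  }
  v <- as.numeric(parts)
  h <- v[1] + v[2] / 60 + if (length(v) == 3L) v[3] / 3600 else 0
  if (h < 0 || h >= 24) stop("clock time out of range: '", x, "'", call. = FALSE)
  h
}

abort_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
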
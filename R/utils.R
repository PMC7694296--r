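#' @importFrom stats setNames
#' @importFrom dplyr .data
NULL

DNA_BASES <- c("A", "C", "G", "T")

# stop() with sprintf-style formatting and no call in the message
abort <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) abort(fmt, ...)
  invisible(TRUE)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x)
}

is_scalar_string <- function(x) {
  is.character(x) && length(x) == 1L && !is.na(x)
}

#' Derive a stream-specific seed from a master seed
#'
#' Stage seeds are derived deterministically from one master seed so that
#' a single integer reproduces a whole pipeline run while the stages remain
#' statistically independent streams. Kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stream character label of the consuming stage.
#' @return A single integer seed.
#' @keywords internal
derive_seed <- function(master, stream) {
  assert(is_count(abs(master)), "master seed must be an integer")
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(master) * 48271 + h * 9349) %% 2147483647L)
}

# complement / reverse-complement on plain character strings
revcomp <- function(s) {
  chartr("ACGT", "TGCA", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
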
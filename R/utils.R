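#' Four-movement vocabulary
#'
#' The fixed set of hand-movement condition labels used throughout the
#' package. Grip, Extend and Pinch are the ecological movements; Shake is the
#' non-ecological control.
#'
#' @export
MOVEMENTS <- c("Grip", "Extend", "Pinch", "Shake")

ECOLOGICAL <- c("Grip", "Extend", "Pinch")

#' Derive a child seed from a master seed
#'
#' Deterministic arithmetic derivation of per-run / per-subject seeds so that
#' every random quantity in a simulation is a pure function of the master seed.
#' The result always fits in a 32-bit signed integer.
#'
#' @param master integer master seed.
#' @param ... one or more non-negative integer stream identifiers
#'   (e.g. subject index, run index).
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  ids <- c(...)
  stopifnot(length(ids) >= 1L, all(is.finite(ids)))
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(master) %% m
  for (id in ids) {
    # 48271: multiplier of the MINSTD linear congruential generator
    s <- (s * 48271 + as.double(id) + 1) %% m
  }
  as.integer(s)
}

# evaluate `code` with a locally-set RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_count <- function(x, name = deparse(substitute(x)), positive = TRUE) {
  ok <- length(x) == 1L && is.finite(x) && x == round(x) && (x > 0 || !positive)
  if (!ok) stop(sprintf("'%s' must be a %s integer, got %s",
                        name, if (positive) "positive" else "non-negative",
                        paste(format(x), collapse = ",")), call. = FALSE)
  invisible(as.integer(x))
}

assert_number <- function(x, name = deparse(substitute(x)), positive = FALSE) {
  ok <- length(x) == 1L && is.finite(x) && (!positive || x > 0)
  if (!ok) stop(sprintf("'%s' must be a finite%s number", name,
                        if (positive) " positive" else ""), call. = FALSE)
  invisible(as.numeric(x))
}
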
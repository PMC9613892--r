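# Internal helpers shared across modules.

#' Derive a per-stage seed from a global seed
#'
#' A single global seed fans out to independent per-stage seeds through a
#' fixed counter scheme: `seed * 101 + offset`, reduced modulo 2^31 - 1 so the
#' result is always a valid R integer. The offsets are fixed per stage, so a
#' rerun with the same global seed reproduces every stage exactly while
#' different stages see uncorrelated streams.
#'
#' @param seed integer global seed.
#' @param offset integer stage offset (each pipeline stage has its own).
#' @return an integer seed.
#' @export
stage_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(as.numeric(seed)) * 101 + offset) %% (2^31 - 1))
}

# stop() with a consistent header for user-facing configuration errors
config_error <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# check a probability-like scalar/vector lies in [0, 1]
check_rates <- function(x, what = "rate") {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    config_error("%s must be numeric in [0, 1]", what)
  }
  invisible(x)
}

# statistical mode (most common value); ties broken by first occurrence in
# sorted order for determinism
stat_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA)
  tab <- table(x)
  val <- names(tab)[which.max(tab)]
  if (is.numeric(x)) as.numeric(val) else val
}
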
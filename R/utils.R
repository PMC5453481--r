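#' Derive a reproducible sub-seed
#'
#' All stochastic stages draw their randomness from per-operation streams
#' derived from a single user seed and an operation tag, so that e.g. the
#' i-th PSO start sees the same stream regardless of how many later starts
#' are requested (prefix property).
#'
#' @param seed integer master seed.
#' @param tag character operation tag.
#' @param index integer stream index within the operation (default 0).
#' @return an integer in `[0, 2^31)` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, tag, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  # linear congruential mix, kept within 32-bit integer range
  (as.double(seed) * 69069 + h * 2654435 + as.double(index) * 40503) %% 2147483647
}

# internal: stop with a consistent error class
cp_stop <- function(msg, class) {
  stop(structure(class = c(class, "colorpart_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# FNV-1a style hash of a character scalar, for config stamping
cp_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}
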
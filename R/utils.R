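#' Derive a reproducible sub-stream seed
#'
#' Deterministically combines a base seed with an arbitrary set of labels
#' (cruise ids, site ids, stage names) into a new integer seed below
#' 2^31 - 1. Used so that every simulated cruise and every site-pair null
#' model draws from its own reproducible RNG stream: results are then
#' independent of the order in which pairs are processed.
#'
#' @param seed integer base seed.
#' @param ... labels (coerced to character) identifying the sub-stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime; keeps the state in integer range
  h <- abs(as.double(seed)) %% m
  parts <- unlist(lapply(list(...), as.character), use.names = FALSE)
  for (p in parts) {
    for (k in utf8ToInt(p)) h <- (h * 31 + k) %% m
  }
  as.integer(h)
}

# internal: evaluate `code` under a fixed seed without disturbing the
# caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
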
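# Internal helpers: structured conditions, seed handling.

stop_famlmm <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "famlmm_error")))
}

#' Derive a child seed from a base seed and an index path
#'
#' Deterministically mixes a base seed with a path of integer indices
#' (replicate number, draw number, ...) so that every randomized step of a
#' study gets its own reproducible stream. The mixing is a fixed
#' linear-congruential fold modulo 2^31 - 1, so derived seeds stay inside the
#' 32-bit integer range accepted by [set.seed()].
#'
#' @param base Integer base seed.
#' @param ... Integer indices identifying the step (e.g. replicate, draw).
#' @return A single integer seed.
#' @examples
#' derive_seed(1, 1, 1)
#' derive_seed(1, 1, 2)  # differs
#' @export
derive_seed <- function(base, ...) {
  idx <- c(..., 0)
  s <- as.double(abs(as.integer(base)) %% 2147483647)
  for (x in idx) {
    # 2^31 * 69069 < 2^53: exact in double arithmetic
    s <- (s * 69069 + as.double(x) * 1234567 + 12345) %% 2147483647
  }
  as.integer(s)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
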
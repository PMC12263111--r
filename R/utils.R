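# Internal helpers: deterministic RNG substreams and small assertions.

#' Derive a reproducible substream seed from a base seed and name parts
#'
#' Hashes the base seed together with arbitrary string/integer tokens into
#' a 31-bit integer, so that each (component, unit) pair gets its own
#' independent, order-insensitive RNG stream. Adding simulation units never
#' perturbs the streams of existing ones.
#'
#' @param seed integer base seed.
#' @param ... tokens (coerced to character) naming the substream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, ...) {
  parts <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 0
  for (v in utf8ToInt(parts)) h <- (h * 31 + v) %% 2147483629
  as.integer(h)
}

# Evaluate `code` under a local RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_data <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
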
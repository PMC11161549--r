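#' Derive a reproducible substream seed
#'
#' Every stochastic operation in the package draws its random numbers from a
#' substream derived from a single root seed and a set of string/integer keys
#' (typically the operation name and a replicate or clone index).  The same
#' root seed and keys always yield the same substream, so simulations are
#' bit-reproducible regardless of the order in which clones or replicates are
#' generated.
#'
#' @param seed integer root seed.
#' @param ... additional keys (coerced to character) identifying the
#'   operation and replicate.
#' @return An integer in \code{[0, 2^31 - 2]} suitable for \code{set.seed()}.
#' @examples
#' substreamSeed(1L, "simulateClone", 3)
#' @export
substreamSeed <- function(seed, ...) {
  key <- paste(c(format(seed), vapply(list(...), format, "")), collapse = "/")
  h <- 17
  for (b in utf8ToInt(key)) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

## Evaluate `expr` under a temporary RNG state seeded by `seed`, restoring the
## caller's .Random.seed afterwards so package functions never clobber the
## user's stream.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}
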
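#' Derive a reproducible substream seed from a master seed
#'
#' All randomness in the package flows from a single master seed through
#' named substreams, so that individual pipeline stages (cohort generation,
#' case-control sampling, bootstrap resampling, study-estimate simulation)
#' are independently reproducible: re-running one stage with the same master
#' seed gives the same draws regardless of what ran before it.
#'
#' @param seed master integer seed.
#' @param stream character name of the substream.
#' @return an integer seed in [0, 2^31 - 2], deterministic in (seed, stream).
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # simple polynomial rolling hash of the stream name, folded into the seed
  h <- 0
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((abs(seed) + h * 7919) %% 2147483647)
}

# run expr with a local RNG state seeded from (seed, stream); restores the
# caller's RNG state afterwards
with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}
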
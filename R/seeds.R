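#' Derive a named substream seed from a master seed
#'
#' Each stochastic generator in the package draws from its own substream so
#' that modules stay decoupled: changing how many numbers one generator
#' consumes never perturbs another. The substream seed is a deterministic
#' 31-bit hash of the master seed and a stream label.
#'
#' @param seed master seed (single integer-like value).
#' @param stream character label of the substream.
#' @return A single integer in `[0, 2^31 - 1)` suitable for [set.seed()].
#' @examples
#' substream_seed(1, "cohort") != substream_seed(1, "variants")
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stream), length(stream) == 1L)
  m <- 2^31 - 1
  h <- as.numeric(seed) %% m
  for (b in utf8ToInt(stream)) {
    # 31-bit multiplicative hash; kept in double precision (< 2^53 throughout)
    h <- (h * 131 + b) %% m
  }
  as.integer((h * 2654435761) %% m)
}

with_substream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, stream))
  expr
}
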
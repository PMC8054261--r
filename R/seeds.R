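#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one top-level integer seed.
#' Stage- or unit-specific seeds are derived deterministically from that
#' seed and a label, so that adding a stage never perturbs the random
#' stream of another and whole pipelines are reproducible end-to-end.
#'
#' The derivation is a 31-bit polynomial string hash of `label` folded into
#' `seed`; results always lie in `[0, 2^31 - 2]` and are stable across
#' platforms.
#'
#' @param seed integer top-level seed.
#' @param label character scalar naming the substream (e.g. `"scene"`,
#'   `"dose:0.555"`).
#' @return an integer seed.
#' @examples
#' derive_seed(1L, "scene")
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- abs(as.double(seed)) %% m
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

# run expr with a local RNG state seeded from (seed, label)
with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, label))
  expr
}
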
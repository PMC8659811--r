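#' Derive a named sub-seed from a master seed
#'
#' All stochastic components of the package (cohort generation, embedding
#' initialisation, dropout, dynamic sampling, fold assignment) draw their
#' randomness from independent named streams derived from one master seed, so
#' each sub-component is reproducible in isolation.
#'
#' @param seed Master integer seed.
#' @param stream Character stream name, e.g. `"sampling"`, `"dropout"`.
#' @return An integer seed in `[0, 2^31)`, deterministic in `(seed, stream)`.
#' @export
#' @examples
#' derive_seed(1, "sampling")
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435 + h) %% 2147483647)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards (so library functions never perturb
# user-visible randomness).
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
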
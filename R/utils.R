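#' Run code with a local RNG state
#'
#' Seeds the RNG for the duration of `expr` and restores the caller's RNG
#' state afterwards, so stochastic package functions are reproducible
#' without clobbering the session's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

# Derive a per-unit child seed from a base seed, staying within 32-bit
# integer range.
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1000L + index) %% .Machine$integer.max)
}
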
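#' @keywords internal
"_PACKAGE"

#' Evaluate code under a local RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals do not disturb
#' the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a sub-generator seed from a global seed
#'
#' Deterministic spawning scheme: every stochastic stage draws its own seed
#' from the single user-supplied seed and a fixed stream index, so partial
#' reruns of any stage reproduce the full-run results.
#'
#' @param seed Global integer seed.
#' @param stream Integer stream index (>= 1).
#' @return An integer seed below 2^31.
#' @export
spawn_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(stream))
  as.integer((abs(seed) + 7919 * abs(stream)) %% 2147483587L)
}

stop_arg <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
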
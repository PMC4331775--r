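# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so generator calls do not disturb the
#' caller's RNG stream. All synthetic-data generators route their randomness
#' through this helper; sub-generators derive their streams from one base seed
#' plus a fixed documented offset (expression: +0, probe level: +1,
#' ontology: +2, annotations: +3).
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Offsets for the seed-splitting scheme (documented in with_seed()).
SEED_OFFSET_EXPRESSION <- 0L
SEED_OFFSET_PROBES     <- 1L
SEED_OFFSET_ONTOLOGY   <- 2L
SEED_OFFSET_ANNOTATION <- 3L

stop_input <- function(...) stop(..., call. = FALSE)
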
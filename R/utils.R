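# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's random number stream. A `NULL` seed evaluates the
#' code against the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
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
  force(code)
}

# Consistent message prefix so pipeline logs are greppable.
fm_log <- function(...) {
  message("[hlafinemap] ", ...)
}

stop_fm <- function(...) stop(..., call. = FALSE)
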
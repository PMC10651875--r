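#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `fn()` with the global random-number state set from `seed`, then
#' restores the previous state so callers' RNG streams are unaffected.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param fn A zero-argument function to call.
#' @return The value of `fn()`.
#' @keywords internal
with_seed <- function(seed, fn) {
  if (is.null(seed)) {
    return(fn())
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  fn()
}

# stop() with the offending argument named, for contract errors
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}
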
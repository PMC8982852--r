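# Internal helpers shared across modules.

#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic entry points funnel through
# this so that a single integer seed makes a whole pipeline reproducible.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label, staying within
# the 32-bit integer range.
#' @keywords internal
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 69069 + 12345 + sum(utf8ToInt(as.character(stream)))) %%
    2147483647
  as.integer(s)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
abort_if <- function(cond, msg) {
  if (cond) stop(msg, call. = FALSE)
  invisible(TRUE)
}
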
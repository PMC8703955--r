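# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so generators are reproducible
#' without clobbering the caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' @noRd
stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  invisible(x)
}

# Overflow-safe log(sum(exp(x))).
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}
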
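#' Run an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package internals do
#' not perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps (seed, stage label) to an integer in [1, 2^31 - 2]
#' so pipeline stages can be rerun in isolation with reproducible streams.
#'
#' @param seed integer global seed.
#' @param stage character label or integer index of the stage.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  key <- if (is.character(stage)) sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
         else as.numeric(stage) * 7919
  m <- 2147483647  # 2^31 - 1, Park-Miller modulus
  s <- (abs(as.numeric(seed)) %% m)
  s <- (s * 48271 + key) %% m
  s <- (s * 48271 + 11) %% m
  as.integer(s %% (m - 2) + 1)
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

is_power_of_two <- function(n) n >= 1 && bitwAnd(as.integer(n), as.integer(n - 1L)) == 0L

next_pow2 <- function(n) 2^ceiling(log2(max(1, n)))

stop_bandelet <- function(...) stop(..., call. = FALSE)
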
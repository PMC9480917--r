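#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} with the global RNG seeded at \code{seed}, restoring the
#' previous RNG state afterwards so that seeded generators do not disturb the
#' caller's random stream. A \code{NULL} seed evaluates the code unchanged.
#'
#' @param seed integer seed or \code{NULL}
#' @param code expression to evaluate
#' @return the value of \code{code}
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

#' Derive a child seed from a parent seed
#'
#' Deterministic fan-out of one top-level seed to per-stage seeds, kept below
#' 2^31 so the result is always a valid R integer seed.
#'
#' @param seed parent integer seed
#' @param stage stage index (1, 2, ...)
#' @return integer seed
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 48271 + stage * 10007) %% 2147483647L)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
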
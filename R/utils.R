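## Internal helpers shared across the package.

#' @importFrom methods new validObject is slot
#' @importFrom stats cor pt p.adjust sd lm rnorm rpois runif rbinom cmdscale
#' @importFrom utils read.table write.table
NULL

## Classed stop() so callers/tests can distinguish failure modes
## (format, parameter, degenerate input, ...) without string matching.
mnStop <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "mnError", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1))
  ))
}

## Evaluate expr with a locally seeded RNG, restoring the caller's RNG
## state afterwards. All seeded operations in the package route through
## this so that a given seed is reproducible regardless of surrounding
## RNG use.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    mnStop("mnParameterError", "'seed' must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Upper-triangle (i < j) values of a square matrix, in column order.
upperTri <- function(m) m[upper.tri(m)]

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

checkProb <- function(x, name) {
  if (!isScalarNumber(x) || x < 0 || x > 1)
    mnStop("mnParameterError", sprintf("'%s' must be a probability in [0, 1]", name))
  invisible(x)
}
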
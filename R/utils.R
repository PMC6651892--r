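## Internal helpers shared across modules.

#' @importFrom methods new is validObject slot slotNames
#' @importFrom stats cor pt rnorm runif sd setNames t.test
#' @importFrom utils head read.table write.table
NULL

## Classed conditions so callers (and tests) can dispatch on failure modes.
.stopf <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "chimeraZooError", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

## Round-half-up: the convention used to turn fractional percentile ranks
## into integer counts (round() in R rounds half to even, which is wrong here).
roundHalfUp <- function(x) floor(x + 0.5)

## Evaluate expr under a fixed RNG state without disturbing the caller's
## random stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive per-stage seeds from one master seed
#'
#' All randomness in the package flows from stage seeds drawn once, by a fixed
#' deterministic sequence, from a single master seed. Storing the master seed
#' (or the stage seeds themselves, as the build recipe does) is enough to
#' replay any build or experiment exactly.
#'
#' @param masterSeed Single integer seed.
#' @param stages Character vector of stage names.
#' @return Named integer vector, one seed per stage, all distinct.
#' @examples
#' spawnSeeds(42L, c("labeling", "assignment"))
#' @export
spawnSeeds <- function(masterSeed, stages) {
  stopifnot(length(masterSeed) == 1L, is.finite(masterSeed))
  n <- length(stages)
  seeds <- withSeed(masterSeed, sample.int(.Machine$integer.max - 1L, n))
  setNames(as.integer(seeds), stages)
}

## Stable ascending order by statistic, ties broken by id: the deterministic
## ranking used for goat/lamb candidate selection.
.orderByStat <- function(values, ids) order(values, ids, method = "radix")
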
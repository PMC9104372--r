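## Internal helpers shared across modules.

#' Round half away from zero
#'
#' Deterministic commercial rounding used wherever a fraction of a count must
#' become an integer (sample splits, planted loss/gain cells), so that tests
#' can predict counts exactly. `round()` in R rounds half to even, which would
#' make 2.5 -> 2; here 2.5 -> 3 and -2.5 -> -3.
#'
#' @param x numeric vector.
#' @return integer vector of the same length.
#' @keywords internal
roundHalfAwayFromZero <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

## Condition constructors: validation errors (bad arguments/config, exit code
## 2 at the CLI) vs data errors (unusable inputs at run time, exit code 3).
stopValidation <- function(...) {
  stop(errorCondition(paste0(...), class = c("sgd_validation_error", "error")))
}

stopData <- function(...) {
  stop(errorCondition(paste0(...), class = c("sgd_data_error", "error")))
}

## Seed scoping: functions that accept `seed` must not disturb the caller's
## RNG stream. Restores (or removes) .Random.seed on exit.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Derive a stage-specific child seed from a master seed, kept < 2^31.
childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483647L)
}
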
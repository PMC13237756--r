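# Seed plumbing: every stochastic stage draws its own seed deterministically
# from the master seed plus a stage tag, so stages are reproducible in
# isolation and independent of execution order.

#' Derive a stage seed from a master seed and a tag
#'
#' @param seed master integer seed
#' @param tag character stage tag (e.g. "cohort", "rec P01 closed")
#' @return integer in [0, 2^31 - 2]
#' @export
deriveSeed <- function(seed, tag) {
  h <- 0
  for (cc in utf8ToInt(tag)) h <- (h * 31 + cc) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 1103 + h) %% 2147483647)
}

# Evaluate expr under a given seed, restoring the caller's RNG state after.
# The promise is forced in the caller's frame, so assignments inside expr
# land where the call sits.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (hadSeed) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Labeled-error helper: all user-facing errors carry a short context label.
stopLabeled <- function(label, ...) {
  stop(sprintf("[%s] %s", label, paste0(...)), call. = FALSE)
}
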
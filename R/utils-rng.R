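#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded package
#' operations never perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named substream seed from a root seed
#'
#' All randomness in the package flows from one root seed; each stage
#' (cohort, features, images, matching, folds, ...) draws from its own
#' named substream so stages can be regenerated independently.
#'
#' @param seed Integer root seed.
#' @param stream Character substream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 1000003
  # 48271 is the classic Lehmer multiplier; arithmetic stays < 2^53 in doubles
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
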
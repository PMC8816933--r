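#' Derive a named-stream sub-seed from a global seed
#'
#' Every stochastic stage of the pipeline draws from its own RNG stream so that
#' stages are independently reproducible: re-running one stage with the same
#' global seed gives bit-identical output regardless of what ran before it.
#' The sub-seed is a deterministic hash of the stream name mixed with the
#' global seed, kept below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stream character stream name (e.g. `"phantom"`, `"cohort"`).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' stream_seed(1, "cohort")
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  h <- (h + (abs(seed) %% m) * 7919) %% m
  as.integer(h %% (m - 2L) + 1L)
}

#' Evaluate an expression under a named RNG stream
#'
#' Sets the RNG to `stream_seed(seed, stream)`, evaluates `expr`, and restores
#' the caller's `.Random.seed` afterwards, so library code never perturbs the
#' user's RNG state.
#'
#' @param seed integer global seed.
#' @param stream character stream name.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_stream <- function(seed, stream, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(stream_seed(seed, stream))
  expr
}
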
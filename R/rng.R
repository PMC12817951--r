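#' Independent reproducible RNG streams
#'
#' A lightweight stream object holding its own Mersenne-Twister state, so
#' that a consumer (e.g. data augmentation) draws reproducible random numbers
#' independently of any other randomness in the session (weight
#' initialization, batch shuffling). `with_stream()` evaluates an expression
#' with the stream's state installed as the session RNG, saves the advanced
#' state back into the stream, and restores the caller's RNG untouched.
#'
#' @param seed integer seed initializing the stream.
#' @return `rng_stream()` returns an object of class `rng_stream`;
#'   `with_stream()` returns the value of `expr`.
#' @examples
#' s <- rng_stream(1)
#' a <- with_stream(s, runif(3))
#' b <- with_stream(s, runif(3))   # continues the stream; a != b
#' identical(a, with_stream(rng_stream(1), runif(3)))
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  e$state <- get(".Random.seed", envir = globalenv())
  restore_rng(old)
  class(e) <- "rng_stream"
  e
}

#' @rdname rng_stream
#' @param stream an `rng_stream`.
#' @param expr expression to evaluate under the stream's RNG state.
#' @export
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    restore_rng(old)
  })
  expr
}
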
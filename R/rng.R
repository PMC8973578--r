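#' Explicit random-number streams
#'
#' All stochastic generator functions in traplife draw from an explicit
#' stream object rather than the global R random state. A stream carries its
#' own Mersenne-Twister state, so two mechanisms (say, trap occupancy and
#' lifespan sampling) can be given independent, individually reproducible
#' sequences, and changing how many draws one mechanism makes does not
#' perturb the other.
#'
#' @param seed Single finite integer seed.
#' @return An object of class `rng_stream`.
#' @examples
#' r <- rng_stream(1)
#' with_stream(r, runif(2))
#' @seealso [substream()], [with_stream()]
#' @export
rng_stream <- function(seed) {
  if (missing(seed) || length(seed) != 1L || !is.numeric(seed) || !is.finite(seed))
    stop("rng_stream() requires a single finite integer seed")
  e <- new.env(parent = emptyenv())
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  if (is.null(old)) {
    rm(".Random.seed", envir = genv)
  } else {
    assign(".Random.seed", old, envir = genv)
  }
  class(e) <- "rng_stream"
  e
}

#' Derive a named substream from a master seed
#'
#' A single experiment seed fans out to named substreams (e.g. `"occupancy"`,
#' `"run2"`) so each mechanism of the simulation has its own reproducible
#' sequence. The derived seed is kept below 2^31.
#'
#' @param seed Master integer seed.
#' @param name Character label of the substream.
#' @return An `rng_stream`.
#' @export
substream <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  rng_stream(derive_seed(seed, name))
}

# deterministic integer hash of (seed, name), < 2^31
derive_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * (31 ^ (seq_along(codes) %% 5)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973) %% 2147483629)
}

#' Evaluate an expression using a stream's random state
#'
#' Swaps the stream's state into the R session for the duration of `expr`,
#' then saves the advanced state back into the stream and restores the
#' previous global state.
#'
#' @param rng An `rng_stream`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_stream <- function(rng, expr) {
  if (!inherits(rng, "rng_stream"))
    stop("an explicit rng stream is required (see rng_stream())")
  genv <- globalenv()
  old <- get0(".Random.seed", envir = genv, inherits = FALSE)
  assign(".Random.seed", rng$state, envir = genv)
  on.exit({
    rng$state <- get(".Random.seed", envir = genv, inherits = FALSE)
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  expr
}
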
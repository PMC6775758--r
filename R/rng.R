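# Named RNG substreams. Each stream owns a private generator state, so draws on
# one path (e.g. intertrial intervals) never perturb another (e.g. the mouse),
# and a fixed root seed yields byte-identical session logs.

#' Create an independent random-number substream
#'
#' A substream is an environment holding a private Mersenne-Twister state.
#' Draws are made with [stream_eval()], which swaps the stream state into the
#' session generator, evaluates, and restores whatever global state existed
#' before, so package simulations never disturb the caller's RNG.
#'
#' @param seed Integer seed (< 2^31).
#' @return An object of class `rng_stream`.
#' @seealso [rng_streams()], [stream_eval()]
#' @export
new_rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate a random expression on a substream
#'
#' @param stream An [new_rng_stream()] object.
#' @param fn A zero-argument function performing the random draws.
#' @return The value of `fn()`.
#' @export
stream_eval <- function(stream, fn) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

# Deterministic seed for a named substream of a root seed (kept < 2^31 - 1).
substream_seed <- function(root_seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1048573
  (abs(as.numeric(root_seed)) * 1021 + h * 7919 + 1) %% 2147483647
}

#' Build the named substreams used by a session
#'
#' @param root_seed Integer root seed of the session.
#' @param names Character vector of substream names.
#' @return A named list of `rng_stream` objects.
#' @export
rng_streams <- function(root_seed,
                        names = c("iti", "refrain", "category", "auto",
                                  "mouse", "background", "engagement")) {
  stats::setNames(
    lapply(names, function(nm) new_rng_stream(substream_seed(root_seed, nm))),
    names
  )
}
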
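# Named RNG streams, each a saved .Random.seed, so that every stochastic
# component (pair noise, events, model fixtures) consumes an independent,
# serializable stream. Swapping streams in and out of the global RNG state
# keeps trajectories bitwise reproducible across checkpoint/restart.

.stream_names <- c("engine", "events", "model")

rng_init <- function(seed) {
  streams <- list()
  old <- .save_global_seed()
  on.exit(.restore_global_seed(old), add = TRUE)
  for (i in seq_along(.stream_names)) {
    # distinct sub-seed per stream, kept inside 32-bit integer range
    sub <- (as.double(seed) * 7919 + i * 104729) %% 2147483647
    set.seed(as.integer(sub))
    streams[[.stream_names[i]]] <- get(".Random.seed", envir = globalenv())
  }
  streams
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Evaluate code under one of a universe's named RNG streams
#'
#' The universe owns independent random-number streams (`"engine"` for pair
#' noise and thermal forces, `"events"` for event-system draws, `"model"` for
#' fixture generation). `with_stream()` swaps the named stream into the global
#' RNG state, evaluates `code`, and saves the advanced stream back, leaving
#' the caller's RNG state untouched.
#'
#' @param universe a [universe] object
#' @param name one of `"engine"`, `"events"`, `"model"`
#' @param code expression to evaluate
#' @return the value of `code`
#' @export
with_stream <- function(universe, name, code) {
  stopifnot(name %in% .stream_names)
  old <- .save_global_seed()
  assign(".Random.seed", universe$rng[[name]], envir = globalenv())
  on.exit({
    universe$rng[[name]] <- get(".Random.seed", envir = globalenv())
    .restore_global_seed(old)
  }, add = TRUE)
  eval(substitute(code), envir = parent.frame())
}
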
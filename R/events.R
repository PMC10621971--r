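# The event system injects user-defined instructions into the simulation
# loop. Events fire during the Update stage (after integration and species
# transport), in registration order, and may create or destroy particles
# and bonds; mutations take effect before the next Force stage.

#' Register an event
#'
#' The callback `fn(u, time)` is invoked on every step whose (pre-step)
#' counter is a multiple of `period_steps` (1 = every step). Returning the
#' string `"stop"` terminates [sim_run()] at the end of the current step.
#' Frequencies are expressed in steps, not continuous time, so firing is
#' exactly reproducible.
#'
#' @param u a [universe]
#' @param fn callback `function(u, time)`
#' @param period_steps positive integer firing period
#' @param name optional registry name (required for JSON serialization)
#' @return integer event handle
#' @export
register_event <- function(u, fn, period_steps = 1L, name = NULL) {
  stopifnot(is.function(fn))
  period_steps <- as.integer(period_steps)
  if (period_steps < 1L) stop("`period_steps` must be >= 1")
  id <- u$event_id_next
  u$event_id_next <- id + 1L
  if (!is.null(name)) register_callback(name, fn)
  u$events <- c(u$events, list(list(id = id, period = period_steps,
                                    fn = fn, name = name)))
  id
}

#' Remove a registered event
#' @param u a [universe]
#' @param handle event handle from [register_event()]
#' @export
remove_event <- function(u, handle) {
  hit <- which(vapply(u$events, function(e) e$id == handle, TRUE))
  if (!length(hit)) stop(sprintf("unknown event handle %s", handle))
  u$events[hit] <- NULL
  invisible(u)
}

#' Uniformly select a random live particle of a type
#'
#' Draws from the universe's `"events"` RNG stream; returns `NULL` when the
#' type currently has no live particles.
#'
#' @param u a [universe]
#' @param type type name or handle (must be registered)
#' @return a particle id, or `NULL`
#' @export
select_random_particle <- function(u, type) {
  t <- get_type(u, type)
  ids <- particle_ids(u, t$name)
  if (!length(ids)) return(NULL)
  ids[with_stream(u, "events", sample.int(length(ids), 1L))]
}
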
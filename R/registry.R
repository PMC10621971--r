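# Package-level callback registry. JSON state documents reference custom
# potentials, reactions and event callbacks by registered name only (JSON is
# data, not code); importing a document requires the same names to be
# registered, which the bundled model builders do for their own callbacks.

.callbacks <- new.env(parent = emptyenv())

#' Register a named callback for serialization
#'
#' @param name unique callback name
#' @param fn the function
#' @param overwrite replace an existing registration
#' @export
register_callback <- function(name, fn, overwrite = TRUE) {
  if (!overwrite && !is.null(.callbacks[[name]])) {
    stop(sprintf("callback '%s' is already registered", name))
  }
  .callbacks[[name]] <- fn
  invisible(name)
}

#' @rdname register_callback
#' @export
get_callback <- function(name) {
  fn <- .callbacks[[name]]
  if (is.null(fn)) {
    stop(sprintf("callback '%s' is not registered; register it before importing state that references it", name))
  }
  fn
}
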
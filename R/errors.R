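# Classed conditions so callers can distinguish failure modes with
# tryCatch(..., speckit_<class> = ...). All package errors inherit
# "speckit_error".

spk_condition <- function(class, message, ..., call = NULL) {
  structure(
    class = c(paste0("speckit_", class), "speckit_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
}

spk_stop <- function(class, message, ...) {
  stop(spk_condition(class, message, ...))
}

spk_warning <- function(class, message, ...) {
  warning(structure(
    class = c(paste0("speckit_", class), "speckit_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
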
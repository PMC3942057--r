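# Typed conditions shared across the package. Each maps to a CLI exit code:
# validation 2, data integrity 3, insufficient data 4.

stop_typed <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cohortsig_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

stop_validation <- function(msg, ...) stop_typed("validation_error", msg, ...)
stop_data_integrity <- function(msg, ...) stop_typed("data_integrity_error", msg, ...)
stop_insufficient_data <- function(msg, ...) stop_typed("insufficient_data_error", msg, ...)
stop_sizing <- function(msg, ...) stop_typed("sizing_error", msg, ...)

assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) stop_validation(msg, ...)
  invisible(TRUE)
}
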
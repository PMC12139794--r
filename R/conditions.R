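# Condition constructors shared across the package.  Validation errors signal
# bad user input (CLI exit 2); format/io errors signal unreadable or unwritable
# files (CLI exit 3).

stop_validation <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("watsite_validation_error", "watsite_error")))
}

stop_format <- function(msg) {
  stop(errorCondition(msg, class = c("watsite_format_error", "watsite_error")))
}

stop_io <- function(msg) {
  stop(errorCondition(msg, class = c("watsite_io_error", "watsite_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
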
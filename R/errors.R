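# Classed conditions used across the package.
#
# spherofall_invalid  -- bad parameters / configuration (CLI exit code 2)
# spherofall_data     -- valid request, unusable data   (CLI exit code 3)

stop_invalid <- function(msg, class = NULL, call. = FALSE) {
  stop(structure(
    class = c(class, "spherofall_invalid", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

stop_data <- function(msg, class = NULL, call. = FALSE) {
  stop(structure(
    class = c(class, "spherofall_data", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

warn_spherofall <- function(msg, class = NULL) {
  warning(structure(
    class = c(class, "spherofall_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}
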
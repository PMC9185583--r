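# Classed conditions so callers (and the CLI) can distinguish configuration
# mistakes from bad input data and from numerical/segmentation failures.

exo_abort <- function(msg, class) {
  stop(errorCondition(msg,
    class = c(class, "exolift_error")))
}

abort_config  <- function(msg) exo_abort(msg, "exolift_config_error")
abort_input   <- function(msg) exo_abort(msg, "exolift_input_error")
abort_segment <- function(msg) exo_abort(msg, "exolift_segmentation_error")
abort_numeric <- function(msg) exo_abort(msg, "exolift_numeric_error")

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_config(sprintf("`%s` must be a single finite number", name))
  }
}
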
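# Classed conditions so callers (and tests) can distinguish failure modes.

stop_strab <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "strab_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Shared argument checks ------------------------------------------------

assert_point <- function(p, what = "point") {
  if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p)))
    stop_strab("strab_input_error", "%s must be a finite numeric (x, y) pair", what)
  as.numeric(p)
}

assert_mask <- function(mask, what = "mask") {
  if (!is.matrix(mask))
    stop_strab("strab_input_error", "%s must be a matrix", what)
  if (is.logical(mask)) return(mask)
  mask != 0
}
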
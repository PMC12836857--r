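# Structured conditions so callers (and the CLI exit-code map) can tell
# I/O, validation and quantification failures apart.

slogp_stop <- function(msg, class = "slicelogp_validation_error", call. = sys.call(-1L)) {
  cond <- structure(
    class = c(class, "slicelogp_error", "error", "condition"),
    list(message = msg, call = call.)
  )
  stop(cond)
}

slogp_io_stop <- function(msg) slogp_stop(msg, class = "slicelogp_io_error")
slogp_quant_stop <- function(msg) slogp_stop(msg, class = "slicelogp_quant_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Internal trapezoid over an ascending grid.
trapz_asc <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}
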
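## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## classed conditions so callers/tests can distinguish failure modes
stop_resolvst <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("resolvst_", class), "resolvst_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

## truncated normal initializer (values resampled outside +-2 sd)
rtruncnorm02 <- function(n, sd = 0.02) {
  x <- stats::rnorm(n, 0, sd)
  bad <- abs(x) > 2 * sd
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 2 * sd
  }
  x
}
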
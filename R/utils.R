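# Internal helpers: classed error conditions and intensity quantization.

srs_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "srsphasor_error", "error")))
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    srs_error("srsphasor_invalid_parameter", sprintf("%s must be finite", what))
  }
  invisible(x)
}

# Intensity storage grid. Stacks travel as 16-bit TIFF samples of
# data/scale in [0,1] (16 bits cover the 12-bit acquisition depth of
# typical SRS detection); snapping generator output onto this grid makes
# write -> read round trips exact.
INTENSITY_LEVELS <- 65535

quantize_intensity <- function(x, scale = NULL) {
  if (is.null(scale)) scale <- max(x, 1e-300)
  if (scale <= 0) scale <- 1
  k <- round(pmin(pmax(x / scale, 0), 1) * INTENSITY_LEVELS)
  q <- (k / INTENSITY_LEVELS) * scale  # same expression as the read path
  if (!is.null(dim(x))) dim(q) <- dim(x)
  q
}

# nearest grid sample in [0,1], biased +half a quantum because the TIFF
# writer truncates; floor((k + 0.5)/L * L) == k for all k
to_storage_units <- function(x, scale) {
  k <- round(pmin(pmax(x / scale, 0), 1) * INTENSITY_LEVELS)
  pmin((k + 0.5) / INTENSITY_LEVELS, 1)
}

nearest_channel <- function(axis_values, shift, tol = 5) {
  k <- which.min(abs(axis_values - shift))
  if (abs(axis_values[k] - shift) > tol) {
    srs_error("srsphasor_axis_mismatch",
              sprintf("no channel within %g cm^-1 of %g (nearest: %.1f)",
                      tol, shift, axis_values[k]))
  }
  k
}
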
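#' Hyperspectral image stack container
#'
#' A `hyperstack` holds a nonnegative intensity array with the spectral
#' channel as the last dimension — `(y, x, channel)` for a single focal
#' plane or `(z, y, x, channel)` for a z-stack — together with its
#' `wavenumber_axis` and the physical voxel geometry. Indices are given in
#' `(z, y, x)` order; physical sizes are carried separately in micrometres.
#'
#' @param data Numeric array, 3D `(y, x, channel)` or 4D `(z, y, x, channel)`,
#'   finite and nonnegative.
#' @param axis A `wavenumber_axis` whose length matches the last dimension.
#' @param pixel_size Lateral pixel size in micrometres.
#' @param z_step Axial step in micrometres (z-stacks only; `NULL` otherwise).
#' @return A `hyperstack` object.
#' @export
hyperstack <- function(data, axis, pixel_size, z_step = NULL) {
  d <- dim(data)
  if (is.null(d) || !(length(d) %in% c(3L, 4L))) {
    srs_error("srsphasor_invalid_parameter",
              "data must be a 3D (y,x,channel) or 4D (z,y,x,channel) array")
  }
  if (d[length(d)] != axis$n_channels) {
    srs_error("srsphasor_format",
              sprintf("last dimension (%d) != axis channels (%d)",
                      d[length(d)], axis$n_channels))
  }
  if (anyNA(data) || any(!is.finite(data)) || any(data < 0)) {
    srs_error("srsphasor_invalid_parameter",
              "intensities must be finite and >= 0")
  }
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    srs_error("srsphasor_invalid_parameter", "pixel_size must be > 0")
  }
  if (length(d) == 4L && (is.null(z_step) || z_step <= 0)) {
    srs_error("srsphasor_geometry", "z-stacks require a positive z_step")
  }
  structure(list(data = data, axis = axis, pixel_size = pixel_size,
                 z_step = if (length(d) == 4L) z_step else NULL),
            class = "hyperstack")
}

#' @export
print.hyperstack <- function(x, ...) {
  d <- dim(x$data)
  geom <- if (length(d) == 4L) {
    sprintf("%d z-planes (step %g um) x %d x %d px", d[1], x$z_step, d[2], d[3])
  } else {
    sprintf("%d x %d px", d[1], d[2])
  }
  cat(sprintf("hyperstack: %s, %d channels (%.1f-%.1f cm^-1), pixel %g um\n",
              geom, x$axis$n_channels, min(x$axis$values), max(x$axis$values),
              x$pixel_size))
  invisible(x)
}

spatial_dim <- function(stack) {
  d <- dim(stack$data)
  d[-length(d)]
}

# flatten to (n_voxels, n_channels); voxels in array order
stack_matrix <- function(stack) {
  d <- dim(stack$data)
  matrix(stack$data, prod(d[-length(d)]), d[length(d)])
}

#' Spectral average-intensity projection
#'
#' Pixelwise mean over the spectral channels; the standard projection used
#' to define the intensity threshold mask before phasor analysis. For a
#' z-stack the result keeps the `(z, y, x)` spatial shape.
#'
#' @param stack A `hyperstack`.
#' @return Numeric array with the stack's spatial shape.
#' @export
average_projection <- function(stack) {
  d <- dim(stack$data)
  out <- rowMeans(stack_matrix(stack))
  dim(out) <- d[-length(d)]
  out
}

#' Maximum-intensity projection of a single-channel z-stack
#'
#' Collapses a `(z, y, x)` volume to a 2D image by the maximum voxel
#' intensity along z, the standard rendering of lipid-droplet z-stacks
#' acquired at a single Raman shift.
#'
#' @param volume Numeric 3D array `(z, y, x)`.
#' @return 2D numeric matrix `(y, x)`.
#' @export
max_projection <- function(volume) {
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) {
    srs_error("srsphasor_invalid_parameter", "volume must be a 3D (z,y,x) array")
  }
  apply(volume, c(2, 3), max)
}

#' Extract the image at (or nearest to) a Raman shift
#'
#' @param stack A `hyperstack`.
#' @param shift Raman shift in cm^-1; the nearest channel is used.
#' @param tol Maximum allowed distance to the nearest channel (cm^-1).
#' @return The spatial array at that channel.
#' @export
channel_image <- function(stack, shift, tol = 5) {
  k <- nearest_channel(stack$axis$values, shift, tol)
  d <- dim(stack$data)
  m <- stack_matrix(stack)[, k]
  dim(m) <- d[-length(d)]
  m
}

#' Intensity-threshold background mask
#'
#' Separates cells from background (noncell areas) on an average-intensity
#' projection, either by Otsu's method or a manual threshold. Foreground is
#' every pixel at or above the threshold; the method and threshold are
#' recorded in the mask's provenance.
#'
#' @param projection Numeric array (any spatial shape), e.g. from
#'   [average_projection()].
#' @param method `"otsu"` (default) or `"manual"`.
#' @param manual_threshold Threshold used when `method = "manual"`.
#' @return A `pixel_mask`: logical array plus a `provenance` attribute
#'   listing `method` and `threshold`.
#' @export
background_mask <- function(projection, method = c("otsu", "manual"),
                            manual_threshold = NULL) {
  method <- match.arg(method)
  rng <- range(projection)
  if (method == "otsu") {
    if (diff(rng) == 0) {
      srs_error("srsphasor_degenerate_histogram",
                "constant image: Otsu threshold is undefined")
    }
    x01 <- (projection - rng[1]) / diff(rng)
    # 2D slice-wise is fine: EBImage::otsu needs a matrix; pool all voxels
    th01 <- EBImage::otsu(EBImage::Image(matrix(x01, length(x01), 1)),
                          range = c(0, 1), levels = 256L)
    threshold <- rng[1] + th01 * diff(rng)
  } else {
    if (is.null(manual_threshold) || !is.finite(manual_threshold)) {
      srs_error("srsphasor_invalid_parameter",
                "manual method requires a finite manual_threshold")
    }
    threshold <- manual_threshold
  }
  mask <- projection >= threshold
  structure(mask,
            provenance = list(method = method, threshold = threshold),
            class = c("pixel_mask", class(mask)))
}
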
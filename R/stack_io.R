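#' Write / read hyperspectral stacks as multi-frame TIFF + YAML sidecar
#'
#' Stacks are exchanged as multi-frame grayscale TIFF with one frame per
#' spectral channel, ordered z-major then channel-minor (all channels of
#' z-plane 1, then z-plane 2, ...). TIFF samples are 16-bit and store
#' `data / intensity_scale` rounded to the storage grid; the scale,
#' wavenumber axis, and voxel geometry travel in a YAML sidecar. There is no silent fallback to a channel-index
#' axis: the sidecar is required. Data written by [write_stack()] (and
#' phantoms from [generate_phantom()], which are pre-snapped onto the
#' storage grid) round-trip bit-exactly.
#'
#' @param stack A [hyperstack()].
#' @param path TIFF file path.
#' @param sidecar_path YAML sidecar path; defaults to `path` + `.yaml`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar_path = paste0(path, ".yaml")) {
  d <- dim(stack$data)
  N <- d[length(d)]
  scale <- max(stack$data)
  if (scale <= 0) scale <- 1
  if (length(d) == 4L) {
    frames <- vector("list", d[1] * N)
    for (z in seq_len(d[1])) {
      for (k in seq_len(N)) {
        frames[[(z - 1L) * N + k]] <- to_storage_units(stack$data[z, , , k], scale)
      }
    }
  } else {
    frames <- lapply(seq_len(N),
                     function(k) to_storage_units(stack$data[, , k], scale))
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, reduce = FALSE,
                  compression = "LZW")
  ax <- stack$axis
  meta <- list(
    format = "srsphasor-hyperstack",
    axis = list(values = as.numeric(ax$values),
                stokes_wavelength = ax$stokes_wavelength,
                retune_step = ax$retune_step,
                acquisition_order = ax$acquisition_order),
    n_channels = N,
    n_z = if (length(d) == 4L) d[1] else 1L,
    spatial_shape = as.integer(d[-length(d)]),
    pixel_size = stack$pixel_size,
    z_step = stack$z_step,
    intensity_scale = scale,
    frame_order = "z_major_channel_minor")
  yaml::write_yaml(meta, sidecar_path, precision = 17L)  # doubles round-trip
  invisible(path)
}

#' @param path TIFF path to read.
#' @param sidecar_path YAML sidecar path.
#' @rdname write_stack
#' @export
read_stack <- function(path, sidecar_path = paste0(path, ".yaml")) {
  if (!file.exists(sidecar_path)) {
    srs_error("srsphasor_format",
              sprintf("sidecar '%s' not found; an explicit wavenumber axis is required",
                      sidecar_path))
  }
  meta <- yaml::read_yaml(sidecar_path)
  frames <- tiff::readTIFF(path, all = TRUE)
  N <- meta$n_channels
  nz <- meta$n_z %||% 1L
  if (length(frames) %% N != 0 || length(frames) != nz * N) {
    srs_error("srsphasor_format",
              sprintf("frame count %d does not match %d z-plane(s) x %d channel(s)",
                      length(frames), nz, N))
  }
  axm <- meta$axis
  axis <- structure(
    list(values = as.numeric(axm$values), n_channels = N,
         stokes_wavelength = axm$stokes_wavelength,
         retune_step = axm$retune_step,
         pump_wavelengths = 1e7 / (1e7 / axm$stokes_wavelength + as.numeric(axm$values)),
         acquisition_order = axm$acquisition_order),
    class = "wavenumber_axis")
  scale <- meta$intensity_scale %||% 1
  fd <- dim(frames[[1]])
  if (nz > 1L) {
    data <- array(0, dim = c(nz, fd[1], fd[2], N))
    for (z in seq_len(nz)) {
      for (k in seq_len(N)) {
        data[z, , , k] <- frames[[(z - 1L) * N + k]] * scale
      }
    }
    hyperstack(data, axis, meta$pixel_size, meta$z_step)
  } else {
    data <- array(0, dim = c(fd[1], fd[2], N))
    for (k in seq_len(N)) data[, , k] <- frames[[k]] * scale
    hyperstack(data, axis, meta$pixel_size)
  }
}

#' Write / read integer label images as 8-bit TIFF
#'
#' Label and mask images use 8-bit TIFF with 0 = background; a z-stack is
#' written as one frame per z-plane.
#'
#' @param labels Integer array (2D or 3D `(z, y, x)`), values 0-255.
#' @param path TIFF file path.
#' @return `path` invisibly (writer); integer array (reader).
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 255 || min(labels) < 0) {
    srs_error("srsphasor_invalid_parameter", "labels must be in 0..255")
  }
  d <- dim(labels)
  if (length(d) == 3L) {
    frames <- lapply(seq_len(d[1]), function(z) labels[z, , ] / 255)
  } else {
    frames <- list(labels / 255)
  }
  tiff::writeTIFF(frames, path, bits.per.sample = 8L, compression = "LZW")
  invisible(path)
}

#' @rdname write_label_tiff
#' @export
read_label_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (length(frames) == 1L) {
    out <- round(frames[[1]] * 255)
  } else {
    fd <- dim(frames[[1]])
    out <- array(0L, dim = c(length(frames), fd[1], fd[2]))
    for (z in seq_along(frames)) out[z, , ] <- round(frames[[z]] * 255)
  }
  storage.mode(out) <- "integer"
  out
}
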
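#' Ratiometric CH2/CH3 lipid map
#'
#' Pixelwise ratio \eqn{R = I(2851)/I(2930)} of the CH2 symmetric stretch
#' (lipids) to the CH3 stretch (proteins), the standard ratiometric readout
#' of cellular lipid content. Channels are matched to the requested shifts
#' by nearest neighbor (within `tol` cm^-1). The ratio is computed on
#' foreground pixels only; pixels whose denominator is at or below `eps`
#' are flagged undefined (`NA`). R is invariant to overall intensity
#' scaling of the stack. Display clamping (e.g. the usual 0-1 rainbow LUT)
#' is a rendering choice and never applied to the data.
#'
#' @param stack A [hyperstack()]; alternatively supply `num_image` and
#'   `den_image` directly and leave `stack` `NULL`.
#' @param shift_num,shift_den Numerator/denominator Raman shifts in cm^-1.
#' @param mask Optional logical foreground array.
#' @param num_image,den_image Optional pre-extracted single-frequency
#'   images (used when `stack` is `NULL`).
#' @param eps Denominator threshold below which the ratio is undefined.
#' @param tol Channel-matching tolerance in cm^-1.
#' @return A `ratio_map`: list with `ratio` (array, `NA` off-foreground or
#'   undefined), `shift_num`, `shift_den`, `provenance`.
#' @export
ratio_map <- function(stack = NULL, shift_num = 2851, shift_den = 2930,
                      mask = NULL, num_image = NULL, den_image = NULL,
                      eps = 1e-9, tol = 5) {
  if (!is.null(stack)) {
    num_image <- channel_image(stack, shift_num, tol)
    den_image <- channel_image(stack, shift_den, tol)
  }
  if (is.null(num_image) || is.null(den_image)) {
    srs_error("srsphasor_invalid_parameter",
              "supply either a stack or both single-frequency images")
  }
  if (!identical(dim(num_image), dim(den_image))) {
    srs_error("srsphasor_invalid_parameter", "image shapes differ")
  }
  r <- num_image / den_image
  r[den_image <= eps] <- NA_real_
  if (!is.null(mask)) r[!mask] <- NA_real_
  structure(list(ratio = r, shift_num = shift_num, shift_den = shift_den,
                 provenance = list(eps = eps, tol = tol,
                                   masked = !is.null(mask))),
            class = "ratio_map")
}

#' Per-cell mean CH2/CH3 ratio
#'
#' @param rmap A `ratio_map`.
#' @param cell_instances Integer instance array (0 = background) matching
#'   the ratio map's shape.
#' @return data.frame with `cell`, `mean_ratio`, `n_pixels`. A cell with no
#'   defined foreground pixels yields `NA` with a warning.
#' @export
per_cell_ratio <- function(rmap, cell_instances) {
  if (!identical(dim(rmap$ratio), dim(cell_instances))) {
    srs_error("srsphasor_invalid_parameter", "instance mask shape mismatch")
  }
  ids <- sort(setdiff(unique(as.vector(cell_instances)), 0L))
  rows <- lapply(ids, function(i) {
    v <- rmap$ratio[cell_instances == i]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning(sprintf("cell %d has no defined ratio pixels", i))
      data.frame(cell = i, mean_ratio = NA_real_, n_pixels = 0L)
    } else {
      data.frame(cell = i, mean_ratio = mean(v), n_pixels = length(v))
    }
  })
  do.call(rbind, rows)
}

# 26-connected component labeling of a 3D logical volume (BFS).
# No installed R package labels in 3D, so this is implemented here.
label_components_3d <- function(fg) {
  d <- dim(fg)
  stopifnot(length(d) == 3L)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  off <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  lab <- array(0L, d)
  nextlab <- 0L
  idx_fg <- which(fg)
  for (start in idx_fg) {
    if (lab[start] != 0L) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      i0 <- (cur - 1L)
      z <- i0 %% nz + 1L
      y <- (i0 %/% nz) %% ny + 1L
      x <- i0 %/% (nz * ny) + 1L
      for (o in seq_len(nrow(off))) {
        zz <- z + off[o, 1]; yy <- y + off[o, 2]; xx <- x + off[o, 3]
        keep <- zz >= 1L & zz <= nz & yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
        if (!any(keep)) next
        nb <- (xx[keep] - 1L) * nz * ny + (yy[keep] - 1L) * nz + zz[keep]
        nb <- nb[fg[nb] & lab[nb] == 0L]
        if (length(nb)) {
          lab[nb] <- nextlab
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' 3D lipid-droplet segmentation and volumetry
#'
#' Segments lipid droplets from a single-frequency (typically 2851 cm^-1)
#' z-stack: intensity threshold (Otsu within the optional foreground mask,
#' or manual), 26-connected component labeling in 3D, a minimum-size
#' filter, then per-droplet volume as voxel count x pixel_size^2 x z_step.
#'
#' @param volume Numeric 3D `(z, y, x)` array of intensities.
#' @param pixel_size Lateral pixel size, micrometres.
#' @param z_step Axial step, micrometres; required (geometry error if
#'   missing).
#' @param method `"otsu"` or `"manual"`.
#' @param manual_threshold Threshold for `method = "manual"`.
#' @param min_voxels Minimum component size kept (default 4).
#' @param mask Optional logical array restricting thresholding/segmentation
#'   (e.g. cell foreground).
#' @param cell_instances Optional integer array assigning voxels to cells;
#'   each droplet is attributed to the cell holding its majority voxels.
#' @return List with `droplets` (data.frame: `droplet`, `cell`,
#'   `voxel_count`, `volume_um3`, centroid `z`/`y`/`x` in voxel units,
#'   `threshold`) and `labels` (integer volume).
#' @export
ld_segment_3d <- function(volume, pixel_size, z_step,
                          method = c("otsu", "manual"),
                          manual_threshold = NULL, min_voxels = 4L,
                          mask = NULL, cell_instances = NULL) {
  method <- match.arg(method)
  if (missing(z_step) || is.null(z_step) || !is.finite(z_step) || z_step <= 0) {
    srs_error("srsphasor_geometry", "volumetry requires a positive z_step")
  }
  d <- dim(volume)
  if (is.null(d) || length(d) != 3L) {
    srs_error("srsphasor_invalid_parameter", "volume must be 3D (z,y,x)")
  }
  vals <- if (is.null(mask)) volume else volume[mask]
  if (method == "otsu") {
    bm <- background_mask(array(vals, c(length(vals), 1)), "otsu")
    threshold <- attr(bm, "provenance")$threshold
  } else {
    if (is.null(manual_threshold)) {
      srs_error("srsphasor_invalid_parameter", "manual_threshold required")
    }
    threshold <- manual_threshold
  }
  fg <- volume >= threshold
  if (!is.null(mask)) fg <- fg & mask
  lab <- label_components_3d(fg)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  voxvol <- pixel_size^2 * z_step
  if (!length(keep)) {
    return(list(droplets = data.frame(droplet = integer(0), cell = integer(0),
                                      voxel_count = integer(0),
                                      volume_um3 = numeric(0),
                                      z = numeric(0), y = numeric(0),
                                      x = numeric(0)),
                labels = array(0L, d), threshold = threshold))
  }
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  lab_new <- array(0L, d)
  nz_idx <- lab > 0L
  lab_new[nz_idx] <- relabel[lab[nz_idx]]
  rows <- lapply(seq_along(keep), function(i) {
    vidx <- which(lab_new == i)
    i0 <- vidx - 1L
    z <- i0 %% d[1] + 1L
    y <- (i0 %/% d[1]) %% d[2] + 1L
    x <- i0 %/% (d[1] * d[2]) + 1L
    cell <- if (is.null(cell_instances)) NA_integer_ else {
      cv <- cell_instances[vidx]
      cv <- cv[cv > 0]
      if (length(cv)) as.integer(names(which.max(table(cv)))) else NA_integer_
    }
    data.frame(droplet = i, cell = cell, voxel_count = length(vidx),
               volume_um3 = length(vidx) * voxvol,
               z = mean(z), y = mean(y), x = mean(x))
  })
  list(droplets = do.call(rbind, rows), labels = lab_new, threshold = threshold)
}

#' Per-cell percent area of a segmented class
#'
#' 100 x (class pixels in cell) / (foreground pixels in cell), the per-cell
#' percent-area readout used to compare steatosis and phospholipidosis
#' burdens across treatments.
#'
#' @param labels Integer class-label array (e.g. from [segment_by_rois()]).
#' @param class_label Label id (integer) to quantify.
#' @param cell_instances Integer instance array (0 = background).
#' @param foreground Optional logical array defining each cell's reference
#'   area; defaults to `cell_instances > 0`.
#' @return data.frame with `cell`, `percent_area`, `class_pixels`,
#'   `cell_pixels`.
#' @export
percent_area <- function(labels, class_label, cell_instances,
                         foreground = NULL) {
  if (!identical(dim(labels), dim(cell_instances))) {
    srs_error("srsphasor_invalid_parameter", "label/instance shape mismatch")
  }
  if (is.null(foreground)) foreground <- cell_instances > 0L
  ids <- sort(setdiff(unique(as.vector(cell_instances)), 0L))
  rows <- lapply(ids, function(i) {
    in_cell <- cell_instances == i & foreground
    denom <- sum(in_cell)
    num <- sum(in_cell & labels == class_label)
    data.frame(cell = i,
               percent_area = if (denom > 0) 100 * num / denom else NA_real_,
               class_pixels = num, cell_pixels = denom)
  })
  do.call(rbind, rows)
}

#' Pixelwise colocalization (Pearson r)
#'
#' Pearson correlation between two single-frequency images over masked
#' pixels — e.g. the total-lipid channel at 2851 cm^-1 against the alkyne
#' channel at 2233 cm^-1 to test whether an alkyne-tagged drug accumulates
#' in lipid-rich inclusions.
#'
#' @param image_a,image_b Numeric arrays of identical shape.
#' @param mask Optional logical array; at least 10 masked pixels required.
#' @return Pearson r in \eqn{[-1, 1]}.
#' @export
colocalize <- function(image_a, image_b, mask = NULL) {
  if (!identical(dim(image_a), dim(image_b))) {
    srs_error("srsphasor_invalid_parameter", "image shapes differ")
  }
  a <- as.vector(image_a); b <- as.vector(image_b)
  if (!is.null(mask)) { a <- a[mask]; b <- b[mask] }
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 10) {
    srs_error("srsphasor_invalid_parameter",
              "need at least 10 masked pixels for colocalization")
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    srs_error("srsphasor_undefined_correlation",
              "zero variance in one of the images")
  }
  stats::cor(a, b)
}
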
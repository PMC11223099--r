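#' Ground-truth class codes of the synthetic phantom
#'
#' @return Named integer vector mapping class names to the codes used in
#'   `truth_labels`: background 0, nucleus 1, cytoplasm 2, steatosis droplet
#'   3, phospholipidosis inclusion 4, alkyne-tagged drug inclusion 5.
#' @export
phantom_classes <- function() {
  c(background = 0L, nucleus = 1L, cytoplasm = 2L,
    steatosis = 3L, phospholipidosis = 4L, alkyne = 5L)
}

#' Configuration of the synthetic hyperspectral cell phantom
#'
#' The phantom emulates a hyperspectral SRS acquisition of HepG2-like cells:
#' ellipsoidal cells containing a nucleus (with 1-3 brighter nucleoli that
#' share the nucleus spectrum), cytoplasm, and spherical lipid inclusions of
#' configurable classes, imaged over a wavenumber axis built from the Stokes
#' wavelength and pump retune step. Every voxel renders the Lorentzian model
#' spectrum of its class; shot-like Poisson noise and additive Gaussian read
#' noise are then applied.
#'
#' @param image_shape Integer `(z, y, x)` voxel counts.
#' @param pixel_size Lateral pixel size in micrometres.
#' @param z_step Axial step in micrometres (z-stacks are acquired at 1 um
#'   increments by default).
#' @param n_cells Number of cells to place (0 gives pure background).
#' @param droplet_counts Named list of per-cell inclusion counts:
#'   `steatosis`, `phospholipidosis`, `alkyne`.
#' @param droplet_radius_range Inclusion radius range in micrometres; radii
#'   must be at least one pixel.
#' @param alkyne_colocalized If `TRUE`, alkyne-drug inclusions are placed
#'   concentric inside phospholipidosis inclusions (the lamellar-body
#'   trapping scenario); if `FALSE` they are placed independently.
#' @param noise List `poisson_scale` (expected counts per unit intensity;
#'   0 disables shot noise) and `gaussian_sd` (additive read noise; 0
#'   disables).
#' @param axis A `wavenumber_axis`; defaults to 2800-3050 cm^-1 at 0.4 nm
#'   pump retune against a 1031.4 nm Stokes (40 channels).
#' @param nucleolus_brightness Intensity multiplier of nucleoli relative to
#'   the rest of the nucleus (they share its spectrum; 1 renders a
#'   spectrally and radiometrically homogeneous nucleus).
#' @param seed Integer seed; the phantom is bit-reproducible given the
#'   config and seed.
#' @param cell_radius_range Lateral cell semi-axis range in micrometres.
#' @param max_attempts Rejection-sampling budget per placed object.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_shape = c(6L, 120L, 120L),
                           pixel_size = 0.4, z_step = 1,
                           n_cells = 3L,
                           droplet_counts = list(steatosis = 5L,
                                                 phospholipidosis = 3L,
                                                 alkyne = 0L),
                           droplet_radius_range = c(0.8, 1.5),
                           alkyne_colocalized = TRUE,
                           noise = list(poisson_scale = 400,
                                        gaussian_sd = 0.01),
                           axis = NULL, seed = 1L,
                           nucleolus_brightness = 1.6,
                           cell_radius_range = c(6.5, 8.5),
                           max_attempts = 500L) {
  if (pixel_size <= 0 || z_step <= 0) {
    srs_error("srsphasor_invalid_parameter", "pixel_size and z_step must be > 0")
  }
  if (min(droplet_radius_range) < pixel_size) {
    srs_error("srsphasor_invalid_parameter",
              "droplet radii must be at least one pixel_size")
  }
  for (k in c("steatosis", "phospholipidosis", "alkyne")) {
    if (is.null(droplet_counts[[k]])) droplet_counts[[k]] <- 0L
  }
  if (is.null(axis)) axis <- build_wavenumber_axis(1031.4, 2800, 3050, 0.4)
  structure(list(image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, z_step = z_step,
                 n_cells = as.integer(n_cells),
                 droplet_counts = droplet_counts,
                 droplet_radius_range = droplet_radius_range,
                 alkyne_colocalized = isTRUE(alkyne_colocalized),
                 noise = noise, axis = axis, seed = as.integer(seed),
                 nucleolus_brightness = nucleolus_brightness,
                 cell_radius_range = cell_radius_range,
                 max_attempts = as.integer(max_attempts)),
            class = "phantom_config")
}

#' Preset phantom configurations for treatment conditions
#'
#' Presets mirror the cell-culture contrasts the pipeline is designed to
#' detect: `control` carries a small basal steatosis-droplet load and no
#' phospholipidosis; `steatosis` a heavy neutral-lipid droplet load (the
#' cyclosporin-A-like phenotype); `phospholipidosis` many CH2-rich
#' inclusions (the propranolol-like phenotype); `alkyne` adds drug
#' inclusions co-placed inside the phospholipidosis bodies.
#'
#' @param condition One of `"control"`, `"steatosis"`, `"phospholipidosis"`,
#'   `"alkyne"`.
#' @param seed Integer seed.
#' @param noiseless If `TRUE`, disable both noise sources.
#' @param ... Further arguments passed to [phantom_config()].
#' @return A `phantom_config`.
#' @export
default_phantom_config <- function(condition = c("control", "steatosis",
                                                 "phospholipidosis", "alkyne"),
                                   seed = 1L, noiseless = FALSE, ...) {
  condition <- match.arg(condition)
  counts <- switch(condition,
    control          = list(steatosis = 2L, phospholipidosis = 0L, alkyne = 0L),
    steatosis        = list(steatosis = 8L, phospholipidosis = 1L, alkyne = 0L),
    phospholipidosis = list(steatosis = 2L, phospholipidosis = 8L, alkyne = 0L),
    alkyne           = list(steatosis = 2L, phospholipidosis = 8L, alkyne = 6L))
  args <- list(droplet_counts = counts, seed = seed, ...)
  if (noiseless) args$noise <- list(poisson_scale = 0, gaussian_sd = 0)
  cfg <- do.call(phantom_config, args)
  cfg$condition <- condition
  cfg
}

# ellipsoid membership, vectorized over voxel-center coordinate arrays
.inside_ellipsoid <- function(X, Y, Z, c0, ax) {
  ((X - c0[1]) / ax[1])^2 + ((Y - c0[2]) / ax[2])^2 + ((Z - c0[3]) / ax[3])^2 <= 1
}

#' Generate a synthetic labeled hyperspectral phantom
#'
#' Deterministically renders the configured cell geometry, evaluates each
#' class's spectrum model on the axis at every voxel, applies the configured
#' noise (Poisson-like scaling followed by additive Gaussian, negative
#' values clipped to zero), and snaps intensities onto the storage grid used
#' by [write_stack()] so that written phantoms round-trip exactly.
#'
#' @param config A `phantom_config`.
#' @param library Spectral library (default [default_library()]); must
#'   contain models named `background`, `nucleus`, `cytoplasm`,
#'   `steatosis droplet`, `phospholipidosis inclusion`, `alkyne drug`.
#' @return A `labeled_phantom`: list with `stack` (a [hyperstack()]),
#'   `truth_labels` and `cell_instances` (integer `(z, y, x)` arrays),
#'   `config`, and `clip_fraction` (fraction of voxel-channel values clipped
#'   at zero after noise).
#' @export
generate_phantom <- function(config, library = default_library()) {
  stopifnot(inherits(config, "phantom_config"))
  withr::with_seed(config$seed, .generate_phantom_impl(config, library))
}

.generate_phantom_impl <- function(config, library) {
  shp <- config$image_shape
  nz <- shp[1]; ny <- shp[2]; nx <- shp[3]
  px <- config$pixel_size; dz <- config$z_step
  # voxel-center coordinates in micrometres
  zs <- (seq_len(nz) - 0.5) * dz
  ys <- (seq_len(ny) - 0.5) * px
  xs <- (seq_len(nx) - 0.5) * px
  Z <- array(rep(zs, times = ny * nx), dim = shp)
  Y <- array(rep(rep(ys, each = nz), times = nx), dim = shp)
  X <- array(rep(xs, each = nz * ny), dim = shp)

  labels <- array(0L, shp)
  instances <- array(0L, shp)
  brightness <- array(1, shp)
  cls <- phantom_classes()

  ext_x <- nx * px; ext_y <- ny * px; ext_z <- nz * dz
  cells <- list()
  for (ci in seq_len(config$n_cells)) {
    placed <- FALSE
    for (att in seq_len(config$max_attempts)) {
      a <- stats::runif(1, config$cell_radius_range[1], config$cell_radius_range[2])
      b <- stats::runif(1, config$cell_radius_range[1], config$cell_radius_range[2])
      cc <- min(stats::runif(1, 2.4, 3.0), ext_z / 2)
      if (1.2 * a >= ext_x || 1.2 * b >= ext_y) next  # cell larger than field
      cx <- stats::runif(1, 0.6 * a, ext_x - 0.6 * a)
      cy <- stats::runif(1, 0.6 * b, ext_y - 0.6 * b)
      cz <- ext_z / 2 + stats::runif(1, -0.3, 0.3)
      ok <- TRUE
      for (other in cells) {
        d <- sqrt((cx - other$center[1])^2 + (cy - other$center[2])^2)
        if (d < 0.95 * (max(a, b) + max(other$axes[1], other$axes[2]))) {
          ok <- FALSE; break
        }
      }
      if (ok) {
        cells[[ci]] <- list(center = c(cx, cy, cz), axes = c(a, b, cc))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      srs_error("srsphasor_placement",
                sprintf("could not place cell %d without overlap", ci))
    }
  }

  all_droplets <- list()
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    c0 <- c(cell$center[1], cell$center[2], cell$center[3])
    ax <- cell$axes
    in_cell <- .inside_ellipsoid(X, Y, Z, c0, ax)
    labels[in_cell] <- cls[["cytoplasm"]]
    instances[in_cell] <- ci

    # nucleus: scaled ellipsoid with a small lateral offset
    nuc_ax <- 0.45 * ax
    off <- stats::runif(2, -0.15, 0.15) * ax[1:2]
    nuc_c <- c(c0[1] + off[1], c0[2] + off[2], c0[3])
    in_nuc <- .inside_ellipsoid(X, Y, Z, nuc_c, nuc_ax)
    labels[in_nuc] <- cls[["nucleus"]]

    # 1-3 brighter nucleoli, same spectrum as the nucleus
    for (k in seq_len(sample.int(3, 1))) {
      r <- stats::runif(1, 0.5, 0.9)
      th <- stats::runif(1, 0, 2 * pi); fr <- stats::runif(1, 0, 0.5)
      nc <- c(nuc_c[1] + fr * nuc_ax[1] * cos(th),
              nuc_c[2] + fr * nuc_ax[2] * sin(th), nuc_c[3])
      in_nl <- .inside_ellipsoid(X, Y, Z, nc, c(r, r, r)) & in_nuc
      brightness[in_nl] <- config$nucleolus_brightness %||% 1.6
    }

    # spherical inclusions per class, non-overlapping, in the cytoplasm
    counts <- config$droplet_counts
    place_class <- function(class_name, n, droplets) {
      for (k in seq_len(n)) {
        done <- FALSE
        for (att in seq_len(config$max_attempts)) {
          r <- stats::runif(1, config$droplet_radius_range[1],
                            config$droplet_radius_range[2])
          th <- stats::runif(1, 0, 2 * pi)
          fr <- stats::runif(1, 0.35, 0.88)
          dc <- c(c0[1] + fr * (ax[1] - r) * cos(th),
                  c0[2] + fr * (ax[2] - r) * sin(th),
                  c0[3] + stats::runif(1, -0.35, 0.35) * max(ax[3] - r, 0))
          # fully inside the cell, center clear of the nucleus, no overlap
          margin <- sum(((dc - c0) / pmax(ax - r, 1e-6))^2)
          in_nucleus <- sum(((dc - nuc_c) / (nuc_ax + 0.3 * r))^2) <= 1
          if (margin > 1 || in_nucleus) next
          clash <- FALSE
          for (o in droplets) {
            if (sqrt(sum((dc - o$center)^2)) < r + o$radius) { clash <- TRUE; break }
          }
          if (clash) next
          vox <- .inside_ellipsoid(X, Y, Z, dc, c(r, r, r))
          if (!any(vox)) next
          droplets[[length(droplets) + 1L]] <-
            list(center = dc, radius = r, class = class_name, cell = ci)
          done <- TRUE
          break
        }
        if (!done) {
          srs_error("srsphasor_placement",
                    sprintf("could not place %s inclusion %d in cell %d",
                            class_name, k, ci))
        }
      }
      droplets
    }
    droplets <- list()
    droplets <- place_class("steatosis", counts$steatosis, droplets)
    droplets <- place_class("phospholipidosis", counts$phospholipidosis, droplets)
    n_alk <- counts$alkyne
    if (n_alk > 0 && config$alkyne_colocalized) {
      # the drug partitions into lamellar bodies: convert hosts to the
      # drug-bearing class, rendered with the phospholipid+alkyne spectrum
      hosts <- which(vapply(droplets, function(d) {
        d$class == "phospholipidosis"
      }, logical(1)))
      if (length(hosts) < n_alk) {
        srs_error("srsphasor_placement",
                  "not enough phospholipidosis hosts for colocalized alkyne inclusions")
      }
      for (k in hosts[seq_len(n_alk)]) droplets[[k]]$class <- "alkyne"
    } else if (n_alk > 0) {
      droplets <- place_class("alkyne", n_alk, droplets)
    }
    all_droplets <- c(all_droplets, droplets)
  }

  # render inclusions last so specific classes win over compartments;
  # alkyne last so a colocalized inclusion overwrites its host core
  order_cls <- c("steatosis", "phospholipidosis", "alkyne")
  for (cn in order_cls) {
    for (d in Filter(function(x) x$class == cn, all_droplets)) {
      vox <- .inside_ellipsoid(X, Y, Z, d$center, rep(d$radius, 3))
      labels[vox] <- cls[[cn]]
      instances[vox] <- d$cell
    }
  }

  alkyne_model <- if (config$alkyne_colocalized) "alkyne lamellar body"
                  else "alkyne drug"
  model_names <- c("background", "nucleus", "cytoplasm", "steatosis droplet",
                   "phospholipidosis inclusion", alkyne_model)
  missing <- setdiff(model_names, names(library))
  if (length(missing)) {
    srs_error("srsphasor_invalid_parameter",
              paste("library lacks models:", paste(missing, collapse = ", ")))
  }
  lut <- t(vapply(model_names, function(nm) {
    evaluate_spectrum(library[[nm]], config$axis)
  }, numeric(config$axis$n_channels)))

  stack_mat <- lut[as.vector(labels) + 1L, , drop = FALSE] * as.vector(brightness)

  ps <- config$noise$poisson_scale %||% 0
  gs <- config$noise$gaussian_sd %||% 0
  if (ps > 0) {
    stack_mat[] <- stats::rpois(length(stack_mat), as.vector(stack_mat) * ps) / ps
  }
  if (gs > 0) {
    stack_mat[] <- stack_mat + stats::rnorm(length(stack_mat), 0, gs)
  }
  clipped <- sum(stack_mat < 0)
  stack_mat[stack_mat < 0] <- 0
  stack_mat <- quantize_intensity(stack_mat)

  data <- array(stack_mat, dim = c(shp, config$axis$n_channels))
  hs <- hyperstack(data, config$axis, config$pixel_size, config$z_step)
  structure(list(stack = hs, truth_labels = labels,
                 cell_instances = instances, config = config,
                 droplets = all_droplets,
                 clip_fraction = clipped / length(stack_mat)),
            class = "labeled_phantom")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.labeled_phantom <- function(x, ...) {
  tab <- table(factor(x$truth_labels, levels = phantom_classes(),
                      labels = names(phantom_classes())))
  cat("labeled_phantom:", paste(dim(x$truth_labels), collapse = " x "),
      "voxels;", x$config$n_cells, "cells\n")
  print(tab)
  cat(sprintf("clip fraction after noise: %.2g\n", x$clip_fraction))
  invisible(x)
}
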
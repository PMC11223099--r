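#' Phasor-plane region of interest
#'
#' A named simple polygon in (G, S) coordinates used to segment the phasor
#' plot into cellular classes. Canonical class labels mirror the standard
#' segmentation of hepatocyte hyperspectral data: nucleus, cytoplasm,
#' total_lipid, steatosis, phospholipidosis; any other label is treated as
#' custom. Point-in-polygon tests use the even-odd rule and are
#' boundary-inclusive (a point on an edge or vertex is inside).
#'
#' @param label Class label.
#' @param polygon Numeric matrix with columns (G, S), >= 3 vertices, simple
#'   (non-self-intersecting), contained in \eqn{[-1.05, 1.05]^2}.
#' @param color Optional display color tag.
#' @return A `phasor_roi`.
#' @export
phasor_roi <- function(label, polygon, color = NULL) {
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2 || nrow(polygon) < 3) {
    srs_error("srsphasor_invalid_parameter",
              "polygon must be an n x 2 matrix with n >= 3")
  }
  if (any(!is.finite(polygon)) || any(abs(polygon) > 1.05)) {
    srs_error("srsphasor_invalid_parameter",
              "polygon vertices must lie in [-1.05, 1.05]^2")
  }
  if (.polygon_self_intersects(polygon)) {
    srs_error("srsphasor_invalid_parameter", "polygon is self-intersecting")
  }
  structure(list(label = label, polygon = unname(polygon), color = color),
            class = "phasor_roi")
}

.seg_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

.polygon_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  for (i in seq_len(n)) {
    i2 <- i %% n + 1L
    for (j in seq_len(n)) {
      if (j %in% c(i, i2, (i - 2L) %% n + 1L)) next
      j2 <- j %% n + 1L
      if (j2 == i) next
      if (.seg_intersect(p[i, ], p[i2, ], p[j, ], p[j2, ])) return(TRUE)
    }
  }
  FALSE
}

#' Test points against a phasor ROI
#'
#' Even-odd (crossing-number) point-in-polygon, boundary-inclusive:
#' points exactly on an edge or vertex count as inside.
#'
#' @param roi A `phasor_roi`.
#' @param g,s Numeric vectors of phasor coordinates.
#' @param eps Collinearity tolerance for the on-boundary test.
#' @return Logical vector (`NA` inputs give `FALSE`).
#' @export
roi_contains <- function(roi, g, s, eps = 1e-12) {
  p <- roi$polygon
  n <- nrow(p)
  ok <- is.finite(g) & is.finite(s)
  inside <- rep(FALSE, length(g))
  boundary <- rep(FALSE, length(g))
  j <- n
  for (i in seq_len(n)) {
    xi <- p[i, 1]; yi <- p[i, 2]; xj <- p[j, 1]; yj <- p[j, 2]
    crosses <- ((yi > s) != (yj > s)) &
      (g < (xj - xi) * (s - yi) / (yj - yi) + xi)
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
    # on-segment: collinear and within the segment's bounding box
    cross <- (xj - xi) * (s - yi) - (yj - yi) * (g - xi)
    seglen2 <- (xj - xi)^2 + (yj - yi)^2
    onseg <- abs(cross) <= eps * max(1, sqrt(seglen2)) &
      g >= pmin(xi, xj) - eps & g <= pmax(xi, xj) + eps &
      s >= pmin(yi, yj) - eps & s <= pmax(yi, yj) + eps
    onseg[is.na(onseg)] <- FALSE
    boundary <- boundary | onseg
    j <- i
  }
  (inside | boundary) & ok
}

#' Segment a phasor map with ROIs
#'
#' Labels every valid pixel by the ROI containing its (G, S) point
#' (boundary-inclusive). Overlaps are resolved by precedence: ROIs are
#' applied in listed order with later ROIs overwriting earlier ones, and
#' the specific lipid classes `steatosis` and `phospholipidosis` are always
#' applied after (i.e. override) `total_lipid`, mirroring the nested
#' steatosis/phospholipidosis regions inside the total-lipid region of the
#' phasor plot. Invalid pixels get label 0, so the result is a partition of
#' the valid pixels.
#'
#' @param pmap A `phasor_map`.
#' @param rois List of `phasor_roi`s.
#' @return A `roi_segmentation`: list with `labels` (integer array, 0 =
#'   unlabeled/invalid, otherwise the ROI's index in `rois`) and `classes`
#'   (data.frame mapping label ids to class labels).
#' @export
segment_by_rois <- function(pmap, rois) {
  if (!length(rois)) {
    srs_error("srsphasor_invalid_parameter", "need at least one ROI")
  }
  cls <- vapply(rois, `[[`, character(1), "label")
  ord <- order(cls %in% c("steatosis", "phospholipidosis"))  # specific last
  labels <- array(0L, dim(pmap$G))
  g <- as.vector(pmap$G); s <- as.vector(pmap$S)
  lab_v <- integer(length(g))
  for (i in seq_along(rois)[ord]) {
    hit <- roi_contains(rois[[i]], g, s)
    lab_v[hit] <- i
  }
  lab_v[!as.vector(pmap$valid)] <- 0L
  labels[] <- lab_v
  structure(list(labels = labels,
                 classes = data.frame(label = seq_along(rois), class = cls,
                                      stringsAsFactors = FALSE)),
            class = "roi_segmentation")
}

#' Derive a phasor ROI from a reference
#'
#' Automates manual ROI placement: from either the phasor cloud of a
#' pure-class reference region (a `phasor_map` or an n x 2 (G, S) matrix)
#' or a noiseless `spectrum_model`, builds a convex polygon enclosing the
#' reference phasor position(s) dilated outward by `padding` in (G, S)
#' units. Outputs derived this way are flagged with
#' `derived_from_reference = TRUE` since they stand in for hand-drawn ROIs.
#'
#' @param reference A `phasor_map` (>= 10 valid pixels), an n x 2 numeric
#'   matrix of (G, S) points, or a `spectrum_model`.
#' @param label Class label for the resulting ROI.
#' @param padding Dilation in (G, S) units; must be > 0 for point-like
#'   references.
#' @param axis Wavenumber axis (required for a `spectrum_model` reference).
#' @param harmonic Harmonic order.
#' @return A `phasor_roi` with attribute `derived_from_reference`.
#' @export
derive_roi_from_reference <- function(reference, label = "custom",
                                      padding = 0.04, axis = NULL,
                                      harmonic = 1L) {
  if (inherits(reference, "spectrum_model")) {
    if (is.null(axis)) {
      srs_error("srsphasor_invalid_parameter",
                "axis required for a spectrum_model reference")
    }
    pts <- matrix(phasor_of_spectrum(reference, axis, harmonic), 1, 2)
  } else if (inherits(reference, "phasor_map")) {
    pts <- cbind(reference$G[reference$valid], reference$S[reference$valid])
    if (nrow(pts) < 10) {
      srs_error("srsphasor_invalid_parameter",
                "reference phasor cloud needs >= 10 valid pixels")
    }
  } else {
    pts <- as.matrix(reference)
  }
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  span <- max(dist(rbind(pts[grDevices::chull(pts), , drop = FALSE])), 0)
  if (span > 1.0) {
    srs_error("srsphasor_ambiguous_reference",
              sprintf("reference cloud spans %.2f in (G,S); too diffuse to define a class ROI", span))
  }
  point_like <- span < 1e-9
  if (point_like) {
    if (padding <= 0) {
      srs_error("srsphasor_degenerate_roi",
                "point-like reference with zero padding gives a degenerate ROI")
    }
    th <- seq(0, 2 * pi, length.out = 17L)[-17L]
    poly <- cbind(pts[1, 1] + padding * cos(th), pts[1, 2] + padding * sin(th))
  } else {
    hull <- pts[grDevices::chull(pts), , drop = FALSE]
    ctr <- colMeans(hull)
    dirs <- sweep(hull, 2, ctr)
    nrm <- sqrt(rowSums(dirs^2))
    nrm[nrm == 0] <- 1
    poly <- hull + padding * dirs / nrm
    if (nrow(poly) < 3) {
      if (padding <= 0) {
        srs_error("srsphasor_degenerate_roi",
                  "collinear reference with zero padding gives a degenerate ROI")
      }
      # collinear cloud: pad into a rectangle along the principal direction
      v <- poly[2, ] - poly[1, ]
      nvec <- c(-v[2], v[1]) / sqrt(sum(v^2)) * padding
      poly <- rbind(poly[1, ] + nvec, poly[2, ] + nvec,
                    poly[2, ] - nvec, poly[1, ] - nvec)
    }
  }
  poly <- pmin(pmax(poly, -1.05), 1.05)
  roi <- phasor_roi(label, poly)
  attr(roi, "derived_from_reference") <- TRUE
  roi
}

#' Serialize phasor ROIs to / from JSON
#'
#' @param rois List of `phasor_roi`s.
#' @param path JSON file path.
#' @return `path` invisibly (writer); list of `phasor_roi`s (reader).
#' @export
write_rois_json <- function(rois, path) {
  payload <- lapply(rois, function(r) {
    list(label = r$label, color = r$color,
         vertices = lapply(seq_len(nrow(r$polygon)),
                           function(i) as.numeric(r$polygon[i, ])))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(r) {
    poly <- do.call(rbind, lapply(r$vertices, as.numeric))
    phasor_roi(r$label, poly, color = r$color)
  })
}

#' Mean spectrum of a segmented class
#'
#' Channelwise mean spectrum over all pixels carrying a given label, then
#' normalized (`max`: peak = 1, the convention for plotting normalized SRS
#' segment spectra; `area`: sum = 1).
#'
#' @param stack The [hyperstack()] the segmentation came from.
#' @param labels Integer label array matching the stack's spatial shape
#'   (e.g. `segment_by_rois(...)$labels` or phantom truth labels).
#' @param label Label id to average over.
#' @param normalization `"max"` (default) or `"area"`.
#' @return A `segment_spectrum`: list with `label`, `mean_spectrum`,
#'   `normalization`, `pixel_count`, `shifts`.
#' @export
segment_spectrum <- function(stack, labels, label,
                             normalization = c("max", "area")) {
  normalization <- match.arg(normalization)
  sel <- as.vector(labels) == label
  if (!any(sel)) {
    srs_error("srsphasor_empty_segment",
              sprintf("no pixels carry label %s", format(label)))
  }
  m <- stack_matrix(stack)
  spec <- colMeans(m[sel, , drop = FALSE])
  spec <- switch(normalization,
                 max = spec / max(spec),
                 area = spec / sum(spec))
  structure(list(label = label, mean_spectrum = spec,
                 normalization = normalization, pixel_count = sum(sel),
                 shifts = stack$axis$values),
            class = "segment_spectrum")
}
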
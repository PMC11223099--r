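square_roi <- function(label, cx, cy, half) {
  phasor_roi(label, cbind(c(cx - half, cx + half, cx + half, cx - half),
                          c(cy - half, cy - half, cy + half, cy + half)))
}

test_that("ROI polygons are validated", {
  expect_error(phasor_roi("a", cbind(c(0, 1), c(0, 1))),
               class = "srsphasor_invalid_parameter")
  expect_error(phasor_roi("a", cbind(c(0, 2, 0), c(0, 0, 1))),
               class = "srsphasor_invalid_parameter")  # outside [-1.05, 1.05]
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(phasor_roi("a", bowtie),
               class = "srsphasor_invalid_parameter")  # self-intersecting
})

test_that("point-in-polygon is even-odd and boundary-inclusive", {
  r <- square_roi("a", 0, 0, 0.5)
  expect_true(roi_contains(r, 0, 0))
  expect_true(roi_contains(r, -0.5, -0.5))   # vertex counts as inside
  expect_true(roi_contains(r, 0.5, 0))       # edge midpoint too
  expect_false(roi_contains(r, 0.51, 0))
  expect_false(roi_contains(r, NA, 0))
  # concave polygon: the notch is outside under the even-odd rule
  cshape <- phasor_roi("c", cbind(c(-0.5, 0.5, 0.5, 0, 0, 0.5, 0.5, -0.5),
                                  c(-0.5, -0.5, -0.2, -0.2, 0.2, 0.2, 0.5, 0.5)))
  expect_true(roi_contains(cshape, -0.25, 0))
  expect_false(roi_contains(cshape, 0.4, 0))
})

test_that("an ROI covering the unit disc labels exactly the valid pixels", {
  ph <- generate_phantom(small_phantom_config(seed = 23))
  pm <- phasor_transform(ph$stack)
  disc <- square_roi("everything", 0, 0, 1.04)
  seg <- segment_by_rois(pm, list(disc))
  expect_identical(seg$labels > 0, unclass(pm$valid))
})

test_that("segmentation partitions the valid pixels under any precedence", {
  ph <- generate_phantom(small_phantom_config(seed = 24))
  pm <- phasor_transform(ph$stack)
  rois <- list(square_roi("a", -0.3, 0.1, 0.4), square_roi("b", 0, 0, 0.45),
               square_roi("c", -0.5, -0.2, 0.35))
  seg <- segment_by_rois(pm, rois)
  expect_true(all(seg$labels[!pm$valid] == 0L))
  covered <- rep(FALSE, length(pm$G))
  for (r in rois) covered <- covered | roi_contains(r, as.vector(pm$G), as.vector(pm$S))
  expect_true(all((seg$labels > 0) == (covered & as.vector(pm$valid))))
  # later-listed ROI wins in overlaps
  p_overlap <- which(
    roi_contains(rois[[1]], as.vector(pm$G), as.vector(pm$S)) &
    roi_contains(rois[[3]], as.vector(pm$G), as.vector(pm$S)) &
    as.vector(pm$valid))
  if (length(p_overlap)) expect_true(all(seg$labels[p_overlap] == 3L))
})

test_that("specific lipid classes override total_lipid regardless of listed order", {
  ph <- generate_phantom(small_phantom_config(seed = 25))
  pm <- phasor_transform(ph$stack)
  big <- square_roi("total_lipid", -0.2, 0.3, 0.6)
  inner <- square_roi("steatosis", -0.11, 0.33, 0.15)
  seg <- segment_by_rois(pm, list(inner, big))  # total_lipid listed later
  in_inner <- roi_contains(inner, as.vector(pm$G), as.vector(pm$S)) &
    as.vector(pm$valid)
  if (any(in_inner)) expect_true(all(seg$labels[in_inner] == 1L))
})

test_that("ROIs derived from references enclose the reference phasor", {
  ax <- default_axis()
  lib <- default_library()
  m <- lib[["cytoplasm"]]
  roi <- derive_roi_from_reference(m, "cytoplasm", padding = 0.05, axis = ax)
  p <- oracle_phasor(evaluate_spectrum(m, ax))
  expect_true(roi_contains(roi, p["G"], p["S"]))
  expect_equal(colMeans(roi$polygon), unname(p), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(isTRUE(attr(roi, "derived_from_reference")))

  # from a noisy reference cloud
  hs <- homogeneous_stack(m, poisson_scale = 400, gaussian_sd = 0.01, seed = 2)
  pmap <- phasor_transform(hs)
  roi2 <- derive_roi_from_reference(pmap, "cytoplasm", padding = 0.02)
  expect_true(roi_contains(roi2, p["G"], p["S"]))
})

test_that("degenerate and ambiguous references are rejected", {
  ax <- default_axis()
  lib <- default_library()
  expect_error(derive_roi_from_reference(lib[["nucleus"]], padding = 0,
                                         axis = ax),
               class = "srsphasor_degenerate_roi")
  # a cloud spanning more than half the unit disc is too diffuse
  withr::with_seed(1, {
    diffuse <- cbind(stats::runif(100, -0.9, 0.9), stats::runif(100, -0.9, 0.9))
  })
  expect_error(derive_roi_from_reference(diffuse, padding = 0.02),
               class = "srsphasor_ambiguous_reference")
  # too few reference pixels
  tiny <- phasor_transform(homogeneous_stack(lib[["nucleus"]], ny = 3, nx = 3))
  tiny$valid[1:3] <- FALSE
  expect_error(derive_roi_from_reference(tiny, padding = 0.02),
               class = "srsphasor_invalid_parameter")
})

test_that("the nine neat-lipid reference ROIs are mutually disjoint at default padding", {
  ax <- default_axis()
  lib <- default_library()
  nine <- attr(lib, "neat_lipids")
  rois <- lapply(nine, function(nm) {
    derive_roi_from_reference(lib[[nm]], nm, axis = ax)  # default padding
  })
  for (i in seq_along(rois)) {
    for (j in seq_along(rois)) {
      if (i < j) expect_true(rois_disjoint(rois[[i]], rois[[j]]),
                             label = paste(nine[i], "vs", nine[j]))
    }
  }
})

test_that("ROIs serialize to JSON and back without loss", {
  rois <- list(square_roi("steatosis", -0.1, 0.33, 0.1),
               phasor_roi("custom", cbind(c(0, 0.2, 0.1), c(0, 0, 0.3)),
                          color = "#ff0000"))
  f <- withr::local_tempfile(fileext = ".json")
  write_rois_json(rois, f)
  back <- read_rois_json(f)
  expect_identical(back[[1]]$label, "steatosis")
  expect_equal(back[[1]]$polygon, rois[[1]]$polygon)
  expect_identical(back[[2]]$color, "#ff0000")
})

test_that("segment spectra recover the class spectra of a phantom", {
  cfg <- small_phantom_config(seed = 27, noiseless = TRUE,
                              nucleolus_brightness = 1)
  ph <- generate_phantom(cfg)
  lib <- default_library()
  ax <- cfg$axis
  cls <- phantom_classes()
  # homogeneous noiseless region reproduces the normalized model exactly
  sp_cyt <- segment_spectrum(ph$stack, ph$truth_labels, cls[["cytoplasm"]])
  want <- evaluate_spectrum(lib[["cytoplasm"]], ax)
  expect_equal(sp_cyt$mean_spectrum, want / max(want), tolerance = 1e-3)
  expect_identical(max(sp_cyt$mean_spectrum), 1)
  # nucleus: spectral maximum at the nucleic-acid band near 2965
  sp_nuc <- segment_spectrum(ph$stack, ph$truth_labels, cls[["nucleus"]])
  win <- ax$values >= 2940 & ax$values <= 2990
  peak <- ax$values[win][which.max(sp_nuc$mean_spectrum[win])]
  expect_lte(abs(peak - 2965), max(diff(ax$values)))
  # steatosis is CH2-enriched relative to cytoplasm
  sp_st <- segment_spectrum(ph$stack, ph$truth_labels, cls[["steatosis"]])
  k2851 <- which.min(abs(ax$values - 2851))
  expect_gt(sp_st$mean_spectrum[k2851], sp_cyt$mean_spectrum[k2851])
  # area normalization sums to one
  sp_area <- segment_spectrum(ph$stack, ph$truth_labels, cls[["cytoplasm"]],
                              normalization = "area")
  expect_equal(sum(sp_area$mean_spectrum), 1)
  expect_error(segment_spectrum(ph$stack, ph$truth_labels, 99L),
               class = "srsphasor_empty_segment")
})
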
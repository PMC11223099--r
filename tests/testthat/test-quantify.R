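test_that("ratio maps compute pixelwise CH2/CH3 and respect the mask", {
  num <- matrix(3, 4, 4); den <- matrix(6, 4, 4)
  rm0 <- ratio_map(num_image = num, den_image = den)
  expect_equal(rm0$ratio, matrix(0.5, 4, 4))
  # scale invariance: multiplying both channels leaves R unchanged
  rm_scaled <- ratio_map(num_image = 13 * num, den_image = 13 * den)
  expect_equal(rm_scaled$ratio, rm0$ratio)
  # undefined where the denominator vanishes; masked pixels excluded
  den2 <- den; den2[1, 1] <- 0
  msk <- matrix(TRUE, 4, 4); msk[4, 4] <- FALSE
  rm2 <- ratio_map(num_image = num, den_image = den2, mask = msk)
  expect_true(is.na(rm2$ratio[1, 1]))
  expect_true(is.na(rm2$ratio[4, 4]))
  expect_equal(rm2$ratio[2, 2], 0.5)
})

test_that("shifts missing from the axis raise an axis-mismatch error", {
  ph <- generate_phantom(small_phantom_config(seed = 31))
  expect_error(ratio_map(ph$stack, shift_num = 2500),
               class = "srsphasor_axis_mismatch")
})

test_that("noiseless phantoms show the droplet-high / nucleus-low ratio contrast", {
  ph <- generate_phantom(small_phantom_config(seed = 33, noiseless = TRUE))
  rm0 <- ratio_map(ph$stack)
  cls <- phantom_classes()
  expect_gte(mean(rm0$ratio[ph$truth_labels == cls[["steatosis"]]]), 0.8)
  expect_lte(mean(rm0$ratio[ph$truth_labels == cls[["nucleus"]]]), 0.2)
})

test_that("per-cell ratios aggregate by instance and flag empty cells", {
  inst <- array(0L, c(1, 6, 6)); inst[1, 1:3, ] <- 1L; inst[1, 4:6, ] <- 2L
  r <- array(0.4, c(1, 6, 6)); r[1, 4:6, ] <- 0.7
  rmap <- structure(list(ratio = r), class = "ratio_map")
  tab <- per_cell_ratio(rmap, inst)
  expect_equal(tab$mean_ratio, c(0.4, 0.7))
  expect_identical(nrow(tab), 2L)
  # a cell with only undefined pixels yields NA with a warning
  r2 <- r; r2[1, 1:3, ] <- NA
  expect_warning(tab2 <- per_cell_ratio(structure(list(ratio = r2),
                                                  class = "ratio_map"), inst))
  expect_true(is.na(tab2$mean_ratio[1]))
})

test_that("a heavier droplet load raises the mean cellular CH2/CH3 ratio", {
  means <- sapply(c("control", "steatosis"), function(cond) {
    ph <- generate_phantom(default_phantom_config(cond, seed = 35,
                                                  noiseless = TRUE))
    rm0 <- ratio_map(ph$stack)
    mean(rm0$ratio[ph$cell_instances > 0], na.rm = TRUE)
  })
  expect_gt(means["steatosis"], means["control"])
})

test_that("3D droplet segmentation labels 26-connected components with correct volumes", {
  # two disjoint bright spheres in an empty volume
  vol <- array(0, c(8, 40, 40))
  mk_sphere <- function(vol, c0, r, val = 1) {
    d <- dim(vol)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      if ((z - c0[1])^2 / (r / 1)^2 + ((y - c0[2])^2 + (x - c0[3])^2) / (r / 0.25)^2 <= 1) {
        vol[z, y, x] <- val
      }
    }
    vol
  }
  # sphere radius 2 um in 0.25 x 0.25 x 1 um voxels
  vol <- mk_sphere(vol, c(4, 12, 12), 2)
  vol <- mk_sphere(vol, c(4, 30, 30), 2)
  out <- ld_segment_3d(vol, pixel_size = 0.25, z_step = 1,
                       method = "manual", manual_threshold = 0.5)
  expect_identical(nrow(out$droplets), 2L)
  vtrue <- 4 / 3 * pi * 2^3
  expect_true(all(abs(out$droplets$volume_um3 - vtrue) / vtrue < 0.15))
  # volume conservation: totals match labeled voxel count x voxel volume
  expect_equal(sum(out$droplets$volume_um3),
               sum(out$labels > 0) * 0.25^2 * 1)
  # an empty volume yields zero rows
  empty <- ld_segment_3d(array(0, c(4, 10, 10)), 0.25, 1,
                         method = "manual", manual_threshold = 0.5)
  expect_identical(nrow(empty$droplets), 0L)
  # size filter removes single-voxel specks
  speck <- array(0, c(4, 10, 10)); speck[2, 5, 5] <- 1
  filt <- ld_segment_3d(speck, 0.25, 1, method = "manual",
                        manual_threshold = 0.5, min_voxels = 4)
  expect_identical(nrow(filt$droplets), 0L)
  expect_error(ld_segment_3d(vol, 0.25, NULL, method = "manual",
                             manual_threshold = 0.5),
               class = "srsphasor_geometry")
})

test_that("diagonal touching voxels merge under 26-connectivity", {
  vol <- array(0, c(3, 3, 3))
  vol[1, 1, 1] <- 1; vol[2, 2, 2] <- 1; vol[3, 3, 3] <- 1
  out <- ld_segment_3d(vol, 1, 1, method = "manual", manual_threshold = 0.5,
                       min_voxels = 1)
  expect_identical(nrow(out$droplets), 1L)
  expect_identical(out$droplets$voxel_count, 3L)
})

test_that("percent area is measured against each cell's foreground", {
  inst <- array(0L, c(1, 4, 8)); inst[1, , 1:4] <- 1L; inst[1, , 5:8] <- 2L
  lab <- array(0L, c(1, 4, 8))
  lab[1, 1:2, 1:4] <- 7L              # class 7 covers half of cell 1
  tab <- percent_area(lab, 7L, inst)
  expect_equal(tab$percent_area, c(50, 0))
  # class percentages over disjoint classes never exceed 100
  ph <- generate_phantom(small_phantom_config(seed = 37))
  cls <- phantom_classes()
  tot <- 0
  for (cl in c("nucleus", "cytoplasm", "steatosis", "phospholipidosis")) {
    tt <- percent_area(ph$truth_labels, cls[[cl]], ph$cell_instances)
    tot <- tot + tt$percent_area
  }
  expect_true(all(tot <= 100 + 1e-9))
})

test_that("configured droplet load monotonically increases total lipid area", {
  area_for <- function(n_drop, seed) {
    cfg <- small_phantom_config(
      seed = seed,
      droplet_counts = list(steatosis = n_drop, phospholipidosis = 0L,
                            alkyne = 0L))
    ph <- generate_phantom(cfg)
    mean(percent_area(ph$truth_labels, phantom_classes()[["steatosis"]],
                      ph$cell_instances)$percent_area)
  }
  seeds <- 41:44
  lo <- mean(sapply(seeds, function(s) area_for(1L, s)))
  mid <- mean(sapply(seeds, function(s) area_for(4L, s)))
  hi <- mean(sapply(seeds, function(s) area_for(8L, s)))
  expect_lt(lo, mid); expect_lt(mid, hi)
})

test_that("colocalization recovers designed co- and independent placement", {
  expect_equal(colocalize(matrix(1:20, 4), matrix(1:20, 4)), 1)
  expect_equal(colocalize(matrix(1:20, 4), -matrix(1:20, 4)), -1)
  expect_error(colocalize(matrix(1, 2, 2), matrix(1, 2, 2)),
               class = "srsphasor_invalid_parameter")  # too few pixels
  expect_error(colocalize(matrix(1, 5, 5), matrix(1:25, 5)),
               class = "srsphasor_undefined_correlation")
  ax <- build_wavenumber_axis(1031.4, 2200, 3050, 1.0)
  tolc <- 0.75 * max(diff(ax$values))
  r_co <- sapply(51:53, function(s) {
    ph <- generate_phantom(phantom_config(
      seed = s, droplet_counts = list(steatosis = 2L, phospholipidosis = 8L,
                                      alkyne = 6L),
      alkyne_colocalized = TRUE, axis = ax))
    colocalize(channel_image(ph$stack, 2851, tol = tolc),
               channel_image(ph$stack, 2233, tol = tolc),
               ph$cell_instances > 0)
  })
  expect_true(all(r_co >= 0.5))
  r_ind <- sapply(51:53, function(s) {
    ph <- generate_phantom(phantom_config(
      seed = s, droplet_counts = list(steatosis = 2L, phospholipidosis = 4L,
                                      alkyne = 4L),
      alkyne_colocalized = FALSE, axis = ax))
    colocalize(channel_image(ph$stack, 2851, tol = tolc),
               channel_image(ph$stack, 2233, tol = tolc),
               ph$cell_instances > 0)
  })
  expect_true(all(abs(r_ind) <= 0.2))
})
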
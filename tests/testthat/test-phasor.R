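test_that("canonical spectra land at their analytic phasor positions", {
  ax <- default_axis()
  N <- ax$n_channels
  # flat spectrum: full-period cosine and sine sums vanish
  flat <- hyperstack(array(1, c(3, 3, N)), ax, 0.4)
  pm <- phasor_transform(flat)
  expect_equal(max(abs(pm$G)), 0, tolerance = 1e-12)
  expect_equal(max(abs(pm$S)), 0, tolerance = 1e-12)
  # a single bright channel at k = 0 sits on the unit circle at (1, 0)
  delta <- array(0, c(2, 2, N)); delta[, , 1] <- 5
  pd <- phasor_transform(hyperstack(delta, ax, 0.4))
  expect_equal(as.vector(pd$G), rep(1, 4), tolerance = 1e-12)
  expect_equal(as.vector(pd$S), rep(0, 4), tolerance = 1e-12)
  # equal deltas at k = 0 and k = 10 (quarter period): (0.5, 0.5)
  mix <- array(0, c(1, 1, N)); mix[, , 1] <- 1; mix[, , 11] <- 1
  pmx <- phasor_transform(hyperstack(mix, ax, 0.4))
  expect_equal(c(pmx$G[1, 1], pmx$S[1, 1]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(unname(oracle_phasor(as.vector(mix[1, 1, ]))), c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("mixtures lie on the intensity-weighted segment between component phasors", {
  ax <- default_axis()
  N <- ax$n_channels
  withr::with_seed(11, {
    for (rep in 1:20) {
      A <- stats::runif(N); B <- stats::runif(N)
      alpha <- stats::runif(1, 0, 3); beta <- stats::runif(1, 0, 3)
      mixv <- alpha * A + beta * B
      got <- oracle_phasor(mixv)
      pa <- oracle_phasor(A); pb <- oracle_phasor(B)
      wa <- alpha * sum(A) / (alpha * sum(A) + beta * sum(B))
      expect_equal(unname(got), unname(wa * pa + (1 - wa) * pb),
                   tolerance = 1e-12)
      # package transform agrees with the summation oracle
      hs <- hyperstack(array(mixv, c(1, 1, N)), ax, 0.4)
      pm <- phasor_transform(hs)
      expect_equal(c(pm$G[1, 1], pm$S[1, 1]), unname(got), tolerance = 1e-12)
    }
  })
})

test_that("the transform is invariant to intensity scaling and bounded by the unit disc", {
  ph <- generate_phantom(small_phantom_config(seed = 17))
  pm <- phasor_transform(ph$stack)
  scaled <- hyperstack(ph$stack$data * 7.3, ph$stack$axis,
                       ph$stack$pixel_size, ph$stack$z_step)
  pm2 <- phasor_transform(scaled)
  expect_equal(pm$G, pm2$G, tolerance = 1e-12)
  expect_equal(pm$S, pm2$S, tolerance = 1e-12)
  r2 <- pm$G[pm$valid]^2 + pm$S[pm$valid]^2
  expect_true(all(r2 <= 1 + 1e-9))
})

test_that("invalid pixels are excluded by total intensity and by the mask", {
  ax <- default_axis()
  d <- array(1, c(2, 2, ax$n_channels))
  d[1, 1, ] <- 0
  msk <- matrix(TRUE, 2, 2); msk[2, 2] <- FALSE
  pm <- phasor_transform(hyperstack(d, ax, 0.4), mask = msk)
  expect_false(pm$valid[1, 1])   # zero total intensity
  expect_false(pm$valid[2, 2])   # masked out
  expect_true(pm$valid[1, 2])
  expect_true(is.na(pm$G[1, 1]) && is.na(pm$G[2, 2]))
  expect_error(
    phasor_transform(hyperstack(array(1, c(2, 2, ax$n_channels)), ax, 0.4),
                     mask = matrix(TRUE, 3, 3)),
    class = "srsphasor_invalid_parameter")
})

test_that("phasor density conserves the valid-pixel count", {
  ph <- generate_phantom(small_phantom_config(seed = 19))
  pm <- phasor_transform(ph$stack)
  dens <- phasor_density(pm, bins = 64)
  expect_identical(sum(dens$counts), sum(pm$valid))
  # all-identical pixels occupy exactly one bin
  ax <- default_axis()
  pm1 <- phasor_transform(hyperstack(array(rep(stats::runif(40), each = 9),
                                           c(3, 3, 40)), ax, 0.4))
  d1 <- phasor_density(pm1, bins = 128)
  expect_identical(sum(d1$counts > 0), 1L)
})

test_that("a noiseless two-compartment image occupies exactly the two analytic bins", {
  ax <- default_axis()
  lib <- default_library()
  sA <- evaluate_spectrum(lib[["nucleus"]], ax)
  sB <- evaluate_spectrum(lib[["steatosis droplet"]], ax)
  d <- array(0, c(2, 4, 40))
  for (k in 1:40) { d[, 1:2, k] <- sA[k]; d[, 3:4, k] <- sB[k] }
  pm <- phasor_transform(hyperstack(d, ax, 0.4))
  bins <- 128L
  dens <- phasor_density(pm, bins = bins)
  occupied <- which(dens$counts > 0, arr.ind = TRUE)
  expect_identical(nrow(occupied), 2L)
  for (sp in list(sA, sB)) {
    p <- oracle_phasor(sp)
    gi <- findInterval(p["G"], dens$g_edges, rightmost.closed = TRUE)
    si <- findInterval(p["S"], dens$s_edges, rightmost.closed = TRUE)
    expect_true(any(occupied[, 1] == gi & occupied[, 2] == si))
  }
})

test_that("modulation tracks spectral narrowness and unsaturation", {
  ax <- default_axis()
  lib <- default_library()
  # delta spectrum -> modulation 1; origin -> 0
  N <- ax$n_channels
  delta <- array(0, c(1, 1, N)); delta[1, 1, 3] <- 2
  pol <- phasor_polar(phasor_transform(hyperstack(delta, ax, 0.4)))
  expect_equal(pol$modulation[1, 1], 1, tolerance = 1e-12)
  flat <- phasor_polar(phasor_transform(hyperstack(array(1, c(1, 1, N)), ax, 0.4)))
  expect_equal(flat$modulation[1, 1], 0, tolerance = 1e-12)
  # increasing C=C count pulls the fatty-acid phasors towards the origin
  mods <- vapply(c("arachidic acid", "oleic acid", "linolenic acid",
                   "arachidonic acid"), function(nm) {
    p <- oracle_phasor(evaluate_spectrum(lib[[nm]], ax))
    sqrt(sum(p^2))
  }, numeric(1))
  expect_true(all(diff(mods) < 0))
})

test_that("degenerate spectra are rejected", {
  one <- structure(list(values = 2930, n_channels = 1L,
                        stokes_wavelength = 1031.4, retune_step = 0.4,
                        pump_wavelengths = 800,
                        acquisition_order = "descending"),
                   class = "wavenumber_axis")
  hs <- hyperstack(array(1, c(2, 2, 1)), one, 0.4)
  expect_error(phasor_transform(hs), class = "srsphasor_degenerate_spectrum")
  expect_error(phasor_of_spectrum(c(1)), class = "srsphasor_degenerate_spectrum")
})
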
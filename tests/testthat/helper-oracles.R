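# Independent oracles and small fixture builders used across the suite.
# The phasor oracle below deliberately re-derives (G, S) by naive
# term-by-term summation so it never shares code with the package's
# vectorized transform.

oracle_phasor <- function(spectrum, harmonic = 1) {
  N <- length(spectrum)
  g_num <- 0; s_num <- 0; tot <- 0
  for (k in 0:(N - 1)) {
    w <- 2 * pi * harmonic * k / N
    g_num <- g_num + spectrum[k + 1] * cos(w)
    s_num <- s_num + spectrum[k + 1] * sin(w)
    tot <- tot + spectrum[k + 1]
  }
  c(G = g_num / tot, S = s_num / tot)
}

# exhaustive between-class-variance curve over a fixed quantization;
# any threshold on the argmax plateau is a valid Otsu solution
oracle_otsu_variance <- function(x, levels = 256) {
  rng <- range(x)
  u <- (x - rng[1]) / diff(rng)
  h <- tabulate(pmin(floor(u * levels) + 1, levels), levels)
  p <- h / sum(h)
  mids <- (seq_len(levels) - 0.5) / levels
  v <- rep(NA_real_, levels - 1)
  for (t in 1:(levels - 1)) {
    w0 <- sum(p[1:t]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(p[1:t] * mids[1:t]) / w0
    m1 <- sum(p[(t + 1):levels] * mids[(t + 1):levels]) / w1
    v[t] <- w0 * w1 * (m0 - m1)^2
  }
  list(thresholds = rng[1] + mids[-levels] * diff(rng), variance = v)
}

default_axis <- function() build_wavenumber_axis(1031.4, 2800, 3050, 0.4)

# homogeneous single-model stack, optionally with the generator's noise
homogeneous_stack <- function(model, axis = default_axis(), ny = 24, nx = 24,
                              poisson_scale = 0, gaussian_sd = 0, seed = 1) {
  sp <- evaluate_spectrum(model, axis)
  n <- ny * nx
  m <- matrix(rep(sp, each = n), n, axis$n_channels)
  if (poisson_scale > 0 || gaussian_sd > 0) {
    withr::with_seed(seed, {
      if (poisson_scale > 0) {
        m[] <- stats::rpois(length(m), as.vector(m) * poisson_scale) / poisson_scale
      }
      if (gaussian_sd > 0) m[] <- m + stats::rnorm(length(m), 0, gaussian_sd)
    })
  }
  m[m < 0] <- 0
  hyperstack(array(m, c(ny, nx, axis$n_channels)), axis, 0.4)
}

# compact phantom for fast tests; ... overrides the small defaults
small_phantom_config <- function(seed = 1, noiseless = FALSE, ...) {
  args <- list(image_shape = c(4L, 96L, 96L), n_cells = 2L,
               cell_radius_range = c(5.5, 7.5),
               droplet_counts = list(steatosis = 3L, phospholipidosis = 2L,
                                     alkyne = 0L))
  args <- utils::modifyList(args, list(...))
  args$seed <- seed
  if (noiseless) args$noise <- list(poisson_scale = 0, gaussian_sd = 0)
  do.call(phantom_config, args)
}

# do two ROI polygons intersect / contain one another?
rois_disjoint <- function(a, b) {
  pa <- a$polygon; pb <- b$polygon
  if (any(roi_contains(a, pb[, 1], pb[, 2]))) return(FALSE)
  if (any(roi_contains(b, pa[, 1], pa[, 2]))) return(FALSE)
  na <- nrow(pa); nb <- nrow(pb)
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a1, b1, c1) {
      (b1[1] - a1[1]) * (c1[2] - a1[2]) - (b1[2] - a1[2]) * (c1[1] - a1[1])
    }
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (seg_int(pa[i, ], pa[i %% na + 1, ], pb[j, ], pb[j %% nb + 1, ])) {
        return(FALSE)
      }
    }
  }
  TRUE
}
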
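#' Per-pixel spectral phasor transform
#'
#' Projects every pixel spectrum onto the phasor plane via its normalized
#' first-harmonic (or higher) Fourier coefficients. For a spectrum
#' \eqn{I_k, k = 0..N-1} over the acquired window (channels in ascending
#' wavenumber order, the window treated as one period):
#' \deqn{G = \sum_k I_k \cos(2\pi n k/N) / \sum_k I_k, \quad
#'       S = \sum_k I_k \sin(2\pi n k/N) / \sum_k I_k.}
#' Spectrally similar pixels cluster in (G, S); narrow spectra sit near the
#' unit circle and broad spectra near the origin. The phasor of any
#' nonnegative spectrum lies in the unit disc, and is invariant to overall
#' intensity scaling. Pixels with nonpositive total intensity, or outside
#' the supplied foreground mask, are marked invalid.
#'
#' @param stack A [hyperstack()].
#' @param harmonic Harmonic order `n >= 1` (default 1, the standard choice
#'   for spectral phasors).
#' @param mask Optional logical foreground array matching the spatial shape
#'   (e.g. from [background_mask()]).
#' @return A `phasor_map`: list with `G`, `S` (arrays of the spatial shape,
#'   `NA` where invalid), `valid` (logical array), `harmonic`, and the
#'   stack's `axis`.
#' @export
phasor_transform <- function(stack, harmonic = 1L, mask = NULL) {
  N <- stack$axis$n_channels
  if (N < 2) {
    srs_error("srsphasor_degenerate_spectrum",
              "phasor transform needs at least 2 channels")
  }
  if (harmonic < 1) {
    srs_error("srsphasor_invalid_parameter", "harmonic must be >= 1")
  }
  sdim <- spatial_dim(stack)
  m <- stack_matrix(stack)
  if (!is.null(mask)) {
    md <- dim(mask)
    if (is.null(md) || !identical(as.integer(md), as.integer(sdim))) {
      srs_error("srsphasor_invalid_parameter",
                "mask shape does not match the stack's spatial shape")
    }
  }
  k <- 0:(N - 1)
  ang <- 2 * pi * harmonic * k / N
  tot <- rowSums(m)
  G <- as.vector(m %*% cos(ang)) / tot
  S <- as.vector(m %*% sin(ang)) / tot
  valid <- tot > 0
  if (!is.null(mask)) valid <- valid & as.vector(mask)
  G[!valid] <- NA_real_
  S[!valid] <- NA_real_
  dim(G) <- sdim; dim(S) <- sdim; dim(valid) <- sdim
  structure(list(G = G, S = S, valid = valid,
                 harmonic = as.integer(harmonic), axis = stack$axis),
            class = "phasor_map")
}

#' Phasor of a single spectrum
#'
#' Convenience wrapper computing (G, S) for one spectrum or a spectrum
#' model evaluated on an axis; identical maths to [phasor_transform()].
#'
#' @param spectrum Numeric intensity vector, or a `spectrum_model`.
#' @param axis Required when `spectrum` is a model.
#' @param harmonic Harmonic order.
#' @return Named numeric vector `c(G =, S =)`.
#' @export
phasor_of_spectrum <- function(spectrum, axis = NULL, harmonic = 1L) {
  if (inherits(spectrum, "spectrum_model")) {
    spectrum <- evaluate_spectrum(spectrum, axis)
  }
  N <- length(spectrum)
  if (N < 2) {
    srs_error("srsphasor_degenerate_spectrum", "need at least 2 channels")
  }
  tot <- sum(spectrum)
  if (tot <= 0) return(c(G = NA_real_, S = NA_real_))
  ang <- 2 * pi * harmonic * (0:(N - 1)) / N
  c(G = sum(spectrum * cos(ang)) / tot, S = sum(spectrum * sin(ang)) / tot)
}

#' Phasor density histogram
#'
#' 2D histogram of the valid pixels' (G, S) coordinates over the square
#' \eqn{[-1, 1]^2} with uniform bin edges — the density plot of the
#' ensemble of pixel phasors.
#'
#' @param pmap A `phasor_map`.
#' @param bins Number of bins per axis (default 256).
#' @return List with `counts` (bins x bins integer matrix, G along rows),
#'   `g_edges`, `s_edges`.
#' @export
phasor_density <- function(pmap, bins = 256L) {
  if (bins < 2) srs_error("srsphasor_invalid_parameter", "bins must be >= 2")
  g <- pmap$G[pmap$valid]
  s <- pmap$S[pmap$valid]
  edges <- seq(-1, 1, length.out = bins + 1L)
  gi <- pmin(pmax(findInterval(g, edges, rightmost.closed = TRUE), 1L), bins)
  si <- pmin(pmax(findInterval(s, edges, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(gi, levels = seq_len(bins)),
               factor(si, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  list(counts = counts, g_edges = edges, s_edges = edges)
}

#' Polar phasor coordinates
#'
#' Modulation \eqn{\sqrt{G^2+S^2}} (distance from the phasor origin; the
#' quantity that decreases with spectral broadening, e.g. with increasing
#' acyl-chain unsaturation) and phase \eqn{atan2(S, G)}.
#'
#' @param pmap A `phasor_map`.
#' @return List with `modulation` and `phase` arrays (`NA` where invalid).
#' @export
phasor_polar <- function(pmap) {
  list(modulation = sqrt(pmap$G^2 + pmap$S^2),
       phase = atan2(pmap$S, pmap$G))
}
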
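#' Build the Raman-shift axis of a hyperspectral SRS acquisition
#'
#' A hyperspectral stimulated Raman scattering (SRS) stack is acquired by
#' holding the Stokes wavelength fixed and retuning the pump laser in fixed
#' wavelength increments between frames. Each pump wavelength probes the
#' Raman shift \eqn{\nu = 10^7/\lambda_{pump} - 10^7/\lambda_{Stokes}}
#' (wavelengths in nm, shifts in cm^-1). The acquisition steps the pump from
#' the wavelength matching the high end of the requested shift window
#' towards the low end; the axis is stored and reported in ascending
#' wavenumber order, with the acquisition direction kept as metadata.
#'
#' @param stokes_nm Stokes wavelength in nm (e.g. 1031.4).
#' @param shift_start,shift_end Raman-shift window endpoints in cm^-1, in
#'   either order (e.g. 2800 and 3050 for the C-H stretch region).
#' @param retune_step_nm Pump retune increment in nm between frames
#'   (e.g. 0.4).
#' @return An object of class `wavenumber_axis`: a list with `values`
#'   (ascending shifts, cm^-1), `n_channels`, `stokes_wavelength`,
#'   `retune_step`, `pump_wavelengths` (nm, ascending with `values`'
#'   descending order reversed to match), and `acquisition_order`
#'   (`"descending"`: frames are collected from high to low shift).
#' @examples
#' ax <- build_wavenumber_axis(1031.4, 2800, 3050, 0.4)
#' ax$n_channels   # 40 frames across the 2800-3050 cm^-1 window
#' @export
build_wavenumber_axis <- function(stokes_nm, shift_start, shift_end,
                                  retune_step_nm) {
  stopifnot_finite(c(stokes_nm, shift_start, shift_end, retune_step_nm),
                   "axis parameters")
  if (retune_step_nm <= 0 || stokes_nm <= 0) {
    srs_error("srsphasor_invalid_parameter",
              "stokes_nm and retune_step_nm must be positive")
  }
  lo <- min(shift_start, shift_end)
  hi <- max(shift_start, shift_end)
  pump_for <- function(shift) 1e7 / (1e7 / stokes_nm + shift)
  lam_hi <- pump_for(hi)  # shortest pump wavelength (highest shift)
  lam_lo <- pump_for(lo)  # longest pump wavelength (lowest shift)
  n <- as.integer(floor((lam_lo - lam_hi) / retune_step_nm + 1e-9)) + 1L
  if (n < 2) {
    srs_error("srsphasor_degenerate_axis",
              sprintf("retune grid spans %d frame(s); need at least 2", n))
  }
  # acquisition order: pump steps up in wavelength, i.e. shift steps down
  pump <- lam_hi + retune_step_nm * (seq_len(n) - 1)
  shifts <- 1e7 / pump - 1e7 / stokes_nm
  structure(
    list(values = rev(shifts),
         n_channels = n,
         stokes_wavelength = stokes_nm,
         retune_step = retune_step_nm,
         pump_wavelengths = rev(pump),
         acquisition_order = "descending"),
    class = "wavenumber_axis")
}

#' @export
print.wavenumber_axis <- function(x, ...) {
  cat(sprintf("wavenumber_axis: %d channels, %.1f-%.1f cm^-1 (Stokes %.1f nm, retune %.2f nm, acquired %s)\n",
              x$n_channels, min(x$values), max(x$values),
              x$stokes_wavelength, x$retune_step, x$acquisition_order))
  invisible(x)
}

#' Validate a wavenumber axis
#'
#' Checks the axis invariants: strict monotonicity, physical range
#' (0-5000 cm^-1), channel count, and consistency of every shift with a pump
#' wavelength on the retune grid (tolerance 0.05 cm^-1).
#'
#' @param axis A `wavenumber_axis`.
#' @param tol Shift-consistency tolerance in cm^-1.
#' @return `TRUE` invisibly; signals an error on violation.
#' @export
validate_wavenumber_axis <- function(axis, tol = 0.05) {
  v <- axis$values
  if (length(v) != axis$n_channels) {
    srs_error("srsphasor_invalid_axis", "n_channels != length(values)")
  }
  if (any(diff(v) <= 0)) {
    srs_error("srsphasor_invalid_axis", "axis values not strictly increasing")
  }
  if (any(v < 0 | v > 5000)) {
    srs_error("srsphasor_invalid_axis", "axis values outside [0, 5000] cm^-1")
  }
  pump <- 1e7 / (1e7 / axis$stokes_wavelength + v)
  k <- (pump - min(pump)) / axis$retune_step
  grid_pump <- min(pump) + round(k) * axis$retune_step
  grid_shift <- 1e7 / grid_pump - 1e7 / axis$stokes_wavelength
  if (any(abs(grid_shift - v) > tol)) {
    srs_error("srsphasor_invalid_axis",
              "axis values inconsistent with the pump retune grid")
  }
  invisible(TRUE)
}
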
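#' Dice overlap coefficient
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} between two binary masks; 1 for perfect
#' agreement, `NaN` when both masks are empty.
#'
#' @param a,b Logical arrays of identical shape.
#' @return Numeric scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    srs_error("srsphasor_invalid_parameter", "mask shapes differ")
  }
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Derive the default phasor ROI set from the spectral library
#'
#' Builds the canonical five-class ROI set used to segment hepatocyte
#' phantoms: `nucleus` and `cytoplasm` from their compartment models;
#' `total_lipid` as the convex hull of the phasor positions of the nine
#' neat-lipid standards plus both droplet classes; `steatosis` and
#' `phospholipidosis` from their inclusion models. All ROIs are dilated by
#' `padding`. During segmentation the specific lipid classes override
#' `total_lipid`, and later-listed compartments override it as well, so
#' `total_lipid` acts as the fallback lipid region.
#'
#' @param axis A `wavenumber_axis`.
#' @param library Spectral library (default [default_library()]).
#' @param padding ROI dilation in (G, S) units.
#' @param harmonic Harmonic order.
#' @param include_alkyne Add an `alkyne` ROI from the alkyne-drug model.
#' @return Named list of `phasor_roi`s in precedence (listed) order:
#'   total_lipid, nucleus, cytoplasm, steatosis, phospholipidosis
#'   (, alkyne).
#' @export
derive_default_rois <- function(axis, library = default_library(),
                                padding = 0.04, harmonic = 1L,
                                include_alkyne = FALSE) {
  lipids <- attr(library, "neat_lipids")
  lipid_pts <- t(vapply(c(lipids, "steatosis droplet",
                          "phospholipidosis inclusion"),
                        function(nm) phasor_of_spectrum(library[[nm]], axis,
                                                        harmonic),
                        numeric(2)))
  rois <- list(
    total_lipid = derive_roi_from_reference(lipid_pts, "total_lipid",
                                            padding = padding),
    nucleus = derive_roi_from_reference(library[["nucleus"]], "nucleus",
                                        padding = padding, axis = axis,
                                        harmonic = harmonic),
    cytoplasm = derive_roi_from_reference(library[["cytoplasm"]], "cytoplasm",
                                          padding = padding, axis = axis,
                                          harmonic = harmonic),
    steatosis = derive_roi_from_reference(library[["steatosis droplet"]],
                                          "steatosis", padding = padding,
                                          axis = axis, harmonic = harmonic),
    phospholipidosis = derive_roi_from_reference(
      library[["phospholipidosis inclusion"]], "phospholipidosis",
      padding = padding, axis = axis, harmonic = harmonic))
  if (include_alkyne) {
    rois$alkyne <- derive_roi_from_reference(library[["alkyne lamellar body"]],
                                             "alkyne", padding = padding,
                                             axis = axis, harmonic = harmonic)
  }
  rois
}
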
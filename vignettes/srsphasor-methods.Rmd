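---
title: "Spectral phasor analysis of hyperspectral SRS stacks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral phasor analysis of hyperspectral SRS stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srsphasor)
```

This vignette is the package's own account of the science it implements:
the acquisition model, the phasor transform and its properties, how the
synthetic phantom emulates hepatocyte hyperspectral data, which parameters
matter and why their defaults are what they are, and the numerical and
design decisions a maintainer should know about. No empirical claim is
made here beyond what the test suite and `scripts/acceptance.R` compute.

## Acquisition model and the wavenumber axis

Hyperspectral SRS stacks are acquired by holding a Stokes beam at a fixed
wavelength (default 1031.4 nm) and retuning the pump laser in fixed
increments (default 0.4 nm) between frames. Each pump wavelength
$\lambda_p$ addresses the Raman shift
$\nu = 10^7/\lambda_p - 10^7/\lambda_s$ (nm, cm$^{-1}$). Because the pump
steps are uniform in *wavelength*, the resulting shift axis is slightly
non-uniform in cm$^{-1}$ (about 6.3–6.5 cm$^{-1}$ per channel across the
C–H window). `build_wavenumber_axis()` constructs the inclusive grid from
the wavelength matching the top of the requested window down to the last
step inside it; 2800–3050 cm$^{-1}$ at 0.4 nm yields exactly 40 frames.
Acquisition runs high→low shift (the pump retunes upward in wavelength),
but axes are stored and reported ascending, with the acquisition direction
kept as metadata — every consumer of an axis can therefore assume
ascending order.

## The spectral phasor transform

For a pixel spectrum $I_k$, $k = 0..N-1$ over the acquired window
(treated as one period),

$$G = \frac{\sum_k I_k \cos(2\pi n k/N)}{\sum_k I_k}, \qquad
  S = \frac{\sum_k I_k \sin(2\pi n k/N)}{\sum_k I_k}.$$

Three properties carry the whole method and are enforced as tests:

* **Unit-disc bound** — the phasor of any nonnegative spectrum satisfies
  $G^2 + S^2 \le 1$; a delta-like spectrum sits on the unit circle, a flat
  spectrum at the origin.
* **Intensity-scale invariance** — $c\,I$ has the same phasor for any
  $c > 0$, so brightness variations (e.g. the phantom's nucleoli) do not
  move pixels in phasor space.
* **Mixture linearity** — the phasor of $\alpha A + \beta B$ lies on the
  segment joining the phasors of $A$ and $B$, weighted by total
  intensities. The suite checks this against an independently coded
  direct-summation oracle at $10^{-12}$.

The harmonic defaults to $n = 1$, the standard choice for spectral
phasors of single-band windows; higher harmonics are supported but not
used by the pipeline. No baseline is subtracted before the transform: the
measured SRS background is carried into the phasor like any other signal,
which is the conservative choice when the background model is unknown.
Channels enter in ascending wavenumber order.

## ROI segmentation in the phasor plane

Segmentation labels every valid pixel by the polygonal ROI containing its
$(G, S)$ point. Point-in-polygon uses the even-odd rule and is
*boundary-inclusive* (a point on an edge or vertex belongs to the ROI), so
the partition is deterministic at polygon boundaries. Overlaps resolve by
listed order (later wins), except that the specific lipid classes
`steatosis` and `phospholipidosis` always override `total_lipid`: the
specific regions are nested inside the total-lipid region by construction,
and the specific call is the informative one.

Published ROI vertex sets for this kind of segmentation are generally not
available, and this package has no interactive drawing tool. ROIs
therefore come either from JSON or from `derive_roi_from_reference()`,
which encloses the phasor position (or noisy phasor cloud) of a
pure-class reference in a convex polygon dilated by a padding (default
0.04 in $(G,S)$ units). The padding default is sized against the
per-pixel phasor noise at the generator's default settings (σ ≈ 0.010 per
coordinate, so the ROI covers ≈ 4σ) while staying below half the smallest
inter-class distance in the calibrated library (0.094), so that derived
ROIs never overlap. ROIs produced this way are flagged
`derived_from_reference` in all outputs, since they stand in for the
hand-drawn ROIs an operator would use on real data. A reference cloud
whose hull spans more than 1.0 in $(G,S)$ — half the disc's diameter — is
rejected as ambiguous rather than silently enclosed.

## The synthetic phantom: what it emulates, and what it does not

The generator renders HepG2-like cells: non-overlapping ellipsoidal cells
(lateral semi-axes 6.5–8.5 µm) containing one nucleus with 1–3 brighter
nucleoli sharing the nucleus spectrum (×1.6 intensity by default),
cytoplasm, and spherical inclusions of three classes — steatosis-type
neutral-lipid droplets, phospholipidosis-type CH₂-rich inclusions, and
optionally alkyne-tagged drug inclusions. Default geometry: 120×120 px at
0.4 µm and 6 z-planes at 1 µm (z-stacks are acquired at 1 µm increments),
inclusion radii 0.8–1.5 µm. Voxels take exactly their class model's
spectrum; there is no partial-volume mixing, which keeps the analytic
sphere-volume and ground-truth-spectrum oracles exact.

Spectra are sums of Lorentzian bands (the natural Raman line shape) over
a constant baseline, with widths of 16–34 cm$^{-1}$. Band *positions* are
anchored to standard C–H-region assignments (2851 CH₂, 2885 CH₂
asym/Fermi, 2930 CH₃, 2965 nucleic-acid, ~3010 =CH, 2233 alkyne; the
cholesteryl-linoleate ester tail at 3015). Band *amplitudes and widths*
are free design parameters of the phantom: they were calibrated once so
that the generator reproduces the qualitative contrasts the method relies
on — droplet CH₂/CH₃ ratio ≥ 0.8 and nucleus ≤ 0.2 on noiseless
phantoms, a nuclear spectral peak at the channel nearest 2965 cm$^{-1}$,
strictly decreasing phasor modulation across
arachidic → oleic → linolenic → arachidonic acid (0, 1, 3, 4 C=C), and
nine mutually separated neat-lipid phasor clusters at default noise —
and then frozen in the versioned file
`inst/extdata/spectral_library_v1.yaml`, which tests pin. Changing that
file is a breaking change to the package's reference geometry.

Noise is shot-noise-like Poisson resampling (variance ∝ intensity;
`poisson_scale` = 400 expected counts per unit intensity, a mid-range SNR
for video-rate SRS) followed by additive Gaussian read noise
(σ = 0.01), with negative values clipped at zero and the clipped fraction
reported. Absolute SRS intensities and SNR are instrument-specific and
not standardized; these defaults were chosen once as realistic for the
contrasts above and are not tuned per analysis.

The phantom deliberately omits: the optical point-spread function,
cross-phase-modulation and photothermal backgrounds, partial-volume
mixing at boundaries, spectral variability within a class, and cell-shape
irregularity. Passing tests on phantoms therefore demonstrate the
*correctness of the computations* (transform, segmentation back-projection,
volumetry, statistics) under a known forward model — not robustness to
the full messiness of real microscope data; per-class Dice ≈ 1 at these
noise levels should be read in that light.

## Quantification choices

* **Ratio maps** use nearest-channel matching within 5 cm$^{-1}$ by
  default (half the channel spacing of the standard 40-frame axis is
  ≈ 3.2 cm$^{-1}$); the pipeline widens the tolerance proportionally on
  coarser axes. The 0–1 display clamp common for ratio rendering is a
  display property and never touches statistics.
* **Volumetry** thresholds the 2851 cm$^{-1}$ channel (Otsu within the
  cell foreground by default, manual override available), labels
  26-connected components in 3D, drops components under 4 voxels, and
  reports voxel-count × pixel² × z-step, both per droplet and aggregated
  per cell — the per-droplet and per-cell views answer different
  questions (droplet size distribution vs cellular lipid burden), so both
  are emitted. Caveat: Otsu assumes a meaningfully bimodal within-cell
  histogram; in a condition with almost no droplets it can lock onto the
  nucleus/cytoplasm split instead. The analysis driver therefore derives
  one pooled threshold across conditions and applies it globally, the
  usual practice when comparing treatments.
* **Percent areas** divide by each cell's foreground area (not the whole
  image), matching the per-cell reading of treatment effects; cell
  instances come from the phantom ground truth or from user-supplied
  masks — automatic cell segmentation is intentionally out of scope.
* **Colocalization** is plain Pearson correlation over masked pixels
  between the 2851 cm$^{-1}$ lipid channel and the 2233 cm$^{-1}$ alkyne
  channel. In the phantom, drug trapping is modelled by rendering
  drug-bearing lamellar bodies with a phospholipid + alkyne mixture
  spectrum, versus independent drug aggregates with a drug-only spectrum;
  the former yields r ≈ 0.65–0.7, the latter |r| < 0.05 at default
  settings.
* **Statistics**: one-way ANOVA with Tukey HSD across all conditions plus
  pairwise t tests; the t default is pooled-variance Student's t (Welch
  behind a flag). Significance tiers N.S./*/**/*** at 0.05/0.01/0.001.

## The pKa² + cLogP² risk band

Cationic amphiphilic drugs drive phospholipidosis roughly in proportion
to basicity and lipophilicity; the screening score pKa² + cLogP² with an
inconclusive open band (75, 85) encodes this. The band is read with
strict inequalities, so a score of exactly 75 is conclusive-low and
exactly 85 conclusive-high; endpoints are configurable. Richer published
decision rules exist (with additional per-parameter cutoffs), but only
this band is encoded; computing pKa/cLogP from structures is out of
scope — values are user-supplied. The shipped compound panel
(`inst/extdata/synthetic_compounds.csv`) is synthetic demonstration data,
not measurements.

## Numerical and storage decisions

* **TIFF interchange** uses 16-bit samples of `data/intensity_scale` with
  the scale and full-precision axis in a YAML sidecar. 16 bits comfortably
  cover the 12-bit depth of typical SRS acquisition, and the package's
  writer/reader pair is an exact fixed-point map, so write→read
  round-trips are bit-exact; the generator snaps its output onto the same
  grid (quantum ≈ scale/65535 ≈ 4×10⁻⁵), which is also the precision at
  which "noiseless phantom equals model spectrum" holds.
* **Determinism**: phantoms are bit-reproducible from (config, seed) via
  an isolated RNG scope; pipeline summaries contain no timestamps and
  serialize with full digits, so reruns are byte-identical.
* **Degenerate inputs** fail loudly with classed conditions: constant
  images under Otsu, axes with fewer than two frames, spectra with fewer
  than two channels, empty segments, zero-variance colocalization,
  under-replicated designs, droplet packings that cannot be placed within
  the attempt budget.
* **Tie-breaks**: nearest-channel matching takes the single closest
  channel (ties broken toward the lower index by `which.min`); Otsu
  plateaus (empty inter-mode gaps) may return any maximizer — the tests
  assert maximal between-class variance, not a particular plateau point.

## Design decisions that were genuinely open

* The pipeline performs no stage caching. At the problem sizes this
  package targets (phantom fields and single-field microscope stacks) a
  full run takes seconds, and content-addressed caches add invalidation
  risk with no measurable benefit.
* There is no command-line wrapper. The package functions, the numbered
  drivers under `analysis/`, and `scripts/acceptance.R` are the intended
  entry points for scripted use.
* `segment_spectrum` normalizes to max = 1 by default — the convention
  that makes band-ratio changes visible on a common axis — with area
  normalization available.
* Problem sizes in the shipped tests and drivers (120×120×6 default
  fields, 96×96×4 in fast tests, 20-seed recovery studies, 200-rep power
  simulation) were chosen as the smallest sizes at which the targeted
  effects are comfortably resolved; all scale linearly if enlarged.

## Known limitations

Single-harmonic analysis only; no machine-learning segmentation of the
phasor plane; no automatic cell instance segmentation; no proprietary
microscope formats (plain TIFF + sidecar only); the phantom's optics-free
forward model as discussed above. Real-data ROI placement remains an
expert step: derived ROIs are a reproducible substitute, not a claim that
reference spectra of pure compounds match intracellular spectra exactly.
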
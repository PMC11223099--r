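# srsphasor

Label-free detection of drug-induced liver injury (DILI) phenotypes from
hyperspectral stimulated Raman scattering (SRS) microscopy. The package
implements spectral phasor analysis of hyperspectral image stacks —
per-pixel Fourier projection of the C–H stretch spectrum onto the (G, S)
phasor plane, ROI-based segmentation of cellular compartments and lipid
classes, and back-projection into image space — together with the
quantitative readouts built on it: ratiometric CH₂/CH₃ lipid maps, 3D
lipid-droplet volumetry from z-stacks, per-cell percent-area statistics
that discriminate drug-induced steatosis (DIS, neutral-lipid droplets)
from drug-induced phospholipidosis (DIPL, phospholipid-rich lamellar
bodies), alkyne-tag colocalization, and a physicochemical DIPL risk score
from pKa and cLogP.

It is aimed at imaging scientists and DMPK/toxicology groups who want to
analyze hyperspectral SRS stacks of hepatocyte-like cells — or prototype
such analyses — without fluorescent stains. Because raw microscope data
are rarely shareable, the package ships a synthetic hyperspectral
cell-phantom generator with voxel-level ground truth, so the entire
pipeline is testable and every reported number is reproducible from code.

## The model

A hyperspectral SRS stack holds one image per Raman shift ν (cm⁻¹),
acquired by retuning the pump laser in fixed wavelength steps against a
fixed Stokes beam; each pixel carries a spectrum *I₀ … I_{N−1}* over the
acquired window (by default 2800–3050 cm⁻¹ in 40 frames: 1031.4 nm Stokes,
0.4 nm pump retune). The spectral phasor of a pixel is the pair of
normalized first-harmonic Fourier coefficients

    G = Σₖ Iₖ cos(2πnk/N) / Σₖ Iₖ ,   S = Σₖ Iₖ sin(2πnk/N) / Σₖ Iₖ ,

with harmonic n = 1 and channels in ascending wavenumber order. The phasor
of any nonnegative spectrum lies in the unit disc, is invariant to overall
intensity, and is linear in mixtures — spectrally similar pixels cluster,
so compartments (nucleus, cytoplasm) and lipid classes (total lipid,
steatosis, phospholipidosis) can be segmented as polygonal ROIs in (G, S)
and projected back onto the image. Narrow spectra sit near the unit
circle, broad spectra near the origin; the modulation √(G²+S²) therefore
falls with increasing acyl-chain unsaturation across fatty-acid standards.

Downstream quantities follow standard conventions: R = I(2851)/I(2930) is
the CH₂/CH₃ lipid-to-protein ratio; droplet volumes come from
26-connected components of thresholded single-frequency z-stacks
(voxels × pixel² × z-step); percent areas are per cell against the cell's
foreground; group comparisons use one-way ANOVA with Tukey HSD and
Student's t tests; and the DIPL risk score is pKa² + cLogP², with scores
strictly between 75 and 85 treated as inconclusive.

## Worked example

```r
library(srsphasor)

# acquisition geometry: 2800-3050 cm^-1 at 0.4 nm pump retune
ax <- build_wavenumber_axis(1031.4, 2800, 3050, 0.4)
ax
#> wavenumber_axis: 40 channels, 2801.5-3050.0 cm^-1 (Stokes 1031.4 nm,
#> retune 0.40 nm, acquired descending)

# phasor position of a neat lipid standard
p <- phasor_of_spectrum(default_library()[["oleic acid"]], ax)
round(p, 3)
#>      G      S
#> -0.020  0.378

# a synthetic phospholipidosis-like cell population with ground truth
ph <- generate_phantom(default_phantom_config("phospholipidosis", seed = 1))
ph
#> labeled_phantom: 6 x 120 x 120 voxels; 3 cells
#>  background  nucleus  cytoplasm  steatosis  phospholipidosis  alkyne
#>       73774     1104      10473        241               808       0

# full pipeline: mask -> phasor -> ROI segmentation -> per-cell statistics
rep <- run_pipeline(run_config(conditions = c("control", "phospholipidosis"),
                               n_replicates = 3, seed = 42))
rep
#> srsphasor run: 18 cell rows across 2 condition(s)
#>          condition mean_ratio pct_area_steatosis pct_area_phospholipidosis
#> 1          control      0.448               2.53                      0.00
#> 2 phospholipidosis      0.480               1.66                      6.84
#> ...
#> == pct_area_phospholipidosis ==
#> one-way ANOVA: F(1, 16) = 100.348, p = 2.68e-08 (***)
```

The phospholipidosis condition raises the green-segment percent area from
0.00% to 6.84% of cell area (p = 2.7×10⁻⁸) and the mean cellular CH₂/CH₃
ratio from 0.448 to 0.480, while the steatosis percent area is unchanged —
the pattern that separates DIPL from DIS.

The `analysis/` directory holds numbered drivers that walk the same
workflow end to end (phantom simulation, lipid phasor reference map,
condition comparison, volumetry + colocalization, risk scoring), writing
tables under `results/`.

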
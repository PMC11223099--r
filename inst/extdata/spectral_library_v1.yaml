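# Versioned Lorentzian spectral library for the C-H stretch window.
# Band centers follow standard assignments (2851 CH2 sym, 2885 CH2 asym/FR,
# 2930 CH3, 2965 nucleic acid CH3, ~3010 =CH, 2233 alkyne). Amplitudes and
# widths are calibrated package parameters: changing them changes phasor
# cluster geometry, so tests pin this file via its version string.
version: 1
neat_lipids:
  - arachidic acid
  - glyceryl tristearate
  - sphingomyelin
  - cholesterol
  - cholesteryl linoleate
  - L-alpha-phosphatidylcholine
  - linolenic acid
  - oleic acid
  - arachidonic acid
models:
  - name: arachidic acid
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 18, amplitude: 1.00}
      - {center: 2885, fwhm: 22, amplitude: 0.45}
      - {center: 2930, fwhm: 22, amplitude: 0.30}
  - name: glyceryl tristearate
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 22, amplitude: 1.00}
      - {center: 2885, fwhm: 24, amplitude: 0.35}
      - {center: 2930, fwhm: 26, amplitude: 0.85}
  - name: sphingomyelin
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 20, amplitude: 1.00}
      - {center: 2880, fwhm: 24, amplitude: 0.55}
      - {center: 2930, fwhm: 24, amplitude: 0.35}
      - {center: 2965, fwhm: 22, amplitude: 0.25}
  - name: cholesterol
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 32, amplitude: 0.60}
      - {center: 2870, fwhm: 28, amplitude: 0.60}
      - {center: 2905, fwhm: 28, amplitude: 0.38}
      - {center: 2930, fwhm: 30, amplitude: 0.72}
      - {center: 2950, fwhm: 26, amplitude: 0.38}
  - name: cholesteryl linoleate
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 24, amplitude: 1.00}
      - {center: 2885, fwhm: 26, amplitude: 0.30}
      - {center: 2930, fwhm: 26, amplitude: 0.45}
      - {center: 3015, fwhm: 22, amplitude: 0.52}
  - name: L-alpha-phosphatidylcholine
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 34, amplitude: 0.85}
      - {center: 2930, fwhm: 34, amplitude: 0.70}
      - {center: 3010, fwhm: 28, amplitude: 0.22}
  - name: linolenic acid
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 24, amplitude: 0.90}
      - {center: 2930, fwhm: 26, amplitude: 0.45}
      - {center: 3010, fwhm: 24, amplitude: 0.45}
  - name: oleic acid
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 16, amplitude: 1.10}
      - {center: 2895, fwhm: 24, amplitude: 0.12}
      - {center: 2930, fwhm: 22, amplitude: 0.30}
      - {center: 3010, fwhm: 22, amplitude: 0.22}
  - name: arachidonic acid
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 28, amplitude: 0.75}
      - {center: 2930, fwhm: 28, amplitude: 0.55}
      - {center: 3010, fwhm: 26, amplitude: 0.60}
  - name: nucleus
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 26, amplitude: 0.10}
      - {center: 2930, fwhm: 28, amplitude: 0.90}
      - {center: 2965, fwhm: 24, amplitude: 1.00}
  - name: cytoplasm
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 28, amplitude: 0.40}
      - {center: 2930, fwhm: 30, amplitude: 1.00}
      - {center: 2965, fwhm: 26, amplitude: 0.28}
  - name: steatosis droplet
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 22, amplitude: 1.00}
      - {center: 2885, fwhm: 26, amplitude: 0.30}
      - {center: 2930, fwhm: 26, amplitude: 0.50}
      - {center: 3010, fwhm: 24, amplitude: 0.30}
  - name: phospholipidosis inclusion
    baseline: 0.01
    bands:
      - {center: 2851, fwhm: 34, amplitude: 0.90}
      - {center: 2930, fwhm: 34, amplitude: 0.80}
      - {center: 2965, fwhm: 30, amplitude: 0.25}
      - {center: 3010, fwhm: 28, amplitude: 0.12}
  - name: alkyne drug
    baseline: 0.01
    bands:
      - {center: 2233, fwhm: 18, amplitude: 1.00}
      - {center: 2851, fwhm: 26, amplitude: 0.45}
      - {center: 2930, fwhm: 28, amplitude: 0.50}
  - name: alkyne lamellar body
    baseline: 0.01
    bands:
      - {center: 2233, fwhm: 18, amplitude: 1.00}
      - {center: 2851, fwhm: 34, amplitude: 0.90}
      - {center: 2930, fwhm: 34, amplitude: 0.80}
      - {center: 2965, fwhm: 30, amplitude: 0.25}
      - {center: 3010, fwhm: 28, amplitude: 0.12}
  - name: background
    baseline: 0.02
    bands:
      - {center: 3000, fwhm: 400, amplitude: 0.02}
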
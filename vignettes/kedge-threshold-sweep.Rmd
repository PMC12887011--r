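---
title: "Energy-threshold optimization for K-edge contrast materials: model and methods"
author: "kedgeCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Energy-threshold optimization for K-edge contrast materials: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

A photon-counting CT detector with two counting thresholds splits every
acquisition into a low-energy image (photons between the thresholds) and a
high-energy image (photons above the upper threshold, up to the tube
potential). For a contrast material with a K edge — an abrupt upward jump
in attenuation at the binding energy of its K-shell electrons — the choice
of the upper threshold decides how much of the post-edge, strongly
attenuating part of the spectrum lands in each bin. `kedgeCT` simulates
this end to end for a cylindrical water phantom carrying inserts of
fifteen candidate elements (iodine and barium as clinical agents, calcium
and iron as biological references, gadolinium and bismuth as candidate
agents, nanoparticle candidates, and a run of lanthanides), sweeps the
upper threshold over 50–90 keV in 5 keV steps with the lower threshold
fixed at 20 keV, and measures three things per setting: water-background
noise, insert contrast, and pairwise material separability.

## Model components and assumptions

### Attenuation physics

Per-element total mass attenuation tables are bundled as plain text under
`inst/extdata/attenuation/`. They were computed once from a
Cromer–Liberman relativistic photoabsorption calculation (which carries
every absorption edge), plus Klein–Nishina incoherent scattering with a
form-factor-based incoherent scattering function and coherent scattering
integrated from IT92 atomic form factors. Against standard reference
values for water and aluminum the tables agree to within about 1.5% over
20–150 keV; for a heavy element (lead) the agreement is within about 4%,
with the K-edge jump ratio reproduced to 2%. Edges are stored as
duplicated energy abscissae — the first row holds the value just below
the edge, the second just above — so interpolation (linear in
log-energy/log-attenuation, the standard practice for attenuation data)
never bridges a discontinuity; a query exactly at the edge returns the
above-edge branch.

Solutions are ideal dilute mixtures: $\mu(E) = \mu_{water}(E) + c \cdot
(\mu/\rho)_{solute}(E)$ with $c$ in g/cm³ and water at 1.0 g/cm³. Solute
volume displacement is neglected, which keeps attenuation exactly affine
in concentration — the property the matched-concentration design of the
phantom relies on. Air uses the standard dry composition at 1.205 mg/cm³.

### Source spectrum

The tube model is a Kramers bremsstrahlung continuum (photon fluence
$\propto (kV - E)/E$ per 1 keV bin) at 120 kV, filtered by 2.5 mm
aluminum, hardened by an equivalent 0.03 mm tungsten anode
self-filtration (which also imprints the physical tungsten K-edge dip at
69.5 keV), with tungsten characteristic lines at 59.3 and 67.2 keV
carrying 8% and 4% of the continuum fluence. The resulting mean energy is
about 58 keV, inside the range an established spectrum-modeling tool
produces for these settings. The 1 keV grid over 20–120 keV resolves
every K edge in the phantom at the fidelity of the 5 keV threshold sweep.
The spectrum can be exported or replaced via two-column text files
(`write_spectrum()`/`read_spectrum()`).

### Acquisition and detector

Geometry is 2-D parallel-beam, single slice: the metrics of the study are
single-slice ROI statistics, and threshold physics does not depend on the
helical fan-beam geometry of a clinical scanner. The detector is an ideal
energy discriminator: every photon is counted in the bin its true energy
falls in. There is no charge sharing, pulse pileup, or scatter. Expected
counts per ray follow Beer–Lambert composition over the analytic chord
lengths through background and inserts; Poisson noise is sampled per ray
(deterministically under a seed); flat-field normalization divides by the
air-scan expectation and takes the negative log. Zero counts are clamped
to 0.5 before the log — the standard log-sinogram guard — and a photon
starvation warning fires if more than 1% of rays clamp.

### Reconstruction and corrections

Projections pass through a water beam-hardening linearization
(`correct_water_hardening()`): the exact polychromatic water curve
$p(t)$ for the bin's incident spectrum is inverted to water-equivalent
thickness and rescaled by the incident-bin effective water attenuation,
so a pure water object reconstructs uniformly. Reconstruction is filtered
back projection with the discrete Ram-Lak kernel and linear
interpolation. Each bin and threshold gets its own HU calibration
(`bin_calibration()`), measured from noise-free reconstructions of a
water cylinder of the same diameter and an air scan, because the
bin-effective water attenuation shifts as the bin moves — this mirrors
scanner air/water corrections. Noisy images are denoised with a 2-D
Gaussian of 1 pixel standard deviation by default (the single-slice
analog of volumetric Gaussian filtering; the width is a convention, and
`denoise(sigma_px = 0)` is the exact identity).

### Metrology

Contrast is the difference of ROI means, insert minus background, per bin
image. Noise is the sample standard deviation in the central
water-background ROI. For separability, each insert contributes per-voxel
two-component vectors (low-bin HU, high-bin HU) from spatially matched
masks; for materials A and B the Hotelling template
$w = S^{-1}(\bar{x}_A - \bar{x}_B)$, with $S$ the equally weighted
average of the two sample covariances plus a ridge of
$10^{-6}\,\mathrm{tr}(S)/d$, yields per-voxel test statistics
$\lambda = w \cdot x$, and the separability index is

$$ s' = \frac{\bar{\lambda}_A - \bar{\lambda}_B}
   {\sqrt{\tfrac12\,(\sigma^2_{\lambda A} + \sigma^2_{\lambda B})}} $$

reported as a magnitude (with the sign retained separately). On Gaussian
classes this estimator converges to the closed form
$\sqrt{\Delta\mu^\top S^{-1} \Delta\mu}$, which the test suite verifies
(bias below 2% at $n = 10^5$), along with exact symmetry and invariance
under common invertible channel transforms. A covariance that stays
degenerate after the ridge raises an error instead of silently returning
zeros.

ROI conventions: insert ROI radius is 60% of the insert radius;
background ROI is a 2 cm circle at the phantom center. Both are
configurable in `run_sweep()`.

## Key parameters

| parameter | default | units | rationale |
|---|---|---|---|
| background radius | 15 | cm | 30 cm body-size phantom |
| insert radius | 1.25 | cm | clear ROI separation on two rings (5 and 10 cm) |
| concentrations | Ca 50, Fe 30, others 4 | mg/mL | matched to the clinical iodine level; biological materials at dual-energy-phantom levels |
| tube potential | 120 | kV | fixed study setting |
| thresholds | 20 fixed low; 50–90 step 5 high | keV | the sweep under study |
| filtration | 2.5 Al + 0.03 W | mm | typical CT inherent filtration; anode self-absorption |
| N0 (test preset) | 1.09e6 | photons/ray | calibrated so low-bin water noise at T = 50 is ~16 HU |
| N0 (paper preset) | 1.82e7 | photons/ray | same anchor at full resolution |
| denoise sigma | 1 | px | fixed smoothing convention for noisy images |
| Hotelling ridge | 1e-6 | fraction of tr(S)/d | numerical stabilizer, surfaced if insufficient |

The photon budget is a free calibration constant: the clinical dose
descriptors (mAs, CTDIvol) cannot be mapped to per-ray fluence without a
vendor detector model, so the package anchors N0 to the reported low-bin
noise level at the lowest threshold instead, separately for each preset.

## Presets and problem sizes

Two presets bundle the sampling choices: `"paper"` (512 px at 0.5 mm, 360
views, 729 channels) matches the reported reconstruction pixel;
`"test"` (128 px at 2.8125 mm over a 36 cm field, 180 views, 183
channels) is the package's reduced preset used by the test suite and the
acceptance script, where a full noise-free sweep takes a few seconds and
replicate noisy sweeps a few minutes. The spectral transmission of the
phantom is computed once per geometry (`ray_transmission()`) and reused
across all thresholds and bins, which is what makes the sweep cheap.

## What the simulation does and does not emulate

The generator reproduces: polychromatic Beer–Lambert attenuation with
exact K-edge discontinuities, bin partitioning by ideal thresholds,
Poisson counting noise and its threshold dependence, beam hardening and
its correction, FBP noise texture, and the HU calibration chain. On this
physics the high-bin contrast of a K-edge material peaks at (within one
sweep step of) the first threshold clearing its edge, and pairs of
lanthanides with closer edges are harder to separate — both checked by
the test suite.

It deliberately does not emulate: detector spectral distortions (charge
sharing, pileup, cross-talk), scatter, bowtie filtration, helical 3-D
geometry, or tube-current modulation. One measurable consequence: in the
low-energy bin, after 30 cm of water, the detected spectrum is hard
regardless of the threshold, so the low-bin HU contrast of materials
whose K edge lies below about 40 keV (iodine, barium, calcium, iron)
declines monotonically across the sweep here. Measured systems can
instead show a mid-sweep contrast peak in the low-energy image, which
requires low-bin counts originating from high-energy photons — a
detector-response effect outside this model. Passing tests therefore
validate the ideal-detector threshold physics, not vendor-specific
spectral response.

## Numerical choices

- Energy grid: 1 keV bins; bins partition [20, 120] exactly (low bin
  `[20, T)`, terminal high bin `[T, 120]`), so low + high counts equal
  the full-spectrum counts to machine precision.
- Argmax queries (`peak_threshold()`, `best_separation_threshold()`)
  break ties toward the lower threshold — the lower setting leaves more
  photons in the high bin and hence less noise.
- Noise-free mode is used for contrast-argmax questions (they are
  physics-driven; Poisson noise only adds flake); noisy seeded mode for
  noise and separability questions.
- Seeds: `run_sweep()` derives one seed per threshold/bin from the base
  seed; identical configuration and seed reproduce results bitwise.
- Degenerate inputs: inverted bins, overlapping ROIs, negative
  concentrations, and degenerate HU calibrations raise errors rather
  than propagating.

## Known limitations

Absolute HU contrast and noise values depend on the spectrum model and
photon-budget calibration and should be read comparatively, not as
scanner predictions. The separability index from small ROIs (tens of
voxels at the reduced preset) carries sampling error; replicate averaging
is advisable, and the test suite does so. Only two bins and 120 kV are
modeled; material decomposition downstream of separability is out of
scope.

## A minimal session

```{r example}
library(kedgeCT)

sweep <- run_sweep(noise_free = TRUE)          # reduced preset, ~seconds
peak_threshold(sweep, "Lu", "high")            # contrast-optimal threshold
best_separation_threshold(sweep, "I", "Gd")    # separability-optimal
autoplot(sweep, type = "contrast")
render_report(sweep, "sweep-out")
```
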
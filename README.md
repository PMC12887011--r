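# kedgeCT

Simulation and spectral metrology of K-edge contrast materials in
two-threshold photon-counting CT.

## The problem

Photon-counting CT detectors assign each detected photon to an energy bin
defined by counting thresholds. With a fixed low threshold (20 keV) and a
swept upper threshold *T*, every scan yields a low-energy image (photons
in [20, *T*)) and a high-energy image (photons in [*T*, 120]). For a
contrast element with a K edge — the discontinuous jump in x-ray
attenuation at its K-shell binding energy — the threshold decides how
much post-edge, strongly attenuating signal lands in each bin. Anyone
evaluating candidate contrast agents (iodine, gadolinium, bismuth,
nanoparticle metals, lanthanides) needs to know which threshold maximizes
a material's signal and which best separates two materials given to the
same patient.

`kedgeCT` answers both questions with a desk-scale, fully self-contained
simulation: an analytic 30 cm water phantom with 16 inserts (15 elements
at matched concentrations plus a water control), a filtered 120 kV
polychromatic spectrum, an ideal two-bin counting detector, Beer–Lambert
forward projection with exact K-edge physics, Poisson noise, filtered
back projection with water beam-hardening correction and per-bin HU
calibration, and the study metrics on top.

## The metrics

Per threshold and bin image:

- **Contrast** (HU): `Contrast = mean(insert ROI) − mean(background ROI)`.
- **Noise** (HU): standard deviation in the central water ROI.
- **Separability** of materials A and B: per-voxel (low, high) HU vectors
  feed the linear Hotelling observer, `w = S⁻¹(x̄_A − x̄_B)` with pooled
  covariance `S = (Σ_A + Σ_B)/2`; each voxel's test statistic is
  `λ = w·x`, and the separability index is

  ```
  s' = (λ̄_A − λ̄_B) / sqrt( (σ²_λA + σ²_λB) / 2 )
  ```

  Larger |s'| means the two materials are easier to tell apart at that
  threshold.

## Worked example

```r
library(kedgeCT)

sweep <- run_sweep(noise_free = TRUE)   # 50-90 keV sweep, reduced preset
sweep
#> <kedge_sweep> 9 thresholds (50-90 keV), 16 materials, noise-free mode
#>   grid 128 px @ 2.8125 mm, 180 views x 183 channels, N0 = 1.09e+06

dplyr::filter(peak_thresholds(sweep), bin == "high",
              material %in% c("Lu", "Ta", "W", "Pt", "Au", "Bi"))
#> # A tibble: 6 x 3
#>   material bin   peak_threshold_keV
#> 1 Au       high                  80
#> 2 Bi       high                  90
#> 3 Lu       high                  65
#> 4 Pt       high                  80
#> 5 Ta       high                  70
#> 6 W        high                  70
```

Each of these peaks sits at (or one 5 keV step from) the first sweep
threshold clearing the material's K edge — lutetium's edge is 63.3 keV,
so its high-bin contrast peaks at 65 keV; bismuth's edge (90.5 keV) lies
at the top of the sweep, so its contrast keeps rising to 90. In noisy
mode the same driver reports noise:

```r
noisy <- run_sweep(seed = 7)            # Poisson noise + 1 px denoising
unique(noisy$metrics[, c("threshold_keV", "bin", "noise_HU")]) |>
  dplyr::filter(bin == "low") |> head(3)
#>   threshold_keV bin   noise_HU
#> 1            50 low      17.9
#> 2            55 low      10.4
#> 3            60 low       8.83
```

Low-bin noise falls as the threshold rises (the bin gains photons) while
high-bin noise rises; the per-ray photon budget is calibrated so the
low-bin noise at T = 50 sits near 16 HU. `autoplot(sweep, type =
"noise")`, `"contrast"`, `"separability"`, `"matrix"` draw the standard
figures; `render_report(sweep, dir)` persists tidy CSVs, a resolved
config, and the figure set; `tidy()`/`glance()` expose the tables.

A thin command-line wrapper with verbs `build-phantom`, `simulate`,
`reconstruct`, `metrics`, `sweep`, `report` lives at
`inst/cli/kedgect.R`.

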
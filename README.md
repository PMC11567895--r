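# chromrings

Quantitative analysis of large-scale chromatin organization in single
nuclei from multi-channel fluorescence z-stacks, built around the
"concentric chromatin rings" phenotype: in fasted *C. elegans*
intestinal cells, chromatin redistributes into a thin shell around the
central nucleolus (inner ring) and a shell at the nuclear envelope
(outer ring), while fed cells show a single mid-radius peak.

The package provides, as composable R functions:

- **Radial chromatin profiling** — intensity rays from the nucleolus
  centre to every point of the nuclear contour, per-ray distance
  normalization (0% = nucleolus centre, 100% = contour), pooling into
  twenty 5%-wide bins, max-normalization per nucleus, and condition
  averages with a 95% confidence band. A resolvability filter discards
  rays whose nucleolar-edge-to-periphery segment is shorter than the
  imaging resolution limit (default 9 px), and an absolute-distance
  variant profiles intensity in micrometres from the nucleolus edge.
- **Two-peak ring model** — bounded least-squares fit of
  `B + A_i exp(-(x - x_i)^2 / 2σ_i²) + A_o exp(-(x - x_o)^2 / 2σ_o²)`
  to a single-nucleus chromatin profile (amplitudes and background in
  `[0, max]`, centres within ±5% of their starting values, widths in
  (0, 100)%), the outer-to-inner amplitude ratio `A_o/A_i`, the
  Gaussian–Airy resolution limit `d = 1.45 σ_io + 2 Δx_e`, and a
  rule-based classifier of nuclei into `two_rings` / `partial` /
  `single_peak`.
- **Nucleolar volumetry and FISH** — 3D Gaussian smoothing, Yen/Li
  automatic thresholding, 26-connected component labelling, separable
  3D Gaussian fitting on raw intensities with ellipsoid volume
  `V = (4/3) π σ_z σ_y σ_x`, projected nucleolar/nuclear areas, and
  background-corrected integrated FISH intensity (background = median
  of in-nucleus, non-spot pixels at the central slice).
- **Positioning statistics** — the three-zone equal-area assay
  (boundaries `R√(2/3)`, `R√(1/3)`; zone 1 most peripheral), the
  nucleolus-edge-to-periphery decile assay, chi-squared comparisons of
  zone counts, and the composite profile-comparison procedure: per-bin
  permutation tests on nucleus labels, Bonferroni adjustment (m = 20),
  and combined-probability statistics over the 0–30%, 35–65% and
  70–100% regions.
- **Synthetic scenes** — a generator of single-nucleus z-stacks with
  known ground truth: spherical nucleus, central nucleolus, fed/fasted
  radial chromatin density, anisotropic voxels (200 nm z-spacing),
  Gaussian PSF, Poisson photon noise and camera read noise, plus
  reporter spots and nucleolar FISH signal. Every test in the package
  validates the analysis against this generator's recorded truth.

## Worked example

```r
library(chromrings)

cohort <- generate_cohort(
  scene_config(chromatin_mode = "fed",    condition = "fed"),
  scene_config(chromatin_mode = "fasted", condition = "fasted"),
  n_per_condition = 5, seed = 1)
profs <- profile_cohort(cohort)
cond  <- vapply(cohort, function(s) s$condition, character(1))

summary(fit_two_peaks(profs[[which(cond == "fasted")[1]]]))
#> Two-peak chromatin ring model (fasted_001)
#>       B     A_i     x_i sigma_i     A_o     x_o sigma_o
#>  0.0918  0.8982 23.1738 12.3484  0.5106 90.8169  7.4906
#> RSS: 0.01086 (converged)
#> outer/inner amplitude ratio: 0.5685
```

The fitted inner peak sits at ~23% of the centre-to-contour distance
(just outside the nucleolus) and the outer peak at ~91% (the nuclear
periphery); the amplitude ratio ~0.57 recovers the generator's 0.6 up
to the attenuation from PSF blur and binning.

```r
compare_condition_profiles(profs[cond == "fed"], profs[cond == "fasted"],
                           n_perm = 999, seed = 1)
#> <profile_comparison> 999 permutations, fisher combination
#> region p-values:
#>   0-30%  35-65% 70-100%
#>  0.0231  0.0231  0.0231
```

Even with only 5 nuclei per condition, the combined region statistics
flag the redistribution at the nucleolar edge (0–30%) and the nuclear
periphery (70–100%).

```r
sc  <- cohort[[which(cond == "fasted")[1]]]
seg <- detect_spots(sc$channels$nucleolus, sc$mask3d, method = "auto")
nm  <- select_nucleolus(seg, annotation = sc$nucleolus_center,
                        nucleus_mask = sc$mask3d)
fit_gaussian3d(sc$channels$nucleolus, nm, sc$voxel_xy, sc$voxel_z)
#> 3D Gaussian spot fit ( 1088 voxels )
#> ...
#> volume: 230.5 voxel^3 = 0.7793 um^3  (converged)
```

The fitted nucleolar volume (0.7793 µm³) matches the scene's imaged
(PSF-convolved) ground-truth volume of 0.7817 µm³ within 0.4%.

## Documentation

The methods vignette (`vignettes/chromrings-methods.Rmd`) describes the
model, its assumptions, the synthetic-scene generator, all tunable
parameters with their defaults, and known limitations.
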
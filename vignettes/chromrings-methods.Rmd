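---
title: "Radial chromatin profiling and nucleolar volumetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial chromatin profiling and nucleolar volumetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromrings)
```

## The measurement problem

In intestinal cells of fasted *C. elegans*, chromatin reorganizes into
two concentric shells: one apposed to the nuclear envelope and one
wrapped around the single, centrally located nucleolus. In a confocal
section through the nuclear centre these shells appear as two rings,
and in a radial intensity profile as two peaks. `chromrings`
quantifies this phenotype per nucleus from a fluorescence z-stack
(chromatin channel: a tagged histone or DNA stain; nucleolus channel:
tagged fibrillarin), a 2D or 3D nucleus mask, and a manually annotated
nucleolus-centre coordinate.

## Single-nucleus chromatin profiles (SNCPs)

For one nucleus the pipeline is:

1. Take the 2D mask at the central plane (for a 3D mask, the slice at
   the mask's voxel centroid, rounded; exact half-way ties round toward
   the lower slice for determinism).
2. Extract the ordered boundary contour of the mask.
3. Cast one ray from the nucleolus-centre annotation to every contour
   vertex, sampling intensity by bilinear interpolation every 0.5 px,
   with the last sample exactly on the contour.
4. Normalize each ray's sample distances by that ray's length
   (0% = centre, 100% = contour).
5. Pool all samples into twenty 5%-wide bins: `[0, 5)` percent maps to
   bin centre 2.5%, ..., `[95, 100]` to 97.5%. Bins are half-open with
   the last bin closed, so every sample lands in exactly one bin.
6. Average samples within each bin, then divide the 20-bin profile by
   its maximum.
7. Average SNCPs across nuclei of a condition; the confidence band is
   `mean ± z(0.975) · SD/√n` (normal approximation — with the typical
   48–72 nuclei per condition the difference from a t quantile is
   negligible; the level is configurable).

Two ambiguities required a decision. Binning can average the pooled
samples directly (default) or first per ray and then across rays; both
are implemented (`bin_and_normalize(method = )`) and agree exactly for
balanced sampling. Empty bins — possible for very small nuclei — are
filled by linear interpolation from neighbouring bins and flagged in
the profile object, keeping the 20-bin contract; a profile with a
single occupied bin propagates that value.

For small nuclei (muscle nuclei are roughly 25% of the intestinal
nuclear *volume*), rays may be too short to resolve two peaks.
`filter_resolvable_rays()` drops rays whose nucleolar-edge-to-contour
segment is shorter than the resolution limit (default 9 px, see below).
An absolute-distance variant, `nucleolus_edge_profile()`, re-expresses
samples in micrometres beyond each ray's nucleolus-edge crossing,
which makes the inner ring's apposition to the nucleolar surface
directly visible without radial normalization.

## The two-peak ring model

Each max-normalized SNCP is fit with

$$y(x) = B + A_i e^{-(x - x_i)^2 / 2\sigma_i^2}
           + A_o e^{-(x - x_o)^2 / 2\sigma_o^2},$$

by bounded Levenberg–Marquardt least squares (unweighted over the 20
bins): amplitudes and background in `[0, max(profile)]`, each centre
within ±5 percentage points of its starting value, widths in (0, 100)%
(implemented as `[1e-6, 100 - 1e-6]`). The outer/inner ratio `A_o/A_i`
summarizes ring balance; a zero inner amplitude yields `Inf` with a
warning rather than a silent division.

The starting values matter because of the tight centre bounds. The
default initializer is deterministic and data-driven: centres at the
two largest strict local maxima (inner = smaller distance), widths 8%,
amplitudes the profile height above its minimum, background the
minimum. A single-peaked profile anchors the nearer centre at its
global maximum and places the other start at a fixed 25% or 90%
(whichever side is free); anchoring at fixed positions on both sides
was rejected because a mid-radius peak would then be unreachable under
the ±5% bound and the optimizer degenerates. Starting values are also
nudged strictly inside the box: a parameter that begins exactly on a
bound never moves in the bounded update.

### Resolution limit

Approximating the microscope's Airy pattern by a Gaussian, the minimum
resolvable separation of the two peaks is

$$d \approx 1.45\,\sigma_{io} + 2\,\Delta x_e,$$

with `σ_io` the average fitted peak width and `Δx_e` the average offset
between peak centres and the nucleolar edge / nuclear periphery, in
pixels. `estimate_resolution()` converts fitted percent-scale widths to
pixels via the mean ray length. The default ray filter length of 9 px
is the rounded-up value of this limit for the muscle cohort
(d ≈ 8.7 px at σ_io = 3.2414 px, Δx_e = 2 px).

### Organization classes

Published scorings of nuclei into "two rings" / "partial" /
"single peak" categories are visual; `classify_organization()` is an
explicit, reproducible surrogate: `two_rings` requires both fitted
amplitudes to exceed a configurable fraction (default 0.25) of the
profile maximum above background *and* the peak separation to be at
least `d`; an amplitude below the threshold gives `single_peak`;
everything else is `partial`. The thresholds are design choices of this
package, not published criteria, and are recorded in every call object.

## Nucleolar volumetry and FISH quantification

Detection follows the standard spot-segmentation recipe: 3D Gaussian
smoothing (σ = 0.75 voxel), automatic thresholding inside a search
mask, 26-connected 3D labelling. Both Yen and Li thresholds are
provided (computed on a 256-bin histogram); `method = "auto"` tries Yen
and falls back to Li when Yen returns nothing, more than five
components, or only components below a plausible spot size (10 voxels)
— Yen can lock onto the histogram peak of a smooth blob. The method
actually used is always recorded.

The volume comes from a separable 3D Gaussian
`g(x)g(y)g(z) + B` fitted to the *raw* (unsmoothed) intensities inside
the selected component — fitting the smoothed signal would inflate the
widths — with the ellipsoid volume `V = (4/3) π σ_z σ_y σ_x` reported
in voxel³ and µm³ (`µm³ = voxel³ × voxel_xy² × voxel_z`). Fits are
performed in voxel coordinates with explicit unit conversion.
Initialization is the intensity-weighted centroid and second moments;
`B` is bounded by the dimmest voxel in the component, which prevents
the amplitude/background degeneracy that arises when only the bright
core of a blob is segmented.

Because the imaged object is the PSF-convolved nucleolus, the
synthetic-scene truth records both the generative sigmas and the
effective post-PSF sigmas (`σ_eff = √(σ² + σ_PSF²)` per axis); recovery
is judged against the effective volume, which is what any
image-domain estimator measures.

FISH quantification sums raw voxel values over all segmented spot
voxels and subtracts `voxel count × background median`, the background
median taken over central-slice pixels inside the nucleus but outside
the segmented objects. The corrected sum is exactly zero on a constant
stack and invariant to adding a constant offset.

## Positioning assays

The three-zone assay divides the nuclear disc (at the plane where the
scored locus is brightest) into concentric zones of equal area with
boundaries `R√(2/3)` and `R√(1/3)`; zone 1 is the most peripheral ring
— the convention of the zoning-assay literature, stated here explicitly
because it is easy to invert. Boundary ties go to the more peripheral
zone. The decile assay maps the relative nucleolus-edge-to-periphery
position to bins 0–9 (bin 0 adjacent to the nucleolus edge, last bin
closed); loci inside the nucleolus are flagged, not binned. Zone count
tables are compared with Pearson's chi-squared test (no continuity
correction).

## Comparing condition profiles

Profile comparison is a three-stage composite:

1. **Per-bin permutation test.** The statistic is the absolute
   difference of condition means in that bin; nucleus-level condition
   labels are permuted (nuclei are the exchangeable display unit —
   what exactly is permuted is a design decision of this package), and
   the p-value uses the add-one estimator `(1 + #{≥ obs})/(1 + n_perm)`
   so it is never zero. An exact mode enumerates all label assignments
   for small groups. Default `n_perm` = 10,000; the seed is mandatory.
2. **Bonferroni adjustment** with m = 20 (all bins; whether the two
   never-combined bins should count is unstated in the source
   procedure, so the inclusive m is used and configurable).
3. **Combined-probability statistic** per region — 0–30%, 35–65% and
   70–100% of the centre-to-contour distance (six bins each; the bins
   at 32.5% and 67.5% fall in the gaps and enter no region). The
   default combiner is `-2 Σ log p` against the upper tail of
   χ²(2k) (Fisher's product method); a `-2 Σ log(1 - p)` lower-tail
   variant (Pearson's complement form) is selectable because the two
   are often conflated under the name "Pearson's combined probability
   test". Both reduce to the identity for a single p-value, and the
   choice is recorded in the output.

## The synthetic-scene generator

`generate_nucleus_scene()` renders what the analysis consumes: a
spherical nucleus (default radius 3 µm, jittered across a cohort with
CV 0.08) with a single central nucleolus, on an anisotropic grid
(130 nm xy pixels, 200 nm z-spacing). The chromatin channel follows the
same two-Gaussian radial density the ring model fits, with presets

- **fed**: single peak, `A_i = 1, x_i = 0.55, σ_i = 0.15, B = 0.1`
  (a mid-radius maximum, no nucleolar or peripheral enrichment);
- **fasted**: `A_i = 1, x_i = 0.25, σ_i = 0.10` and
  `A_o = 0.6, x_o = 0.90, σ_o = 0.07, B = 0.1` (inner ring just outside
  the nucleolus, outer ring at the periphery, outer/inner ratio 0.6).

These presets are qualitative emulations of the fed/fasted line-plot
shapes, not published parameter values. The nucleolus channel is a 3D
Gaussian (σ = 0.55 µm per axis by default); reporter loci are
diffraction-limited Gaussian spots at a chosen relative radius; FISH
signal is a PSF-convolved *uniform ellipsoid* (default semi-axes
0.9 µm), because precursor-rRNA probes light up the nucleolar volume
rather than a point — and a point source's integral is fundamentally
unrecoverable to within a few percent by threshold segmentation, while
a filled compartment's is. Channels are blurred with an anisotropic
Gaussian PSF (σ_xy = 0.08 µm, σ_z = 0.25 µm — near the diffraction
limit of a high-NA objective), converted to photons
(default 200 photons per intensity unit), Poisson-sampled, read-noise
corrupted (SD 1.5 counts) and quantized to integer camera counts.
Tissue presets scale the nuclear radius: muscle = 0.25^(1/3) ≈ 0.63,
reading "muscle nuclei are ~25% of intestinal size" as volume —
the conservative interpretation; hypoderm = 0.85.

Ground truth (ring parameters, nucleolus sigmas and volume both
generative and post-PSF, spot positions and injected integrals) is
recorded before blur and noise, which is what makes the test suite's
recovery checks possible.

What the generator deliberately does **not** emulate: multiple nuclei
per field, neighbouring-tissue signal, intestinal autofluorescence,
photobleaching, nucleolar vacuoles, chromatin texture (the density is
radially smooth), or sub-voxel anti-aliasing (voxel-centre sampling).
Passing recovery tests on these scenes therefore demonstrates
correctness of the estimators under the stated imaging model, not
robustness to every artefact of real micrographs.

## Numerical conventions and test scales

- In-memory arrays are 1-based `(y, x, z)`; all file coordinates are
  0-based `(z, y, x)`; stacks are stored as 16-bit integer-count TIFFs
  and tables round-trip at full double precision.
- Fits run to the optimizer's default tolerances with a 500-iteration
  cap and report convergence and bound-activity flags rather than
  failing silently.
- The test suite validates calibration of the permutation test with
  200 replicates of 10 + 10 fed-preset nuclei at `n_perm = 999`
  (muscle-sized scenes keep this affordable), parameter recovery on
  100 noiseless profiles and 50 noisy fasted scenes, volumetry on 50
  scenes with varied sigma triplets, and end-to-end discrimination on
  20 + 20 cohorts; these sizes were chosen as the smallest that give
  stable statistics for the properties being checked.

## Known limitations

- The nucleolus-centre annotation is an input, as in the manual
  workflow; no automatic detection of the "inner dark region" is
  attempted.
- Profiles assume a single connected nucleus mask and a single
  nucleolus; multi-nucleolar cells are out of scope.
- The amplitude ratio `A_o/A_i` is measured on the blurred, binned
  image and therefore carries a small attenuation relative to the
  underlying density (the narrower outer peak is attenuated slightly
  more); comparisons between conditions imaged identically are
  unaffected.
- The organization classifier's thresholds are package defaults, to be
  tuned per imaging setup; they are exposed in `analysis_config()` and
  logged with every call.
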
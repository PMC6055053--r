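---
title: "Methods: low-level fusion of Raman and MALDI imaging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-level fusion of Raman and MALDI imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specfuse)
```

## The problem

Raman microscopy and MALDI-TOF imaging interrogate the same tissue
section with different physics: Raman spectra describe the overall
vibrational (chemical) composition at high spatial resolution, while
MALDI mass spectra resolve individual ion species - in lipid-range
imaging, individual lipids - at coarser resolution. Analyzed jointly,
the two are complementary. *Low-level (centralized) fusion* concatenates
the preprocessed per-pixel spectra of both modalities into one matrix
and analyzes them together, rather than fusing model outputs.

The catch is scale. After sensible per-spectrum normalizations (vector
normalization for Raman, total-ion-count for MALDI) the two blocks
differ in dimensionality and dynamic range by orders of magnitude, and a
joint PCA simply reproduces the dominant block. `specfuse` implements
the whole chain - preprocessing, co-registration, weighting, fused PCA -
plus a phantom generator that makes every stage testable without any
external data.

## Pipeline and model

The fixed stage order of `run_pipeline()` is:

1. **Co-registration** (first, before spectral preprocessing): a
   6-parameter affine transform is fitted by least squares to manually
   picked landmark pairs (`fit_affine`); Raman pixel centres are mapped
   into the MALDI frame, each is assigned to its nearest MALDI grid
   point, and assigned spectra are averaged (`resample_to_grid`). With
   the 25 um / 75 um pitches of a typical experiment, an interior MALDI
   pixel receives 9 Raman spectra. Grid points receiving nothing are
   flagged and excluded from fusion.
2. **Raman preprocessing**: cosmic-spike detection and removal, SNIP
   fluorescence background subtraction, vector (l2) normalization.
3. **MALDI preprocessing**: SNIP chemical-background subtraction (with
   LLS dynamic-range compression), per-pixel phase correction of the m/z
   axis, peak picking, mass-relative binning, TIC normalization.
4. **Weighting and fusion**: the MALDI block is rescaled by
   `w = ||A||_1 / ||B||_1`, the ratio of the blocks' matrix l1-norms
   (sums of absolute entries), which makes the two blocks' total
   absolute intensities exactly equal; then `[A | wB]` is concatenated
   with per-column provenance.
5. **Evaluation**: column-mean-centred PCA (no per-column
   standardization - unit-variance scaling would equalize the blocks and
   erase the weighting question), cumulative explained-variance curves,
   a sweep of the weighting coefficient, per-modality loading splits,
   RGB score composites, and cross-modality channel correlations.

The quality criterion for a weighting is deliberately indirect: for a
complex biological sample, many independent features should be
extractable, so the *best* weighting is the one whose cumulative
explained-variance curve rises **slowest** with the number of PCs. The
`weight_sweep()` operation maps this criterion over a coefficient grid
(1..20 by default).

## Key parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `snip.window_raman` | 40 | channels | SNIP half-window; must exceed the band half-width. Larger windows sag at map edges (reach ~ m(m+1)/2 channels). |
| `snip.window_maldi` | 25 | channels | applied to profile spectra before peak picking, with LLS compression on. |
| `raman.spike_z` | 8 | robust-MAD units | spike flagging threshold. |
| `maldi.snr` | 6 | - | peak SNR cutoff, with `noise = "local"` (see below). |
| `maldi.tolerance_ppm` | 200 | ppm | mass-relative binning tolerance against the running intensity-weighted bin centroid. |
| `maldi.max_shift` | 0.5 | Da | maximum credible phase shift; anchors above the 0.99 intensity quantile of the mean spectrum. |
| `fuse.weight` | `"auto"` | - | the l1-norm ratio; any positive number overrides. |

## Numerical and design choices

**SNIP.** The clipping rule per window p is
`y_i <- min(y_i, (y_{i-p} + y_{i+p})/2)`, iterated for p = 1..m
(increasing; the decreasing order is available). Out-of-range indices
clamp to the edge, which means a rising ramp is clipped near its top
end; tests therefore assert exactness on the interior. Without LLS the
estimate is a pointwise lower envelope (`baseline <= y`), so the
subtracted spectrum keeps a small positive offset everywhere - this
matters for peak picking (below). LLS defaults off for Raman and on for
MALDI, whose shot-noise background spans a larger dynamic range.

**Spike detection.** Cosmic spikes hit one detector pixel during one
acquisition; genuine Raman bands are shared by neighbouring pixels. The
statistic is the sum of symmetric spatial second differences of each
channel image (the 5-point Laplacian at interior pixels). One-sided
stencils are never used - they respond to gradients of smooth fields
and would flag map edges - so edge pixels use the one direction with
both neighbours and the four corners go unscreened. Scores are
standardized by median/MAD over the whole map. A detection-limit remark:
for an isolated spike of amplitude a in noise of scale s, no statistic
can exceed z = a/s, so at the conventional threshold of 8 robust units a
"10 x noise" spike is detected with at best ~95-98% probability; in
practice raw Raman spectra carry baseline and band structure, so an
amplitude calibrated to 10 x the local MAD of the *data* sits well
above the threshold and recall is robust.

**Peak picking.** The contract statistic is `snr x estimate_noise(y)`
with the diff-based MAD estimator. For pipeline use this is evaluated
*locally* (block-wise noise plus a block-median local level): the SNIP
lower envelope leaves a ~1 sigma positive offset that a zero-referenced
threshold would count as signal, and MALDI noise is heteroscedastic
(shot noise follows the chemical background). Without the local level,
thousands of noise maxima pass any global threshold; with it, the
phantom's ~33 true peaks are recovered with a handful of extras.

**Phase correction.** Anchors are local maxima of the pixel-mean
spectrum above an intensity quantile; each anchor is matched per pixel
to the *strongest* refined local maximum within `max_shift` (nearest
matching is fragile against small noise maxima that happen to sit
closer than the true shifted peak), and a constant offset (optionally
offset + slope) is fitted by least squares. Apexes are refined to
sub-channel precision by a 3-point parabola; recovered uniform shifts
are accurate to ~1 mDa at 0.05 Da channel spacing.

**Binning.** Peaks from all pixels are pooled, sorted, and clustered in
one greedy left-to-right pass that opens a new bin when the next m/z
exceeds the running intensity-weighted centroid by more than the
mass-relative tolerance. This is deterministic and invariant to pixel
order, and widening absolute tolerance with mass matches how TOF peak
width grows.

**PCA.** Computed by SVD of the centred matrix; explained proportions
are taken against the total variance of the full centred matrix so they
remain correct under truncation. Loading signs are fixed so each
column's largest-magnitude element is positive, making score composites
reproducible. RGB composites clip each channel to its 2nd-98th
percentile before min-max scaling; constant channels map to 0.5 and
missing grid cells render neutral grey.

## The phantom: what it emulates, and what it does not

`generate_phantom()` renders K = 3 smooth abundance fields (random
Gaussian blobs plus one geometric region each) in the MALDI frame.
Component 3 - "the lipid" - has **no Raman endmember**; its ions exist
only in the MALDI block, and its raw signal energy is pinned to 1% of
the Raman block's (`lipid_energy_ratio = 0.01`). The Raman map lives on
a 25 um raster rotated by 2 degrees and translated relative to the
75 um MALDI raster, with exact landmarks recorded. Raman spectra are
abundance-weighted pseudo-Voigt bands at plausible positions (1004,
1340, 1660, ... cm^-1) over a per-pixel cubic fluorescence baseline
whose coefficients vary smoothly across the map (fluorophore content is
a tissue property), plus Gaussian noise and sparse cosmic spikes. MALDI
spectra are Gaussian ion peaks with width growing as m/z (constant
resolving power 6000), 3-peak isotope envelopes (1 : 0.6 : 0.2 at
+1.0034 Da spacing), per-pixel uniform m/z jitter (+-0.15 Da), an
exponentially decaying chemical background, multiplicative TIC
variation and Poisson-like noise.

Three generator choices deserve explanation because the headline
experiment depends on them:

* **Field decorrelation.** Random blob fields can correlate at |r| up
  to ~0.7 by chance on a 400-pixel grid, which would make "which
  component does this PC recover" unanswerable. The raw fields are
  therefore whitened (Cholesky) on the MALDI grid before a logistic
  squash into [0, 1]; the resulting true components are spatially
  independent and recovery correlations are attributable.
* **Matrix-cluster ions.** Spatially uniform "matrix" ions (CHCA-like
  clusters at 609-689 Da) dominate the TIC. This mirrors real
  lipid-range MALDI spectra and is what keeps TIC normalization from
  imprinting compositional closure (a shared 1/TIC factor) onto the
  minor ions: with only the ~20 component ions present, the lipid
  abundance estimate is capped at |r| ~ 0.82 to its own truth no matter
  how clean the data, because the denominator varies with the *other*
  components. The matrix ions also provide the stable intense anchor
  peaks that phase correction needs.
* **Energy ratio as the contrast dial.** At the stated 1:100
  lipid-to-Raman energy ratio, the lipid direction is invisible to the
  unweighted fused PCA (best |r| ~ 0.1-0.4 among the first 3 PCs) but
  is recovered by the third PC at |r| > 0.9 once the blocks are
  l1-equalized - mirroring the third-component reading of the real
  experiment. Setting the ratio to 1:1 makes both variants recover it,
  confirming the contrast is scale-driven, not structural.

What a green phantom test does **not** establish: real tissue
morphology, ion suppression and matrix effects, detector saturation,
mass-dependent calibration drift beyond a constant offset, or Raman
intensity calibration across devices. The phantom is a controlled world
for the *pipeline logic*, not a simulator of mouse brain.

## Worked example

```{r example, eval = FALSE}
res <- run_pipeline(run_config(list(seed = 42)))
res$report$fuse$w                  # ~9.7: the Raman block dominates
res$report$recovery$best_abs_r     # per-component recovery, weighted
# compare with the unweighted case
res1 <- run_pipeline(run_config(list(seed = 42, fuse = list(weight = 1))))
res1$report$recovery$best_abs_r
```

On the default phantom (seed 42) this prints a weighting coefficient of
about 9.7 and lipid recovery of about 0.97 (weighted) versus about 0.14
(unweighted); the exact numbers are recomputed by
`scripts/acceptance.R` and asserted by `tests/testthat/test-acceptance.R`.

## Known limitations

* imzML support is a minimal reader/writer pair (continuous and
  processed modes, 64-bit floats, external binary arrays) validated by
  round-trip; vendor idiosyncrasies and compressed arrays are out of
  scope. Exact micrometre coordinates ride along as userParams.
* Phase correction models a constant (optionally linear) shift; true
  TOF miscalibration can be nonlinear in m/z.
* The cumulative-variance criterion compares curves of the *same*
  dimensionality; comparing across data of different dimensionality can
  mislead and is not done automatically.
* Landmark selection is manual by design; intensity-based registration
  is out of scope.
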
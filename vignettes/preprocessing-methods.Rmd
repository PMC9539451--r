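---
title: "Methods: preprocessing cyclic multiplexed fluorescence imaging data"
author: "codexpp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: preprocessing cyclic multiplexed fluorescence imaging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cyclic multiplexed immunofluorescence (CODEX-style) experiments image the
same tissue section over tens of cycles, revealing two to four antibody
channels per cycle. The raw data for one region is a grid of overlapping
microscope tiles, each a short z-stack, repeated per channel and cycle.
Before any cell-level analysis the tiles must be turned into a single
aligned hyperstack — one registered mosaic plane per (cycle, channel) —
and four physical nuisances must be corrected on the way:

1. **Optical blur**: every plane mixes in-focus and out-of-focus light
   (the microscope's 3-D point-spread function).
2. **Axial drift**: the best-focus plane wanders within the z-stack over
   hours-to-days of cyclic imaging.
3. **Lateral drift**: the stage does not return to identical positions
   across cycles, and within a cycle adjacent tiles are not placed at
   their exact nominal offsets.
4. **Autofluorescence**: endogenous fluorophores — erythrocytes above
   all — masquerade as marker signal, drowning weak markers.

`codexpp` implements the full chain: Born–Wolf PSF synthesis and
single-iteration accelerated Richardson–Lucy deconvolution, per-address
best-focus selection, phase-correlation registration against a reference
cycle, stage-model stitching with linear blending, blank-cycle
background subtraction, and detection/zeroing of high-intensity
autofluorescent objects. A synthetic-experiment generator produces
raw datasets with known ground truth so that every stage is testable
without external data.

# Data model and conventions

All indices are 1-based (tiles, z-planes, channels, cycles, pixels), the
natural convention of the host language. Images are `(row, col)` = `(y,
x)` matrices with the origin at the top left. Tiles are numbered
row-major over the grid (a serpentine option exists but is off by
default, since acquisition scan order varies by instrument). The
canonical file addressing is
`region_RRR/cycle_CCC/tile_TTT_z_ZZ_ch_K.tif` — a bijection between
addresses and paths — with a pluggable parser for other naming schemes.
All intermediate computation is floating point; final outputs are
clipped to `[0, 65535]` and stored as 16-bit TIFF. The hyperstack is a
multi-page 16-bit TIFF whose cycle/channel axis metadata lives in a JSON
sidecar (`<file>.tif.json`), so the pair round-trips losslessly.

An experiment directory is self-describing through `experiment.yaml`.
`discover_layout()` reconciles the declared layout with the directory
tree; cycles not yet on disk are dropped and the layout is flagged
`partial`, so any acquired portion of an experiment can be processed
while imaging continues.

# Deconvolution

## PSF model

The widefield PSF is the Born–Wolf model: for an aberration-free
objective of numerical aperture $\mathrm{NA}$ focused in a medium of
refractive index $n_i$, the amplitude at lateral radius $r$ and defocus
$z$ is the pupil integral

$$U(r, z) = \int_0^1 J_0\!\left(k\,\mathrm{NA}\, r \rho\right)
  \exp\!\left(-\tfrac{i k z \mathrm{NA}^2 \rho^2}{2 n_i}\right)\rho\,
  d\rho, \qquad k = 2\pi/\lambda,$$

and the intensity PSF is $|U|^2$. `generate_psf()` evaluates the
integral per voxel by composite Simpson quadrature over $\rho$ (257
nodes), exploiting radial symmetry: a fine radial profile is computed
per z-plane and interpolated onto the pixel grid. The volume is
normalized to unit sum; with an even number of planes the focal plane
sits at index $\lfloor (n_z-1)/2 \rfloor + 1$. The oracle test compares
the focal-plane FWHM against the same integral evaluated on an
8×-oversampled radial grid.

The default acquisition optics are a 20×/0.75 NA air objective with
377.44 nm lateral pixels and 1500 nm z-steps, and emission wavelengths
425/525/595/670 nm for the four standard filters. Note the lateral
Airy FWHM at these settings ($0.51\lambda/\mathrm{NA} \approx 357$ nm)
is *below* one pixel: the data are laterally undersampled, so measured
FWHMs hover near 1 px and deconvolution gains are correspondingly
modest at the pixel scale.

## Accelerated Richardson–Lucy with an unmatched back projector

Classical Richardson–Lucy iterates
$e_{k+1} = e_k \cdot \mathrm{PSF}^\ast \!\otimes\!
\left(\mathrm{raw} / (\mathrm{PSF} \otimes e_k)\right)$
and needs tens of iterations. Replacing the flipped PSF
$\mathrm{PSF}^\ast$ with an engineered *unmatched back projector* makes
a single iteration sufficient. The back projector is built in the
frequency domain as $W(k) \cdot B(k)$:

* $W = \overline{H} / (|H|^2 + \alpha)$ is the Wiener inverse of the
  PSF's transfer function $H$; $\alpha$ (default 0.05) keeps the
  inversion away from division by zero. (Published guidance also
  mentions an $\alpha$ range of 0.001–0.005 for other data; both scales
  are exposed, and the default follows the setting used for this data
  type.)
* $B(\rho) = 1/\sqrt{1 + \varepsilon^2 \rho^{2n}}$ with
  $\varepsilon^2 = 1/\beta^2 - 1$ is an $n$-th order Butterworth
  low-pass over the normalized radial frequency $\rho$, so that $B = 1$
  at DC and exactly $\beta$ (default 0.1) at the resolution limit
  $\rho = 1$; $n$ (default 20) sets the transition slope. The combined
  amplitude at the cutoff is therefore $\beta$ *times the Wiener
  amplitude there* — $\beta$ is read as relative to $W$, the reading
  consistent with the multiplicative construction.
* The cutoff is the incoherent widefield limit: $2\,\mathrm{NA}/\lambda$
  laterally and $\mathrm{NA}^2/(2 n_i \lambda)$ axially, expressed in
  the stack's frequency units.

The update starts from $e_0 = \mathrm{raw}$ (standard, and the scheme is
designed to converge in one step), guards the ratio with
$\epsilon = 10^{-6}\max(\mathrm{raw})$, reflect-pads the stack by the
PSF half-width before the FFT and crops after (suppressing wrap-around
ringing at tile borders; a periodic mode exists and makes deconvolution
exactly shift-equivariant), clips the result at zero, and applies **no
intensity rescaling** — output stays on the input scale, which
preserves weak signal downstream. A `backend` flag exists for
configuration portability; only the CPU path is implemented here.

# Axial focus correction

Focus is scored per plane with selectable operators — `tenengrad` (mean
squared Sobel gradient magnitude; the default: robust on fluorescence
texture and cheap), `variance_of_laplacian`, `brenner`, and
`normalized_variance`. All increase with sharpness; the gradient-based
three are invariant to constant intensity offsets. `select_best_plane()`
takes the argmax, breaking ties toward the stack center (then the lower
index), since the acquisition centers the nominal focal plane.

The decisive design point is that the best plane is selected
*independently for every (tile, channel, cycle) address*, not inherited
from one predefined reference cycle — inheriting indices is exactly what
lets axial drift push later cycles out of focus. Focus is scored on the
raw planes, before deconvolution, so that deconvolution ringing cannot
bias the scores; the downstream pipeline then takes the selected plane
from the deconvolved stack.

# Between-cycle registration

Per tile, the reference-channel best-focus plane of each cycle is
registered against the same tile in the reference cycle (default: cycle
1, nuclear channel). The estimator is Fourier phase correlation: the
peak of the inverse FFT of the normalized cross-power spectrum, refined
to 1/20 px by local matrix-multiply DFT upsampling around the integer
peak. Numerical choices:

* A Hann window suppresses edge spectral leakage for full-frame
  content (it is *not* used for adjacent-tile stitching, where the
  shared signal sits at the tile edges the window would destroy).
* An optional magnitude floor (`reg`) on the whitening denominator
  damps the high-frequency noise that full normalization amplifies on
  resampled or weakly textured inputs.
* Rotation and isotropic scale, when requested (`mode = "similarity"`),
  are recovered by phase correlation of log-polar resampled Fourier
  magnitudes (720 angular × 360 log-radius bins, cosine-taper
  high-pass), followed by one refinement pass on the de-rotated image
  and a final translation estimate. A rotation estimate above 45° is
  flagged unreliable and the estimator falls back to translation only.
  The default mode is translation-only: cyclic stage drift is
  overwhelmingly translational, and the translation path is faster and
  more robust.

Estimates whose correlation peak falls below 0.03 (empty tiles without
tissue) are replaced by the identity and flagged, so featureless tiles
cannot inject wild transforms. The transform estimated on the reference
channel is applied — inverted — to all sibling channels of that (cycle,
tile): one transform per cycle and tile, shared across channels.
Applying a transform resamples with bilinear interpolation (exact
integer-shift and Fourier-interpolated pure-translation fast paths),
zero-filling out-of-frame pixels. Transforms serialize losslessly to
CSV at full precision.

# Within-cycle stitching

Stitching follows the stage-model approach of fast grid stitchers: for
every horizontally and vertically adjacent pair of tiles (reference
cycle, reference channel, best focus), phase correlation proposes
candidate offsets — the top 8 peaks in all wrap-around interpretations,
plus every offset within a ±10 px window around the nominal grid offset
— each candidate is scored by the normalized cross-correlation (NCC) of
the overlap it implies, the best is kept and hill-climbed to the local
NCC maximum. The nominal-window search matters on sparse cellular
scenes: with ~15% overlap, chance disk coincidences elsewhere in the
frame can out-rank the true correlation peak.

The mechanical stage model is deliberately simple: per direction, the
robust center (median) of valid pair offsets, with repeatability
estimated as the scaled MAD. Pairs with NCC below 0.5, or farther than
3× repeatability from the center, are replaced by the model value and
flagged; with no valid pair at all the model falls back to the nominal
overlap fraction. Global positions accumulate pairwise offsets along a
maximum-NCC spanning tree anchored at tile 1 (flagged pairs carry
weight 0), translation-only, and are validated in tests against a dense
least-squares oracle on small grids. This is a faithful-behavior, not
bit-identical, re-implementation of the cited full algorithm, which
adds a global hill-climb optimization stage.

Mosaics are composed by linear blending: each tile carries a separable
weight that ramps linearly from the tile edge over the overlap width —
only on sides that have a grid neighbor, plateauing at 1 elsewhere — and
each output pixel is the weight-normalized sum of covering tiles. With
exact overlaps the weights form a partition of unity before
normalization; with jitter, the normalization absorbs the imbalance.
Mosaic geometry is computed once per region, on the reference cycle,
and reused for every cycle and channel (between-cycle drift is already
removed by registration, so per-cycle re-stitching would only add
noise).

# Background subtraction and artifact removal

Blank cycles (no marker fluorophores) record tissue autofluorescence.
For marker channels of stained cycles the aligned first-blank mosaic is
subtracted after exposure-time scaling,
$\max(0, M - B \cdot t_M / t_B)$. This handles diffuse autofluorescence
but not intense objects such as erythrocytes, whose brightness varies
between cycles so that subtraction leaves residuals.

Those objects are removed by a five-step chain on the blank image
(default: the Cy3-like channel of the first blank cycle, where
erythrocyte autofluorescence is strongest), in this pinned order:

1. min–max normalization followed by CLAHE (clip 0.02, 8×8 tiles) —
   absolute scale is destroyed here, which is why step 4 goes back to
   the original image;
2. multilevel Otsu thresholding (3 classes: background, moderate,
   intense autofluorescence), keeping the topmost class as the binary
   mask;
3. removal of connected components (8-connectivity) smaller than 10 px
   — noise;
4. removal of objects whose mean intensity *on the original,
   un-enhanced blank* is below 20% of 65535 (= 13107) — the threshold
   is an absolute-scale quantity, so it cannot be measured on the
   CLAHE-enhanced image;
5. removal of objects sharing any pixel with the nuclear-stain mask
   (single-level Otsu on the registered nuclear plane) — rescues
   genuinely autofluorescent nucleated cells.

Surviving objects are set to exactly zero in every marker plane of
every cycle (idempotent by construction). Step order is intentional and
pinned by a regression test — swapping the area and intensity filters
changes results on crafted fixtures. As an optional QC utility,
`colordeconv_rbc_qc()` unmixes an H&E image by the Beer–Lambert optical
density transform and the pseudo-inverse of the standard H&E stain
matrix, thresholding eosin-dominant dense regions for visual comparison
with the mask.

# Pipeline orchestration

`process_region()` runs: reference-cycle geometry (focus → deconvolve →
pairwise → stage model → positions, cached), then per cycle (the
parallel unit) read → focus → deconvolve → register → compose a
registered mosaic per channel into a float32 cache, then assembly
(subtract, mask, stack, write). Because cycles are independent given
the reference geometry and nothing in the chain is stochastic, outputs
are byte-identical across repeat runs, across worker counts, and under
incremental execution: `process_incremental()` reuses the cached
geometry and mosaics, computes only newly arrived cycles, and
re-assembles — a late-arriving blank cycle therefore updates the
subtracted marker planes without touching geometry. Intermediates are
cached as 32-bit float TIFF on the sensor scale (clipped to
[0, 65535], which the final 16-bit output enforces anyway). Each region
emits diagnostics CSVs (per-address focus scores and chosen planes,
per-(cycle, tile) transforms with peak quality, tile positions,
pairwise offsets with validity, retained artifact objects), a
JSON-lines stage log, and a run manifest with per-cycle status
(done/skipped) and a configuration hash.

# The synthetic experiment generator

`simulate_experiment()` emits a complete raw tree plus a ground-truth
manifest. The scene is random non-overlapping disk "cells" (nuclear
stain in all, markers in random ~50% subsets) and bright
erythrocyte-like blobs; each z-plane is the scene convolved with the
matching-defocus plane of the channel's Born–Wolf PSF; per-cycle
integer drift (±8 px), per-(cycle, tile) stage jitter (±3 px), and
per-cycle focal drift (±2 planes) displace the tile crops; Poisson shot
noise plus Gaussian read noise (σ = 30 DN) complete the image model.
Blank-cycle marker channels contain only background and the blobs; in
stained cycles the blobs bleed into marker channels with a per-cycle
factor drawn from 0.85–1.25. That range deliberately straddles 1:
erythrocyte autofluorescence varies between imaging cycles and can
exceed the blank-cycle level, which is precisely why plain blank
subtraction leaves residuals and a masking step is needed at all.

The default fixture is one region, 2×2 tiles of 256×256 px at 15%
overlap, 6 z-planes, DAPI-like + Cy3-like channels, 4 cycles with cycle
1 blank, rendered with a 31-px PSF support (which contains the blur of
every defocus level at these optics). At this scale generation takes
seconds and a full pipeline run well under a minute, so end-to-end
properties run inside the test suite; unit fixtures are smaller still
(64–192 px). The generator emulates the *geometry and statistics* the
pipeline corrects — drift, jitter, defocus, shot/read noise, bright
blobs, bleed variation — and explicitly not tissue realism: cells are
disks, there is no spectral crosstalk between channels, no illumination
shading, no chromatic aberration, and rotation/scale drift defaults to
zero (the registration estimator's rotation/scale path is validated on
warped fixtures instead). Passing tests therefore demonstrate correct
recovery of modeled degradations, not performance on real tissue.

# Known limitations

* Laterally undersampled optics make FWHM-based sharpening gains small
  in pixel units (see above); on finer-sampled data the same machinery
  yields larger relative gains.
* The stage model is per-direction median/MAD with a spanning-tree
  solve, not a global optimization; grossly wrong grids with few valid
  pairs degrade to nominal placement.
* The artifact mask keeps only the topmost of three Otsu classes:
  moderately bright objects (around 40% of the dynamic range after
  enhancement) can fall into the middle class and escape masking.
* Blending is translation-only and assumes shading differences are
  handled by the linear ramp; no flat-field correction is attempted.
* Non-rigid deformation, chromatic aberration, and depth-varying PSFs
  are out of scope.
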
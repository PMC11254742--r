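---
title: "Methods: from tiled puck images to bead barcodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from tiled puck images to bead barcodes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and numerical choices behind `puckcall`:
what each stage assumes, which parameters matter, what the synthetic data
emulate (and do not), and where the design was genuinely open.

## The measurement model

A puck carries beads at fixed positions; round $r \in 1..R$ (default
$R = 14$) images the puck as a $3\times3$ grid of square tiles with a
nominal 10% overlap, in brightfield plus four fluorescence channels.  The
bead's true base $b_{ir}$ in round $r$ lights one dye; the observed channel
vector is

$$ o_{ir} = g \cdot M \, e(b_{ir}) + \varepsilon, $$

where $e(\cdot)$ is the one-hot dye signal, $M$ the crosstalk matrix
(default diagonal 0.7, uniform off-diagonal bleed), $g$ a per-tile,
per-round gain, and $\varepsilon$ additive Gaussian noise.  Geometrically,
round $r$ sees bead positions

$$ p_{ir} = R_{\theta_r}(p_i - c) + c + t_r + J_r(p_i), $$

a rigid re-mounting motion plus a smooth low-frequency distortion field
$J_r$.  The pipeline inverts this model stage by stage without ever fitting
it directly: binary masks remove the photometric part, rigid registration
removes $(\theta_r, t_r)$, and patch-local shifts absorb $J_r$.

## Stage assumptions and key parameters

**Segmentation.**  Beads are soft-edged round spots, photometrically a
Gaussian with $\sigma = \texttt{bead\_radius}/2$, well separated
(`min_separation` 12 px ≫ spot radius 5 px).  The default detector blurs the
brightfield tile (border-renormalised separable Gaussian — plain
zero-padded blur biases centroids of border spots inward, which corrupts
exactly the overlap strips stitching relies on), finds strict 8-neighbour
local maxima above an adaptive threshold, and refines each to sub-pixel
precision by an intensity-weighted centroid.  The trainable path is a
fully-convolutional net (3×3 conv → 3×3 conv → 1×1 conv, sigmoid; 673
parameters) on 50×50 patches, ADAM + binary cross-entropy, with per-tile
brightness normalisation so one trained model transfers across rounds and
stage positions despite gain variation.  The architecture is deliberately
tiny: its receptive field only needs to distinguish a spot's bright core
from its margin, and few labelled patches suffice.  The default pipeline
detector is the classical one — on synthetic brightfield data the two agree
(tested at ≥ 90% mutual matches), it is deterministic and much faster; the
network path exists because manual labels, not clean simulations, are what
real acquisitions provide, and it is selected with
`run_pipeline(..., segment_method = "cnn")`.

**Masks.**  Detected centres are rendered as radius-3 discs.  Everything
geometric (stitching, registration) runs on these binary masks: gray values
vary between rounds and tiles, so comparing them across images is
meaningless, while disc masks make the costs pure geometry.

**Stitching.**  Cost between two placed tiles is the sum of absolute mask
differences over their overlap.  Normalisation needed care: dividing by
overlap *area* scores an empty strip as perfect, and dividing by foreground
*content* alone biases towards minimal overlap (a lucky lone disc pair
scores 0).  The optimiser therefore minimises a content-regularised
mismatch fraction $(\sum|a-b| + \lambda)/(\sum a + \sum b + \lambda)$ with
$\lambda$ ≈ two rendered discs; reported costs are the raw mismatch
fraction, so a perfect overlap still reads 0.  Placement is sequential
(each tile grid-searched against all already-placed neighbours within
`search_radius` 15 px) followed by coordinate-descent sweeps over all tiles
accepting strict improvements only — the total cost is non-increasing and
the search terminates.  Costs for all integer shifts come from one FFT
cross-correlation per tile pair, rounded back to exact integers so
tie-breaks are deterministic.

**Coarse registration.**  Round 1 is the reference.  Bead-centroid
centering aligns the puck centres; a rotation scan (±5° in 0.5° steps)
exploits that beads are not grid-arranged, so the rotational cost landscape
has a single sharp minimum; a three-level grid refinement with steps
(0.5°, 4 px) → (0.2°, 2 px) → (0.05°, 1 px) polishes (θ, tx, ty).  All
levels except the last run at half resolution (`downsample_factor` 2).  The
cost is the symmetric difference of the two masks, computed on sparse
foreground pixel sets — identical to the sum of absolute differences of the
dense rasters, but linear in the number of bead pixels.  Recovery is tested
to (0.2°, 1 px) on clean masks and (0.5°, 2 px) under 5% washout.

**Fine registration and tracking.**  Residual misalignment after the rigid
fit is the smooth field $J_r$ plus stitching quantisation — a few pixels,
varying slowly across the mosaic.  The mosaic is cut into `patch_size`
square patches; per patch, an integer shift in ±10 px minimises the sum
over reference beads of the distance to the nearest moving bead, truncated
at the congruence threshold (unmatched beads contribute the threshold, so
outliers cannot drag the shift).  Matching is greedy nearest-first,
one-to-one, accepting only pairs strictly closer than 4 px.  Greedy is
provably optimal here in practice because bead separation (≥ 12 px) far
exceeds the threshold; the test suite verifies its cardinality against a
brute-force optimal assignment on small instances.  Default `patch_size` is
128 px: patches must be small enough that $J_r$ is nearly constant within
one (its wavelength is several hundred pixels), yet hold tens of beads for
a stable shift estimate.  With 256-px patches a single integer shift cannot
absorb the within-patch variation of the distortion field and cross-round
linking degrades measurably; 128 px tracks it.  Moving-bead candidates for
a patch come from the patch box expanded by shift-radius + threshold, so
border beads are never lost; a moving bead contested by two patches is
resolved by one global greedy pass per round, keeping matching one-to-one.

**Base calling.**  Each tracked bead/round yields a 4-vector: disc mean
(radius 3) at the matched position in each fluorescence mosaic minus the
local annulus median (radii 5–8), which removes background and bleed from
neighbours.  Vectors are normalised by their maximum — this single
preprocessing step makes calling invariant to global gain, the dominant
nuisance the assay motivates — and classified by a dense 4→16→8→4 network
(tanh hidden, linear output) trained with ADAM at learning rate 0.001 and a
mean-squared-error loss against one-hot targets for 100 epochs.  MSE rather
than cross-entropy is kept deliberately as the stated training recipe.  The
channel→base mapping is a configurable bijection (default
wavelength-ascending → A, C, G, T); it is an assay convention, not
something the data determine.  An exact crosstalk-inverse arg-max
(`unmix_argmax_accuracy()`) serves as the non-learned baseline the network
must match or beat in tests.

**Census.**  Registered bead sets are counted over a 50×50 px patch grid; a
bead counts only if its whole radius-3 disc lies inside the patch (the
"completely within" counting rule), and a patch changes in round $r$ if its
count differs from round 1.  Round 1 as the change reference matches the
pipeline's global reference convention.

## The synthetic acquisition: what it does and does not emulate

Defaults are the study conditions: 14 rounds, 3×3 tiles, 10% overlap,
re-mounting motion |θ| ≤ 3° and |t| ≤ 20 px per round, 1% per-round
permanent washout, a ~0.5% per-round spurious appearance rate, smooth
distortion of ~1.5 px amplitude (three random low-frequency plane-wave
modes), ±3 px integer stage placement error per tile, per-tile gain in
[0.7, 1.3], per-bead brightness in [0.75, 1], crosstalk diagonal 0.7, and
additive noise σ = 0.05.  Motion, distortion and stage-error magnitudes are
not published for this assay; they were fixed once at values that keep each
corrective stage non-trivially exercised (rotation large enough that
translation-only alignment fails; distortion large enough that rigid
alignment alone breaks the 4-px rule) and are stated in
`simulation_config()`'s documentation.  The puck disc is shrunk by an
automatically computed margin so the whole puck stays imaged in every round,
as a real puck is within its 3×3 coverage.

What the simulator does **not** model: diffraction and depth-of-field
optics, bead shape irregularity, illumination flat-field structure,
correlated (striped or vignetted) noise, debris and stains, and the
real study's non-chronological sequence labelling.  Passing tests therefore
demonstrate the pipeline's geometric and spectral logic under realistic
nuisance magnitudes — not robustness to every artefact of a physical
microscope.  Real-data properties tied to the unavailable pucks (absolute
changed-patch counts, the per-sequence washout pattern) are out of scope;
the census is instead validated by exact equivalence against a direct
recount from ground-truth presence flags.

## Numerical choices and degenerate inputs

* All randomness (simulation, weight init, shuffles, splits) derives from
  one seed through named substreams; identical config + seed reproduces
  byte-identical outputs, which the suite asserts.
* Grid searches break ties deterministically: stitching towards the nominal
  offset then smallest |dy|; rotation towards the smallest |angle|; patch
  shifts towards the smallest shift; base calls towards the lower channel.
  Cost tables are exact integers (rounded FFT correlations), so ties are
  real ties, not float noise.
* Empty inputs are contracts, not crashes: an empty bead set matches to
  nothing, an empty patch keeps shift (0, 0), an empty mask refuses to
  centre with an explicit error, a washed-out round stays `NA`/`N` — never
  zero-filled.
* Masks are resampled nearest-neighbour only (binary in, binary out); the
  point and mask transform paths are tested to agree within 1 px.
* Intensities are clipped to [0, 1] at generation and normalised at load.

## Problem sizes

The shipped checks run at desk scale: the end-to-end audit simulates a 3×3
grid of 256-px tiles carrying ~800 beads over 14 rounds (about 700 beads,
i.e. ~10,000 bead-round links, audited against ground truth), and the base
caller trains on 1746 vectors split 1575/171.  Unit fixtures use 96–160-px
tiles with 40–250 beads.  These sizes keep the full suite within a few
minutes while leaving every stage's search spaces (overlap strips, rotation
grid, patch shifts) as rich as at full scale; the pipeline itself is
size-agnostic and handles 1024-px tiles unchanged.

## Known limitations

* Stitching accuracy degrades when an overlap strip holds fewer than ~3
  beads; at realistic densities this only affects corner-to-corner
  constraints, and the global refinement recovers, but extremely sparse
  pucks would need larger overlaps.
* Patch shifts are integer and independent per patch by design (no
  smoothness constraint, no sub-pixel refinement); distortion fields with
  strong gradients inside one patch are only absorbed up to the congruence
  tolerance.
* The tracker links each round to round 1 independently; it does not exploit
  temporal continuity across rounds, so a bead lost to detection in one
  round is simply missing there rather than interpolated — a deliberate
  contract (missing, never imputed).
* Beads closer than about two disc radii merge at the mask stage; the
  simulator's minimum separation reflects the real arrays, but clumped
  beads on a degraded puck would be under-counted.
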
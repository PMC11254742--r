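# puckcall

Bead-barcode calling from multi-round epifluorescence images of Slide-seq
pucks.

## The problem

Slide-seq resolves spatial gene expression by capturing tissue RNA on a ~3 mm
array ("puck") of ~50,000 DNA-barcoded beads.  Before any tissue is applied,
each bead's 14-base barcode must be read out optically: the puck goes through
14 hybridisation rounds, and in each round every bead lights up in one of four
fluorescence channels (475, 555, 575, 635 nm) according to the base it
carries, alongside a brightfield image used for bead detection.  A round is
acquired as a 3×3 grid of 1024×1024 px tiles with ~10% overlap.

Two things make this hard on an ordinary epifluorescence microscope.  First,
between rounds the puck is removed, washed and re-mounted, so every round is
rotated and shifted, optical distortion adds a few pixels of local
misalignment, and some beads wash away entirely.  Second, the emission
spectra bleed into each other (channel crosstalk), so a bead's base cannot be
read by thresholding a single channel.  `puckcall` solves both: it assembles
each round's tiles into a mosaic, chains every bead's identity through all 14
rounds, and calls bases with a small network that is robust to crosstalk and
gain variation — no confocal microscope required.

## The pipeline

1. **Segmentation** — beads are detected on each brightfield tile, either by
   a classical blur + local-maxima detector (`oracle_segment()`, the fast
   default) or by a tiny fully-convolutional network trained on 50×50 patches
   with ADAM + binary cross-entropy (`train_segmenter()`).  Detected centres
   are rendered as radius-3 discs into binary masks; all geometry downstream
   runs on these masks, which makes it insensitive to gray-value variation.
2. **Stitching** — tile masks are placed into one mosaic by minimising the
   normalised sum of mask differences over tile overlaps: pairwise placement
   followed by a coordinate-descent grid search over all tiles
   (`stitch_round()`).
3. **Coarse registration** — each round's mosaic is aligned rigidly to round
   1: bead-centroid centering, a rotation-angle scan, then a shrinking-step
   grid search over (θ, tx, ty), evaluated at half resolution on the
   sum-of-absolute-differences cost (`register_round()`).
4. **Fine registration & tracking** — the mosaic is cut into patches; each
   patch of moving-round detections gets its own integer shift minimising the
   truncated sum of nearest-point distances, and detections are then matched
   one-to-one under the congruence rule: two detections are the same bead iff
   their post-shift distance is **strictly less than 4 px**
   (`link_across_sequences()`).
5. **Base calling** — for every tracked bead and round, the four fluorescence
   gray values are read at the matched position (disc mean minus local
   annulus median) and classified by a dense 4→16→8→4 network trained with
   ADAM (lr 0.001) and a mean-squared-error loss on one-hot targets
   (`train_base_caller()`, `call_base()`); barcodes are assembled with `N` at
   unmatched rounds.
6. **Census** — a 50×50 px patch grid counts beads per round and reports how
   many patches changed relative to round 1 (`patch_census()`), quantifying
   washout.

Because no public dataset of this kind exists, the package ships a seeded
synthetic-acquisition generator (`simulation_config()`,
`generate_acquisition()`) that emulates the whole measurement — per-round
rigid motion, stage placement error, smooth optical distortion, permanent
bead washout, spurious appearances, per-tile gain, spectral crosstalk and
noise — with complete ground truth, so every stage and the end-to-end
pipeline are verifiable.

## Worked example

```r
library(puckcall)

cfg <- simulation_config(
  acquisition = acquisition_spec(n_sequences = 6, tile_size = 160),
  n_beads = 250, seed = 42)
run <- run_pipeline(cfg)
print(run)
#> Puck run: 6 rounds, 255 reference beads
#>   tracked in all rounds: 93.3%
#>   mean barcode completeness: 0.961

print(run$census)
#> ChangeCensus: 81 patches, 6 rounds
#> changed patches per round: 0 24 18 23 22 20

audit <- audit_tracks(run)
sprintf("%d / %d beads correct in all rounds (%.1f%%)",
        audit$n_correct, audit$n_audited, 100 * audit$fraction_correct)
#> "237 / 241 beads correct in all rounds (98.3%)"

head(as.data.frame(run$barcodes)[, 1:5], 4)
#>   bead_id        x        y barcode completeness
#> 1       1 226.0522 55.99222  CGACAC            1
#> 2       2 206.0664 58.01949  AGACCG            1
#> 3       3 193.9724 64.02827  AGCGCG            1
#> 4       4 269.0426 66.06707  GGGGGG            1
```

`run_pipeline(cfg, out_dir = "out")` additionally writes `barcodes.tsv`,
`layouts.json`, `transforms.json`, `census.csv` and `report.json`.
The numbers read as follows: 93.3% of reference-round beads were linked to a
detection in every round (the rest are mostly genuine washout — mean barcode
completeness 0.961 counts those missing rounds), and the ground-truth audit
confirms 98.3% of the beads present in all rounds were chained correctly.
The census row shows ~20 of 81 patches changing bead count per round, the
signature of washout.

A thin command-line wrapper lives at `inst/scripts/puckcall`
(`puckcall simulate|run|stats`); the R functions above are the primary
interface.

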
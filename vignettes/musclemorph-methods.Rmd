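---
title: "Methods: automated myofiber histomorphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated myofiber histomorphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Transverse sections of human skeletal muscle, immunofluorescence-stained for
the sarcolemma (dystrophin + spectrin, channel C1) and for fast myosin heavy
chain (MyHC, channel C2), carry the information a myopathologist needs:
how many fibers there are per unit tissue, how large they are, how the
slow-twitch (type I) and fast-twitch (type II) populations differ, and
whether abnormally small (atrophic) or large (hypertrophic) fibers are
over-represented. Manual quantification covers a few hundred fibers per
section; a whole-section mosaic (~9300 x 9900 px at 0.647 um/px) holds
several thousand. `musclemorph` automates the whole chain: segmentation of
individual fibers from the membrane stain, binary fiber typing from the MyHC
stain, per-fiber morphometry, and section-level summary statistics, with no
interactive steps.

## Pipeline

Each sample is a pair of single-channel 16-bit TIFFs (camera counts
0--4095). The stages, in fixed order:

1. **Membrane enhancement** (`preprocess_membrane`): 3x3 median despeckle
   (edge pixels use the in-bounds neighbourhood), linear contrast stretch
   saturating `saturated_fraction` of the pixels (default 0.35%, split
   between the tails), and rolling-ball background subtraction — a grayscale
   morphological opening with a disc (default radius 50 px) subtracted from
   the image, clipped at zero. The opening is computed on a min-pooled image
   for large radii; the background is smooth at that scale, so pooling does
   not change the estimate materially.
2. **Binarization** (`binarize_membrane`): one global threshold by the
   maximal between-class-variance (Otsu) criterion on the full histogram;
   membrane = strictly above threshold.
3. **Gap closing** (`close_membrane_gaps`): morphological closing of the
   membrane mask with a disc, sealing staining gaps up to about twice the
   radius. See *Choice of the closing radius* below.
4. **Labeling** (`label_fibers`): fiber interiors are 4-connected components
   of the membrane complement (4-connectivity prevents diagonal leakage
   through 1 px membrane lines). Components touching the image border — the
   exterior background and edge-cut fibers — are dropped; organelle-scale
   holes inside a fiber are filled; labels are renumbered in scan order of
   each region's first pixel, so ids are reproducible.
5. **Morphometry** (`measure_fibers`): per fiber, CSA (pixel count x
   calibration^2), perimeter (Moore chain-code boundary with
   Vossepoel--Smeulders corrected weights 0.980/1.406/-0.091, accurate to
   ~1% on digitised disks), major/minor diameters (axes of the
   moment-equivalent ellipse, with the 1/12 unit-square pixel term), and
   circularity 4*pi*A/P^2 capped at 1. The moment-ellipse convention matches
   the platform this class of analyses is usually run on; it is *not* the
   minimal Feret ("narrowest caliper") diameter used in manual myopathology,
   which is available as an optional column (`feret = TRUE`).
6. **Exclusion filters** (`apply_exclusion_filters`): fibers with
   CSA < 200 or > 13000 um^2, circularity < 0.4, or minor diameter < 1.5 um
   are artifacts at deltoid scale and are removed (strict inequalities:
   values exactly at a bound survive). The `pectoral` preset relaxes the
   bounds to 20000 um^2 and 8 um for the larger pectoral fibers.
7. **Typing** (`myhc_threshold`, `classify_fibers`): one Otsu threshold on
   the C2 intensities inside the detected tissue; a fiber is type II when at
   least half of its interior pixels (after 2 px erosion, to keep membrane
   bleed-through out of the vote) exceed it, type I otherwise. The threshold
   is global per section so calls are comparable across the section; typing
   is deliberately binary (no IIa/IIx or hybrid calls).
8. **Section summary** (`summarize_section`): counts and percentages per
   type, tissue area (closing of membrane + fibers, holes filled), fibers
   per 10 mm^2 (`n / area_um2 * 1e7`), mean +/- SEM of the four size
   parameters per class, and atrophy/hypertrophy factors — each fiber's CSA
   scored through fixed bins (atrophy: <=500 um^2 scores 20, then 10, 5, 1,
   0 above 2000; hypertrophy: 0 up to 4500, then 1, 5, 10, 20, 30 above
   8500), summed, divided by the class count. The printed integer bin edges
   are implemented as half-open real intervals so every CSA has a score.

Outputs per sample: three CSV fiber tables (all / type I / type II), a
plain-text run log echoing every parameter, a 16-bit label TIFF, two
colour-coded size maps (CSA and minor diameter through a fixed 8-colour
palette from dark orchid, smallest, to red, largest; the duplicated printed
edge at 1000 um^2 resolves to the first bin), and three outline overlays
(all / type I / type II). `run_batch` loops a folder of samples, isolates
failures, and writes a JSON batch report.

## Parameters that matter

| key | default | meaning |
|---|---|---|
| `pixel_size_um` | 0.647 | um per pixel edge; from a physical ruler, not TIFF tags |
| `saturated_fraction` | 0.0035 | contrast-stretch clipping fraction |
| `ball_radius_px` | 50 | background ball radius; below fiber scale, above noise scale |
| `closing_radius_px` | 7 | membrane gap-closing disc radius (see below) |
| `tissue_close_radius_px` | 20 | closing radius for the tissue envelope |
| `exclusion` | 200/13000/0.4/1.5 | deltoid artifact bounds (um^2, um^2, –, um) |
| `positive_fraction_cutoff` | 0.5 | interior fraction above threshold for a type II call |
| `erosion_px` | 2 | interior erosion before the MyHC vote |

### Choice of the closing radius

The gap-closing contract is parametric — a disc of radius r seals membrane
gaps up to about 2r — but the default matters. Staining gaps arrive in
spatially clumped arcs: at a realistic 5% membrane dropout the mean spacing
between arcs along a fiber boundary is a few tens of pixels, so compound
gaps well beyond a single arc length are common. With r = 2--3 px most
compound gaps stay open, adjacent fibers merge, and section recall collapses
even though each individual arc is small. We set the default to 7 px
(~4.5 um): large enough to seal arc clusters, still a factor 6--10 below
fiber minor diameters (40--80 px), so fibers are not bridged across their
interiors. On clean synthetic sections the larger radius costs a fraction
of a percent in per-fiber boundary placement and nothing in recall (the
acceptance script reports both).

### Otsu conventions

Thresholds are computed on integer histograms; the foreground is *strictly
above* the threshold; ties in the between-class variance resolve to the
smallest candidate, making results deterministic. A constant image yields an
empty mask (membrane) or an all-type-I section (MyHC) with a warning.

## The synthetic section generator

No patient imagery ships with the package; every claim is tested against
`generate_section`, which renders a two-channel section with per-fiber
ground truth:

* **Geometry**: fiber target areas are lognormal (mean 2400 um^2, log-sd
  0.4 — a healthy-deltoid regime; right-skewed so the atrophy/hypertrophy
  bins are exercised); centres are placed by Poisson-disk dart throwing
  inside an elliptical tissue region sized so the tessellation is
  space-filling at the requested mean CSA; fiber regions are the cells of an
  additively weighted Voronoi tessellation (muscle fascicles are
  space-filling polygons), clipped to the tissue ellipse, whose boundary is
  drawn as a stained ring (sections are bounded by stained perimysial
  tissue).
* **Signal**: membrane ridges ~3 px wide at 3300 counts (~80% of the 0--4095
  camera range, matching the acquisition protocol), interiors near 150
  counts on C1; type II interiors at 2800 and type I at 150 counts on C2;
  additive Gaussian noise (default sd 60).
* **Degradation**: membrane dropout in contiguous arcs with
  gamma-distributed lengths (shape 6, mean 3 px) — the few-pixel local
  staining discontinuities of an optimised double-antibody protocol.
  Arcs much longer than twice the closing radius are a documented failure
  regime (fibers merge), not a default condition. Noise sd 165 (5% of the
  membrane signal) defines the degraded regime used in testing.
* **Determinism**: a fixed `seed` reproduces images and truth bit-exactly.

What the generator does *not* emulate: point-spread blur, chromatic shift,
autofluorescence texture, necrotic/regenerating fiber morphology, internal
capillaries, or fiber-type clustering. Tests passing on synthetic sections
therefore demonstrate the correctness and robustness of the *algorithmic
chain* under controlled geometry, noise, exposure and dropout — they do not
certify accuracy on pathological tissue, where segmentation losses are
dominated by biology the simulator does not model.

## Numerical and degenerate-input choices

* Contrast stretch uses exact type-1 order statistics (histogram-based for
  integer rasters, so whole-mosaic images never require a full sort);
  outputs are rounded to integer counts; a constant image is returned
  unchanged with a warning.
* Closing results are unioned with their input so extensivity survives
  image-border padding.
* An isolated single-pixel region gets the perimeter of its unit square;
  circularity is capped at 1 (digitised near-circles can nominally exceed
  it).
* Fibers whose eroded interior is empty fall back to the full region for
  the MyHC vote and are flagged in the result.
* Zero-fiber sections produce zero counts with class statistics reported
  missing; atrophy/hypertrophy factors are errors on empty input (they are
  undefined, not zero).
* Labels, bin functions, palettes and overlays are deterministic functions
  of their inputs; re-running a batch yields byte-identical tables.

## Problem sizes used in the test-suite

Module tests run on 60-fiber sections (~900 x 900 px); the acceptance-style
checks use 200-fiber sections (~1500 x 1500 px) for clean, degraded and
exposure-scaled (0.3x--1.7x) regimes, and one full-scale run analyzes a
~3000-fiber, 9300 x 9900 px mosaic end-to-end — the scale of a stitched
whole-section acquisition. These sizes were chosen as the smallest that
exercise each claim meaningfully (a 200-fiber section already yields
sub-percent sampling noise on recall; the mosaic run validates memory- and
time-scaling on a single CPU).

## Known limitations

* Merged fibers are not split (no watershed); under heavy membrane dropout
  the pipeline loses the affected fibers rather than guessing boundaries.
* Typing is binary; IIa/IIx subtypes and hybrid fibers are out of scope.
* The tool assumes single-channel, single-page TIFF input; composite or
  proprietary formats must be split upstream.
* Exposure robustness holds for global intensity scaling in roughly the
  0.3x--1.7x range; severely under-exposed images (below ~0.2x) lose
  detection gradually, which is expected and not guarded against.
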
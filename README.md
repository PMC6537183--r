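# musclemorph

Automated histomorphometry of immunofluorescence-stained human skeletal
muscle cross-sections.

## The problem

Muscle biopsies are routinely assessed by measuring myofiber size and the
balance of slow-twitch (type I) and fast-twitch (type II) fibers. A
whole-section fluorescence mosaic — sarcolemma outlined by
dystrophin/spectrin on channel 1 (C1), fast myosin heavy chain (MyHC)
marking type II fibers on channel 2 (C2) — contains thousands of fibers;
manual morphometry covers a few hundred and is user-biased. `musclemorph`
analyzes whole sections automatically: it segments every fiber from the
membrane stain, types it from the MyHC stain, measures it, and reports
section-level statistics, per-fiber tables and review images, with no
interaction.

## Method

Per sample (a pair of single-channel 16-bit TIFFs):

1. membrane enhancement: 3x3 median despeckle, percentile contrast stretch,
   rolling-ball background subtraction;
2. global automatic threshold (maximal between-class variance) on the
   membrane channel; morphological closing seals staining gaps;
3. fibers = 4-connected components of the membrane complement (border
   components dropped, internal holes filled);
4. per-fiber morphometry: CSA `A` (px count x s^2, s = 0.647 um/px by
   default), perimeter `P` (corrected chain-code boundary length),
   major/minor diameters (moment-equivalent ellipse axes), circularity
   `4*pi*A / P^2`;
5. exclusion filters remove artifacts (defaults `A < 200` or
   `A > 13000 um^2`, circularity `< 0.4`, minor diameter `< 1.5 um`;
   `--preset pectoral` uses `20000` / `8` for larger pectoral fibers);
6. typing: a fiber is type II iff >= 50% of its (eroded) interior exceeds a
   global Otsu threshold on tissue-restricted C2; type I by difference;
7. section summary: tissue area, fibers per 10 mm^2
   (`n / area_um2 * 1e7`), per-class mean +/- SEM of each size parameter,
   and atrophy / hypertrophy factors — per-fiber CSA scored through fixed
   bins (atrophy: `<=500` um^2 -> 20, `(500,1000]` -> 10, `(1000,1500]` -> 5,
   `(1500,2000]` -> 1, else 0; hypertrophy: `(4500,5500]` -> 1,
   `(5500,6500]` -> 5, `(6500,7500]` -> 10, `(7500,8500]` -> 20,
   `>8500` -> 30), summed and divided by the fiber count.

Outputs: CSV fiber tables (all / type I / type II), a parameter-echoing run
log, a 16-bit label TIFF, colour-coded size maps (8 bins from dark orchid,
smallest, to red, largest, for CSA and minor diameter) and outline
overlays. A synthetic two-channel section generator with per-fiber ground
truth (`generate_section`) backs the entire test-suite; see the methods
vignette (`vignettes/musclemorph-methods.Rmd`) for the model and its
limits.

## Worked example

```r
library(musclemorph)

params  <- synthetic_params(n_fibers = 200, seed = 42)  # deltoid-like section
section <- generate_section(params)
result  <- run_pipeline(section$c1, section$c2)
print(result)
```

```
<section_summary> tissue 555370 um2 | 200 fibers (I: 99, II: 101)
  type I/II: 49.5% / 50.5% | 3601.2 fibers per 10 mm2
  atrophy factor (all/I/II): 1.21 / 1.02 / 1.39
  hypertrophy factor (all/I/II): 0.09 / 0.04 / 0.14
```

All 200 simulated fibers are recovered; the section carries 3601 fibers per
10 mm^2 of detected tissue; atrophy/hypertrophy factors near 1 and 0 are
the healthy-muscle regime (scores rise when abnormally small or large
fibers accumulate). Per-fiber measurements:

```r
head(result$records[, c("fiber_id", "csa_um2", "perimeter_um",
                        "minor_diameter_um", "circularity", "fiber_type")], 4)
```

```
  fiber_id   csa_um2 perimeter_um minor_diameter_um circularity fiber_type
1        1 2616.3063     193.0040          56.81704   0.8826040          I
2        2 2768.6799     201.5043          48.09526   0.8568684          I
3        3 2375.6061     197.8461          39.36595   0.7626568          I
4        4  907.1257     137.7295          18.53465   0.6009295          I
```

Batch use from a shell (every `<id>_C1.tif` / `<id>_C2.tif` pair in a
folder):

```sh
exec/musclemorph simulate --out demo --n-samples 3 --seed 1
exec/musclemorph analyze demo --out demo_results            # deltoid defaults
exec/musclemorph analyze demo --preset pectoral --min-area 250
```

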
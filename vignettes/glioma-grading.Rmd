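---
title: "Grading gliomas from histopathology tiles: methods and design notes"
author: "gliotex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading gliomas from histopathology tiles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliotex)
```

## The problem and the approach

Histologic grading of gliomas (grade II through glioblastoma) is read by
pathologists from H&E-stained tissue, where grade manifests jointly as
*texture* — nuclear density, pleomorphism, micro-architecture — and *color* —
the balance of hematoxylin (nuclei, purple) against eosin (stroma, pink).
`gliotex` implements a classical feature-engineering pipeline for this
problem:

1. **Contrast enhancement.** A global log-normalization
   `I -> round((2^b - 1) * log(1 + I) / log(1 + Imax))` per channel, followed
   by contrast-limited adaptive histogram equalization (CLAHE) on an 8x8
   grid of contextual regions.  Log-normalization is monotone per channel,
   so it never reorders intensities; CLAHE is applied to the HSV value
   channel and the R, G, B planes are rescaled by the value ratio, which
   preserves hue and saturation exactly.
2. **ROI selection.** Images are cut into non-overlapping tiles
   (512 x 512 by default) and each tile's nuclei are counted by a fixed
   watershed pipeline (luminance, Otsu threshold for dark objects,
   Euclidean distance transform, watershed, area filter).  The five tiles
   of highest nuclear density become the regions of interest — a proxy for
   cell proliferation.
3. **Six feature families** per ROI (block-prefixed columns in one table):
   - `glcm.*` — six statistics of the gray-level co-occurrence matrix
     averaged over the 0/45/90/135-degree offsets at distance 1;
   - `glrlm.*` — four run-length statistics, likewise averaged;
   - `lbp.*` / `lbpw.*` — rotation-invariant uniform (riu2) local binary
     pattern histograms at (P, R) = (8,1), (16,2), (24,3), plus
     variance- and dissimilarity-weighted LBP histograms at (8,1);
   - `lbglcm_ms.*` — GLCM statistics of the basic-LBP-coded image at
     every level of a 3-level Gaussian pyramid (the multi-scale LBGLCM);
   - `cm.*` / `hist.*` — color moments of R, G, B and of HSV hue and
     saturation, plus per-channel histograms;
   - `rshd.*` — a 64-shade x 5-structure-element rotation- and
     scale-invariant hybrid color-texture descriptor.
4. **Reduction.** Features are min-max scaled to [0, 1] and factorized with
   non-negative matrix factorization, `X ~ W H`; the rank-32 `W` rows are
   the reduced representation.
5. **Classification.** A majority-vote ensemble of an RBF-kernel SVM, a
   fast large-margin linear classifier and a single randomized decision
   tree, with one-vs-rest metrics (ACC, TPR, PPV, SPC, DSC) and AUC under
   grouped, stratified 10-fold cross-validation or a 40% holdout.

## Formula conventions worth spelling out

Several formulas are implemented in their *printed* form, with a config
switch to the classical form where the two differ:

- **GLCM homogeneity** uses the denominator `1 + (i + j)^2`
  (`homogeneityForm = "printed"`); `"standard"` switches to the conventional
  `1 + (i - j)^2`.  Indices are 0-based levels.
- **GLCM entropy** is named but never printed in the source formulation; it
  is defined here as Shannon entropy in bits over nonzero cells.
- **GLRLM SRE/LRE** place the denominators `1 + (i + j)` and
  `1 + |i - j|` inside the summation (per term), the only reading under
  which the printed expressions are well-formed; indices are 1-based.
  `GLN` and `RLN` are second moments of the run distribution about the
  image's mean gray level and the mean run length.  The mean run length is
  computed per scan direction — the reading consistent with the degenerate
  single-run case, where a constant 1 x L row must give RLN = 0.
  `formulas = "standard"` substitutes the classical Galloway definitions.
- **Color moments** use root forms: skewness is the signed cube root of the
  mean cubed deviation and kurtosis the fourth root of the mean
  fourth-power deviation (`moments = "standardized"` switches to m3/sd^3,
  m4/sd^4).  HSV moments cover hue (degrees) and saturation only; the value
  channel is excluded because it carries the illumination component the
  HSV representation is meant to discount.
- **LBP** thresholds with `s(x) = 1` iff `x >= 0`, bit p at angle
  `2*pi*p/P` counter-clockwise from the positive x axis, bilinear
  interpolation at non-integer positions, and a `1e-7` threshold tolerance
  so `s(0) = 1` survives interpolation round-off on constant
  neighborhoods.  The riu2 variant (at most two circular bit transitions
  maps to its popcount, else P+1) is the default for histogram features
  because it is invariant to the bit-order convention; the well-known
  printed 3x3 worked example for basic LBP is internally inconsistent in
  its thresholding step, so only its string-to-decimal conversion
  (11001001 -> 201) is reproduced.
- **RBF kernel**: the printed kernel carries a spurious `+C` inside the
  exponent; it is implemented as the standard
  `exp(-gamma * ||x - x'||^2)` — C is the soft-margin penalty, not a
  kernel term, and the printed form would merely rescale the kernel by a
  constant factor.
- **Majority vote**: the mode of the three base votes; a three-way tie
  falls back to the first base model (the RBF-SVM).  The vote operator in
  the source formulation is undefined for ties, so the tie-break is this
  package's documented convention.

## Parameters and defaults

| parameter | default | units / notes |
|---|---|---|
| CLAHE grid | 8 x 8 | contextual regions; clip limit 4 (x uniform level) |
| tile size | 512 | pixels; fixture runs use 128 (one tile per image) |
| ROIs per image | 5 | highest watershed nuclei count |
| nucleus area bounds | [8, 2000] | px^2; watershed tolerance 0.5, peak radius 2 |
| GLCM levels | 64 | quantization of the luminance channel |
| GLRLM levels | 16 | coarser: runs need plateaus to form |
| LBP set | (8,1),(16,2),(24,3) | riu2; multi-resolution |
| pyramid depth | 3 | LBGLCM quantized at 128/64/64 levels per scale |
| color histogram bins | 8 | per channel |
| RSHD shades | 64 | 4 bins per RGB channel; 5 structure classes |
| NMF rank k | 32 | the sweep utility `sweepK` explores alternatives |
| NMF stopping | 1e-4 relative, <= 500 iterations | multiplicative updates |
| SVM grids | gamma {1e-5,1e-4,1e-3}, C {0.1..10000} | inner 3-fold CV; ties prefer smaller C, then gamma |
| FLM C | 10 | monotone batch solver, tol 1e-8 |
| tree | depth 12, mtry = ceiling(p/2) | single randomized tree |

The interpretation of the "128 x 128 and 64 x 64" sub-image sizes at the
first and second pyramid levels deserves a note: 512-pixel ROI tiles halve
to 256 and 128, never 64, so the sizes are read as *co-occurrence
quantization levels* (128 at the base scale, 64 deeper), not spatial
dimensions.  The quantization-per-scale vector is exposed in the config.

Two defaults are deliberately non-standard. The randomized tree samples
`ceiling(p/2)` features per node rather than the forest-conventional
`sqrt(p)`: a *single* tree has no ensemble averaging to absorb the variance
of very small feature subsets, and with `sqrt(32) ~ 6` features per node
the tree is too often offered only uninformative factors. The fast
large-margin default C = 10 reflects that the NMF scores it consumes live
in a compressed non-negative range, so a weakly-regularized margin is
appropriate. Both remain arguments.

NMF is always fit on training rows only; held-out rows are projected by
non-negative least squares against the frozen `H` (`nmfTransform`), and
min-max scaling statistics are likewise frozen on the training fold —
fitting either on all data would leak test information into the
representation.

## The synthetic fixture generator

TCGA whole-slide archives cannot ship with a package, so
`generateTextureDataset` builds labeled stand-ins: each image is a noisy
background tint with dark, hematoxylin-colored elliptical blobs.  The four
default classes emulate increasing grade along *both* axes the pipeline
exploits — expected nuclear density rises (12, 26, 45, 70 blobs per
128 x 128) while radius falls slightly, and the background tint darkens
and purples — so texture and color are each informative and their fusion
is testable.  Per-image blob counts are Poisson draws around the class
density (real fields of view show count dispersion), and the drawn count
is recorded as ground truth for the watershed validation.

What the generator does *not* emulate: stain variability between labs,
tissue architecture (sheets, palisades, vessels), nuclear pleomorphism,
overlapping nuclei at realistic densities, and compression artifacts.
Passing the end-to-end fixture check therefore demonstrates that the
pipeline's stages compose correctly and recover class structure carried by
second-order texture and color moments — not clinical-grade performance on
real slides.

## Numerical choices and degenerate inputs

- All operators are total on valid inputs: constant images yield the
  documented constants (GLCM energy 1 and correlation 0, LBP code 255,
  V = 0, H = 1, zero-weight LBP histograms all-zero) rather than NaN.
- Zero-denominator metrics are defined as 0 with a warning.
- Tiny interpolation round-off is floored (V below 1e-16 to 0, H above
  1 - 1e-12 to 1) so degenerate-case identities hold exactly.
- The multiplicative NMF updates guard denominators with 1e-12; the error
  trace is non-increasing and the factorization is bitwise reproducible
  for a fixed seed.
- Ties: ROI selection orders by (density desc, grid row, grid col); the
  SVM grid search prefers smaller C then smaller gamma; the vote tie-break
  is the first base model; AUC uses midranks.
- All randomness (generator, fold deals, NMF init, tree feature draws) is
  seeded through one seed argument per entry point, and seeds never leak
  into the caller's RNG state.

## Problem sizes used in the checks

The shipped checks run the full pipeline on 100 fixture images (4 x 25,
128 x 128, seed 0) — about one hundred 471-feature ROI rows — with 10-fold
grouped CV refitting scaling, NMF (rank 32, 300 iterations) and all three
classifiers in every fold, twice to confirm byte-identical reproduction.
Oracle-equivalence checks run on grids up to 8 x 8 against explicit
enumeration loops, exhaustive 27-triple vote tables and exhaustive small
confusion tuples.  These sizes were chosen so a complete run stays
comfortably under typical continuous-integration budgets while still
exercising every stage end to end.

## Known limitations

- The watershed counter is tuned to fixture-scale nuclei (radius 2-4 px);
  real 40x tiles need the area bounds and peak radius re-examined.
- The RSHD structure elements follow this package's reading (orbit classes
  of 2 x 2 binary patterns under rotation); the original descriptor's
  five elements are defined in a reference that the source formulation
  does not reproduce.
- `applyClahe` delegates to EBImage and requires at least a 2 x 2 region
  grid; single-region CLAHE (= global equalization) is approximated by a
  large clip limit.
- The deep-learning comparison arms, survival analysis and whole-slide
  (SVS/NDPI) ingestion of the original study are out of scope.
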
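---
title: "Counting mosquito eggs by thresholding and box-area filtering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting mosquito eggs by thresholding and box-area filtering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovocount)
```

## The problem

*Aedes aegypti* females glue their eggs one by one onto solid substrates at
the water line — in the laboratory, a sandpaper strip lining a beaker. A
female lays roughly 20–140 eggs per blood meal, and fecundity estimation for
vector monitoring or behavioural assays means counting eggs on many such
strips. Manual counting is slow and error-prone; `ovocount` automates it for
the common imaging setups: microscope snapshots covering part of a strip
("micro" images) and single camera photographs of a whole strip ("macro"
images).

The method exploits one robust property of these images: eggs are nearly
black, the substrate is light. No segmentation model is learned; the whole
pipeline is a fixed global threshold plus area logic, which keeps it fast,
deterministic, and tunable by a non-expert from three parameters.

## The counting model

For a grayscale image $I$ with intensities in $[0, 255]$:

1. **Binarize.** Foreground is $I < \tau$ with BW threshold $\tau$ (default
   80). Eggs are dark-on-light; images with inverted polarity must be
   inverted upstream.
2. **Label.** Foreground pixels are grouped into maximal connected
   components, 8-connectivity by default so diagonally touching eggs merge
   into one (flagged) object.
3. **Classify by bounding-box area** $A_{box}$ against the band
   $[A_{min}, A_{max}]$ (defaults 800 and 1400 px²):
   $A_{box} < A_{min}$ → *rejected* (noise, count 0);
   $A_{min} \le A_{box} \le A_{max}$ → *confident* (one egg);
   $A_{box} > A_{max}$ → *uncertain* (probable cluster of touching eggs).
4. **Estimate clusters.** Each uncertain object gets
   $\hat{n} = \max\!\left(1, \left\lfloor A_{px} / A_{ref} + \tfrac12 \right\rfloor\right)$,
   where $A_{px}$ is its foreground pixel count and $A_{ref}$ the per-image
   single-egg reference: the median pixel area of the confident objects.
   This is the classic particle-counting ratio of total area to average
   single-particle area.
5. **Total.** The image estimate is the sum of per-object counts.

Two deliberate design choices resolve an ambiguity in what "object area"
means. Classification uses the *bounding-box* area, because a box is what a
reviewer sees and judges, and box area grows quickly when eggs merge — a pair
of touching eggs essentially always exceeds $A_{max}$. Cluster estimation
uses the *pixel* area, because pixel area (not box area) is proportional to
egg count for arbitrary cluster shapes.

The reference area is per-image, not global, so magnification differences
between images self-calibrate. When an image has no confident object at all,
the fallback $A_{ref} = 0.7\,(A_{min}+A_{max})/2$ approximates the fill
fraction of a rotated ellipse in its bounding box (an axis-aligned ellipse
fills $\pi/4 \approx 0.79$ of its box; rotation lowers it).

### Modes

* **micro** — the per-object pipeline above; the precise mode.
* **macro** — whole-strip photographs where per-egg boxes are unreliable:
  `estimate_by_histogram()` divides the total foreground pixel count by the
  reference area, skipping labeling. It is coarser but degrades gracefully
  at high density.
* **raft** — *Culex* egg rafts float on water and cannot be split into eggs
  by thresholding; every component at or above $A_{min}$ counts as exactly
  one raft and nothing is flagged as a cluster.

## The semi-automatic workflow

Flagged objects carry the pipeline's own uncertainty signal, so a human only
ever needs to look at those. `export_review()` writes the uncertain and
rejected objects to a CSV with a fixed header
(`image_id,object_id,status,auto_count,corrected_count,note`); the reviewer
fills `corrected_count` where the estimate is wrong; `apply_corrections()`
replaces those per-object counts and recomputes the total. Corrections are
per object rather than a single adjusted total so the audit trail records
*where* errors were; rejected objects can be corrected upward (a rescued
faint egg) just as uncertain ones can be corrected in either direction. The
operation is pure (the input result is untouched) and idempotent.

On synthetic data whose only counting errors occur in flagged objects, this
loop provably reaches zero error — the acceptance suite demonstrates 100%
exact totals over 30 clustered strips with ground-truth corrections.

## The synthetic strip generator

No public corpus of annotated oviposition-strip photographs exists, so the
package ships a seeded generator (`generate_strip()`) that emulates the
regime the algorithm consumes and provides exact ground truth.

* **Background**: per-pixel Gaussian, mean 200, sd 10 — a light, mildly
  textured substrate.
* **Eggs**: filled ellipses, full axes 46 × 24 px with 8% uniform jitter and
  uniform orientation on $[0, \pi)$, per-pixel Gaussian intensity mean 30,
  sd 10. With these defaults an isolated egg's bounding box is ≈ 930–1570 px²
  depending on orientation and jitter: almost always inside the default
  band, occasionally above it (a 45°-rotated large egg), in which case the
  object is flagged and its area-ratio estimate is still 1 — so isolated
  eggs are always counted exactly. The intensity model keeps the default
  threshold 80 more than 5 standard deviations from both populations;
  misclassified pixels are negligible.
* **Placement**: `round(n_eggs (1 - cluster_fraction))` eggs are placed as
  singles by rejection sampling with at least `min_gap` (default 6 px)
  clearance, enforced by stamping each accepted egg's ellipse enlarged by
  `min_gap + 1` into an exclusion mask. The remaining eggs form touching
  groups of 2–4 (a remainder of one egg is placed as a single, since a
  cluster needs two members); successive member centres sit at
  0.85–0.95 × the minor axis from the previous one, which keeps members
  overlapping. Group geometry is resampled until the merged pixel set is a
  single 8-connected component whose bounding box exceeds 1.05 × the default
  $A_{max}$ — so every synthetic merge is guaranteed to be flagged, the
  precondition for the zero-error semi-automatic property. A bounded number
  of attempts (default 10,000 per group) turns impossible densities into an
  explicit capacity error instead of an endless loop.
* **Determinism**: generation runs under its own RNG state derived from the
  spec's seed and restores the caller's state; identical specs give
  bit-identical images and ground truth, and `generate_dataset()` re-runs
  byte-identically.

What the generator deliberately does **not** model: real sandpaper grain and
glints, uneven illumination, egg collapse and debris, perspective. Passing
tests on synthetic strips therefore validate the *algorithmic* contracts
(classification logic, cluster arithmetic, review loop, determinism), not
photographic robustness; on real images the threshold and box band remain
the user's responsibility, which is exactly why they are exposed.

## Validation statistics

`fit_calibration()` regresses automatic on manual counts by OLS and reports
slope, intercept, $R^2$ and the two-sided $t$ test of slope = 0 on $n-2$
degrees of freedom — the standard calibration-curve summary for method
comparison. `fit_calibration_stratified()` fits the two density regimes
(default cutoff 100 eggs per image) separately, because per-object counting
weakens once eggs crowd; on mixed-density synthetic batches the low-density
slope lands closer to 1 than the high-density slope, reproducing the
direction seen with real strips. `evaluate_against_truth()` reports mean
absolute error, mean percent error (images with true count 0 excluded and
tallied separately), and the exact-match fraction.

For dual-choice oviposition assays, egg counts are converted to per-replicate
percentages (`choice_percent()`, the two arms of a replicate summing to 100)
and arms compared by Welch's unequal-variance $t$ test
(`welch_choice_test()`), which reduces to Student's $t$ when group sizes and
variances agree. Normality pre-checks and multi-factor ANOVA are routine
and left to base R (`shapiro.test`, `aov`/`car`), not wrapped here.

## Numerical choices and conventions

* All count rounding is **half-up** (`round_half_up()`), including the
  luminance conversion, cluster estimates and histogram estimates; base R's
  round-half-even would make estimates depend on parity.
* Colour images load through ITU-R BT.601 luminance
  $0.299R + 0.587G + 0.114B$. Conversion is idempotent on grayscale input.
  Orientation metadata embedded by cameras is ignored; images are processed
  as stored.
* Coordinates are 0-based, row 0 at the top, and every rectangle is
  half-open $[top, bottom) \times [left, right)$ — one convention shared by
  crops, bounding boxes, CSV outputs and ground truth.
* Components are ordered by bounding-box top-left corner (top-to-bottom,
  then left-to-right), so object ids are stable across runs and platforms.
* Degenerate inputs fail loudly with typed conditions: thresholds outside
  $[0,255]$, inverted box bands, empty crop rectangles, non-positive
  reference areas, strips too small for their egg load.

## Problem sizes

The shipped test and acceptance workloads use 480 × 1280 px strips (the
micro preset) with 10–150 eggs: large enough that densities, cluster rates
and area statistics behave like the crowded end of real microscope images,
small enough that the full suite runs in well under a minute of labeling and
generation time. The batch stand-ins are 50 low-density strips for automatic
reliability (mean absolute percent error, observed ≈ 0.5%) and 30 clustered
strips for the semi-automatic zero-error property; both are recomputed from
scratch by `scripts/acceptance.R`.

## Known limitations

* A fixed global threshold assumes sharp, roughly uniform contrast; shadowed
  or stained substrates need manual threshold tuning (that limit is
  inherent to the method, not the implementation).
* Cluster counts are area ratios: partially superimposed eggs hide pixels,
  so very dense clumps bias the automatic estimate downward — visible in the
  stratified calibration, and the reason the review loop exists.
* Species cannot be distinguished from egg blobs, and raft mode counts
  rafts, not the eggs within them.
* BMP support covers the uncompressed 8/24/32-bit variants.
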
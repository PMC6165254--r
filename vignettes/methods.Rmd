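---
title: "Quantifying hard tissue in colour strain elastograms: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hard tissue in colour strain elastograms: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 5)
library(elastocad)
```

## The problem

On a colour strain elastogram of the breast, stiff tissue deforms little
under probe compression and is rendered red; soft, high-strain tissue is
rendered blue, with green in between. Because malignant masses tend to be
stiffer than benign ones, the *predominance of red within the lesion* is a
malignancy indicator. Radiologists grade this visually on a three-point
scale, which is subjective and shows substantial inter-observer
variability. `elastocad` replaces the visual grading with a measured
quantity: the fraction of lesion pixels whose colour is red, obtained by a
fixed, deterministic segmentation. The only manual input is the lesion
contour, drawn on the B-mode panel and transferred to the elastogram by a
pure translation (side-by-side exports are same-scale).

## The measurement

1. **Colour representation.** Pixels are converted from 8-bit sRGB to
   CIELab (D65 / 2° observer, the sRGB standard — the source images do not
   state an illuminant, so the sRGB default is the only defensible choice).
   CIELab separates lightness from chroma; its a\* axis opposes green
   (negative) to red (positive), so red-hard tissue sits at large positive
   a\* regardless of brightness. Internally a\* and b\* are kept as
   real-valued CIE quantities; the familiar −127..+127 presentation is a
   display convention, and clamping or rescaling would distort the relative
   ordering that thresholding depends on.

2. **Hard-region delineation.** Within the lesion mask, Otsu's method is
   applied to the a\* values: the threshold maximizing the between-class
   variance splits the (typically bimodal) distribution into a red and a
   non-red class, and pixels above the threshold form the hard mask.
   Thresholding is restricted to lesion pixels because the classification
   concerns within-lesion predominance; converting the full image first and
   masking afterwards is mathematically identical per-pixel.

3. **Scoring.** The hard fraction `|hard| / |lesion|` maps to the ordinal
   score — 1 (soft) below 50%, 2 (intermediate) between 50% and 75%
   inclusive, 3 (hard) above 75% — and score 3 alone is called malignant.
   The boundary convention is the most literal reading of "lower than
   50%", "between 50–75%", "higher than 75%": both exact boundary values
   score 2. The 75% upper cut is the default because it maximizes AUC in a
   sweep over {70%, 75%, 80%, 90%} (`cutoff_sweep()` reproduces this
   analysis); the percentage shown to users is the raw fraction × 100 at
   one decimal, not a calibrated malignancy probability.

## Why a* alone is not enough: the blue gate

A point the colorimetry forces on any implementation: saturated sRGB blue
`(0,0,255)` has a\* ≈ **+79**, essentially the same as saturated red's
+80. The a\* axis only orders softness→hardness along the green↔red hue
limb; blue is far off that axis and is distinguished by its strongly
negative b\* (≈ −108 versus red's +67). An Otsu split of raw a\* values
would therefore classify soft blue tissue as hard. `segment_hard()`
consequently gates hard candidacy on `b* >= blue_floor_b` (default 0):
blue-hued pixels are soft by definition, and Otsu operates on the
remaining green-to-red pixels, where a\* genuinely discriminates. On real
vendor colormaps, whose soft limb is often desaturated, the gate is
harmless; on any colormap it encodes the physical claim actually being
made — "red means hard".

Two degenerate-case guards complete the rule, because Otsu *always* splits
whatever it is given:

* **Red floor** (`red_floor_a`, default 20 a\* units): if the upper Otsu
  class has mean a\* at or below the floor, the lesion contains no red and
  the hard mask is empty. This keeps all-soft lesions at 0% hard, which
  the 0%–100% malignancy axis presupposes.
* **Unimodal red**: if the *lower* class also has mean a\* above the
  floor, the whole candidate set is red (a lesion that is hard throughout,
  e.g. a continuum of saturated reds) and everything is hard. Without
  this, an all-red lesion would be reported as ~50% hard purely because
  Otsu split its reds in half.

Constant (zero-variance) a\* distributions resolve the same way: all hard
when the mean exceeds the floor, else all soft.

## Numerical choices

* **Colour conversion** is the textbook sRGB → linear RGB → XYZ → Lab
  chain, with the reference white taken as the exact XYZ image of
  RGB(255,255,255). This makes neutral grays *exactly* achromatic
  (a\* = b\* = 0 to machine precision) instead of carrying a small
  chromatic residual, at the cost of differing from published D65 white
  coordinates in the 5th decimal. Tests hold the conversion to within 0.1
  of two independent references and require Lab→RGB→Lab round-trips on a
  16³ grid to reproduce all components within 0.5.
* **Otsu candidates** are the interior boundaries of 256 equal-width bins
  over the observed a\* range (the 8-bit convention); class weights and
  means are computed from the raw values rather than binned midpoints, so
  the result is *exactly* the exhaustive search over the candidate grid.
  Ties resolve to the lowest qualifying threshold, for determinism.
* **Rasterization** uses 0-based coordinates, x = column, y = row, pixel
  centers at integers, and the half-open even–odd ray rule: a square with
  corners at 0 and s covers exactly s² pixel centers, abutting polygons
  never double-count a pixel, the rule is orientation-independent and
  equivariant under integer translations, and no tolerance-based
  on-boundary tests are needed.
* **AUC** is the midrank Mann–Whitney probability (ties count half). For
  cut-off sweeps the ROC variable is the *3-level score*, not the
  continuous fraction — the AUC must depend on the cut-off for a sweep to
  select one, which a fraction-based ROC cannot do.
* **Bootstrap** intervals (AUC and paired AUC differences) use stratified
  resampling within each class — every replicate keeps both classes — with
  percentile 2.5/97.5 limits, 2000 replicates by default, and a mandatory
  seed; results are bit-reproducible. The paired difference test reports
  A − B with a two-sided p-value from the sign proportion of the bootstrap
  distribution. A bootstrap approach (rather than DeLong) matches how such
  intervals are typically produced by the clinical software this mirrors.
* **Kappa** is unweighted and computed on the binary calls — the
  "diagnosis" agreement — with the conventional interpretive bands
  (≤0.20 poor … >0.80 very good). **ICC** is the two-way random-effects,
  absolute-agreement, single-rater form ICC(2,1); which ICC variant
  clinical packages report is often unstated, so the choice is pinned here
  and documented.
* **Under/over-segmentation** are the relative set differences
  |G∖S|/|G| and |S∖G|/|S|; a signed area difference could leave [0, 1],
  contradicting the measures' stated range.

## The phantom generator

No public breast elastography image set exists, so the package carries a
first-class synthetic generator. A `phantom_spec` defines an elliptical
lesion on a uniform soft background (strain 0.15); within the lesion,
exactly `round(target_fraction × area)` pixels are hard. The recorded
`true_hard_fraction` is this exact constructed ratio, never the requested
target. Hard regions are spatially coherent — a compact blob grown around
a random interior point, or a band cut by a random half-plane — because
real stiff foci are contiguous, and coherent regions exercise Otsu on the
realistic bimodal a\* distributions it assumes. Hard pixels draw strain
uniformly from [0.85, 1] and soft pixels from [0, 0.35], keeping the two
classes in the red and blue–green limbs of the colormap; these bands are
documented package constants. The colormap itself is piecewise-linear
blue→green→red (0 → blue, 0.5 → green, 1 → red). Optional Gaussian chroma
noise (per channel, clipped to [0, 255]) is applied after colormapping.
All randomness in a study flows from its single recorded seed; identical
specs yield bit-identical images.

`generate_cohort()` emulates a case mix: target fractions drawn from
Beta(2, 5) for benign and Beta(5, 1.5) for malignant lesions, geometry
jittered per lesion, default chroma noise sd 5 (8-bit counts). The Beta
parameters give mostly-soft benign and mostly-hard malignant lesions with
realistic overlap — some malignant lesions fall below the 75% cut, so
cohort sensitivity sits well below 100% while specificity stays high,
qualitatively matching clinical experience with strain scoring.
Default problem sizes (200×200 px images, ~4,800 px lesions, 50+50
cohorts, 2000 bootstrap replicates) keep a full simulated evaluation in
the tens of seconds.

```{r cohort, eval = FALSE}
studies <- generate_cohort(50, 50, seed = 7)
report  <- classify_cohort(studies)
evaluate_performance(report, n_boot = 2000, seed = 7)
#> <cad_eval> 100 lesions (50 malignant / 50 benign)
#>   sensitivity 54.00%, specificity 100.00%, AUC 0.962 (95% CI 0.930-0.987)
```

**What the phantoms do and do not show.** Passing recovery tests on
phantoms demonstrates that the measurement chain — contour, mask, colour
conversion, thresholding, scoring — is internally correct and robust to
moderate chroma noise. It does not validate the clinical claim: phantoms
have no speckle, no overlay transparency blending, no vendor colormap, no
depth-dependent strain artefacts, and their class-conditional hard
fractions are assumed, not measured from tissue. Clinical performance
numbers can only come from patient images.

## Simulated observers

`jitter_contour()` perturbs a contour the way a second reader would
redraw it: a smooth low-order radial modulation about the centroid plus a
small rescale and translation — readers disagree about where the margin
lies, not pixel-by-pixel. Feeding jittered contours through the pipeline
yields per-observer reports whose agreement statistics (pairwise Jaccard
tables, kappa on calls, ICC on scores) exercise the same machinery used
for real multi-reader studies.

## Known limitations

* The colormap inversion problem is ill-posed in general: the package
  quantifies *redness*, not strain. Vendor maps that render hard tissue
  in non-red hues require a different chroma axis.
* The blue gate assumes blue = soft. A colormap using blue for hard
  tissue would need `blue_floor_b` disabled and the sign conventions
  revisited.
* Panel registration is a pure translation; composites with differing
  panel scales or rotations are out of scope.
* The three-level score discards within-class information; the continuous
  fraction is reported alongside it for downstream use.
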
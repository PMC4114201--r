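---
title: "Methods: injection-site quantification, intensity-correlation colocalization, and IPSC decomposition"
author: "tracequant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: injection-site quantification, intensity-correlation colocalization, and IPSC decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracequant)
```

# Scope

`tracequant` implements three quantification procedures that recur in
neural tract-tracing studies of the auditory brainstem (and elsewhere):

1. **Semi-automated injection-site quantification** — given serial
   epifluorescent sections through a tracer-injected nucleus (e.g. the
   MNTB, the medial nucleus of the trapezoid body) and an
   experimenter-traced nucleus outline per section, estimate the
   *apparent* injected volume as a percentage of the nucleus volume,
   locate the injection epicenter, and estimate tracer spillover outside
   the nucleus.
2. **Per-cell intensity-correlation colocalization** — Li's intensity
   correlation analysis (PDM and ICQ) on two-channel cell crops, the
   normalized colocalization color map for hot-spot inspection, and a
   Mann-Whitney rank-sum comparison of per-cell ICQ between groups
   (e.g. age groups).
3. **Pharmacological IPSC decomposition** — split evoked inhibitory
   postsynaptic currents into glycinergic and GABAergic fractions from
   amplitudes measured under receptor blockers (strychnine, then
   strychnine + gabazine), and compare fractions between groups with a
   t-test.

All three stages are validated closed-loop against seedable synthetic-data
generators that emit ground-truth manifests, because the kinds of raw data
these methods consume (injected brains, confocal stacks, patch-clamp
recordings) cannot be bundled with a package.

Everything operates in a single coordinate convention: 0-based pixel
coordinates, x rightward, y downward, pixel centers at half-integers. ROI
files written by the package carry this convention in their header.

# Injection-site quantification

## Model

Images are 8-bit working-depth grids (12- or 16-bit sources are converted
by integer division by `2^(depth - 8)` — a pure bit shift, chosen over
min–max rescaling because it is parameter-free and preserves relative
intensities across sections acquired at constant exposure). The
experimenter's nucleus outline is a simple polygon; it is rasterized by
the pixel-center even-odd rule, which makes containment deterministic and
matches common raster tooling.

Per section, in the tracer channel:

* **Background sampling.** Three square boxes, each covering 1% of the
  image pixels (side `round(sqrt(floor(0.01 N)))`; 205 px on a
  2048 × 2048 frame), sample the background distribution. Automatic
  placement uses image corners skipped when they intersect the nucleus
  ROI — deterministic, and a reasonable stand-in for the experimenter's
  choice of signal-free regions. Supplied positions override this, even
  onto the ROI (with a warning), since an experimenter may know better.
* **Threshold.** `threshold = mean + 2*SD` of the pooled pixel set, where
  the pooled set is the nucleus-ROI pixels **plus** the three boxes
  (the literal reading of the procedure this package operationalizes; a
  `pool = "background"` switch restricts pooling to the boxes, since the
  alternative reading is defensible — the choice is exposed rather than
  hidden). SD uses the sample (n − 1) denominator. If `mean + 2*SD > 255`
  the upper bound `255 - 2*SD` applies and the result is flagged
  `capped`. Thresholds are kept real-valued; labeling uses a strict `>`
  comparison, so integer rounding of the threshold would only add an
  arbitrary convention.
* **Counting.** Labeled = pixels strictly above threshold inside the ROI
  mask.
* **Spillover.** A box of area 1.25 × the ROI area is centered on the ROI
  mask centroid. The box's shape is underdetermined by the procedure's
  description; we give it the aspect ratio of the ROI's bounding box
  (the least surprising reading) and round outward to integer bounds.
  Each 1-pixel-wide side is tested for the fraction of its pixels above
  threshold; a side at or above 10% moves outward one pixel per
  iteration, independently of the others, until all sides fall below 10%
  or hit the image border (flagged and warned). The printed rule "fell
  below 10%" is implemented as strict `< 0.10`, with `>= 0.10`
  triggering expansion. Corner pixels belong to both adjacent sides —
  symmetric and simple, given that side lengths vary while sides stay
  one pixel wide. Spillover = suprathreshold pixels inside the final box
  and outside the ROI. Spillover is reported separately and **not**
  added to the injected-volume percentage, since its contribution is a
  separate question from nucleus fill.

Across sections, areas become volumes via
`pixels × pixelSize² × thickness`; the headline quantity is
`100 · Σ labeled volume / Σ ROI volume`. The epicenter is the section with
the maximal labeled *fraction* (not absolute count — robust to ROI-area
variation along the antero-posterior axis; this is an interpretation and
is flagged as such). Antero-posterior coverage is analyzed sections over
the nucleus's total extent in sections, with the acceptability rule
"at least 70% analyzed". Defaults (80 µm sections, 0.742 µm pixels,
2048 × 2048 frames) echo a typical 10× epifluorescence survey
acquisition.

One section-level assumption: sections arrive pre-aligned by their index;
no registration is performed. One ROI per analyzed section is required —
no interpolation between traced sections.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pool` | `"roi+background"` | pixel set pooled for the threshold |
| `initAreaScale` | 1.25 | initial spillover box area / ROI area |
| `sideFraction` | 0.10 | side-expansion rule |
| `thicknessUm` | 80 | section thickness (µm) |
| `pixelSizeUm` | 0.742 | isotropic pixel size (µm) |

# Intensity-correlation colocalization

For paired per-cell intensity vectors $A$, $B$, the product of the
differences from the mean is
$\mathrm{PDM}_i = (A_i - \bar A)(B_i - \bar B)$, and the intensity
correlation quotient is

$$\mathrm{ICQ} = \frac{\#\{\mathrm{PDM}_i > 0\}}{\#\{\mathrm{PDM}_i \neq 0\}} - 0.5 \in [-0.5, +0.5].$$

Pixels with PDM exactly 0 are excluded from the ratio rather than counted
as non-positive: this keeps the ±0.5 extremes attainable and the statistic
symmetric in its channels. The zero-PDM count is reported so the
alternative convention can be recomputed from the same object. A constant
channel makes the ICQ undefined and raises an error naming the channel.
For a bivariate Gaussian with correlation $\rho$, the expected ICQ is
$\arcsin(\rho)/\pi$ (the orthant probability minus ½), which is what the
synthetic generator's closed loop checks.

Cell crops are 3D (x, y, z) with an optional voxel mask; analysis of a
single confocal plane is the `nPlanes = 1` special case. Both modes are
legitimate usages found in practice; the 3D crop is the default because it
uses all acquired voxels of the cell. No intensity pre-thresholding of
background voxels inside the crop is applied by default (popular plugin
implementations offer one, but it introduces a free parameter); a mask is
the explicit way to restrict the voxel set.

The colocalization color map (nMDP) is the per-pixel PDM normalized by
$(A_{max} - \bar A)(B_{max} - \bar B)$, clipped to $[-1, 1]$; its positive
part is exported as a hot-spot layer. Its sign pattern equals the PDM sign
pattern by construction.

Group comparison is a two-sided Mann-Whitney/Wilcoxon rank-sum test via
`stats::wilcox.test`: exact when both groups have ≤ 20 values and no ties,
otherwise the normal approximation with tie and continuity correction.
Li's per-cell sign test (`icqSignTest`) is provided but is not part of the
headline pipeline, which reports group-level comparisons.

# IPSC decomposition

Amplitudes are peak magnitudes under three conditions: total evoked
inhibitory current, residual after strychnine (the GABAergic component),
and residual after strychnine + gabazine (complete block; any remainder is
leak). The decomposition subtracts the complete-block amplitude from both
numerator and denominator — the convention is stated explicitly because
published trace figures show the complete block without spelling out the
subtraction:

$$f_{GABA} = \frac{A_{stry} - A_{both}}{A_{total} - A_{both}},
\qquad f_{gly} = 1 - f_{GABA}.$$

Fractions are per-cell, normalizing each cell to its own leak-subtracted
total (per-cell normalization is the reading that makes fractions
comparable across cells of different absolute synaptic strength). Records
violating `both ≤ strychnine ≤ total` are flagged and excluded, never
silently dropped. The between-group test on the GABA fraction is Welch's
t-test by default — at group sizes like 5 vs 4, equal variances should not
be presumed — with Student's pooled test available for exact-replication
work. When both groups are degenerate (zero variance, different means) the
p-value is reported as the smallest positive double rather than 0, keeping
it in the documented (0, 1] range.

# Synthetic-data generators

Each generator is a pure function of its parameters plus a seed (the RNG
state is saved and restored around every call), and returns a ground-truth
manifest alongside the data.

**Injection series** (`generateInjectionSeries`). Per section: a
nucleus-shaped ROI polygon (laterally elongated ellipse, eccentricity 1.6,
with smooth low-order radial wobble — always simple), an injected blob,
optional spillover lobes, and Gaussian noise, discretized round-half-up
and clipped to [0, 255] (round-half-up rather than banker's rounding so
the discretization is monotone and unbiased upward symmetric). The blob is
produced by ranking a smooth random field (distance to a random focus plus
low-frequency harmonics) inside the ROI and taking exactly
`round(fraction × ROI area)` top pixels — irregular, contiguous shapes
with *exact* area control, which is what makes noiseless closed-loop
tests exact. Defaults are the conditions the validation suite runs under:
10 sections of 256 × 256 px (a downscaled survey frame that keeps a
20-series simulation in seconds; the procedure is resolution-agnostic
because the threshold and box rules are expressed in fractions of
pixel counts), ROI ≈ 4% of the frame, a bell-shaped antero-posterior
injection profile scaled so the true injected volume fraction is 0.14,
background 20 ± 5, core intensity 200. With these values the pooled
threshold always falls between the background tail and the core, so
recovery error reflects only noise pixels crossing the 2-SD rule — the
peak-section core share must stay below ~20% of the pooled pixel set for
that to hold, which the default geometry guarantees. The generator's
truth records the realized per-section fractions and defines the true
volume fraction as the ROI-area- and thickness-weighted mean — exactly
the quantity the volume-percentage estimator measures (for equal ROI
areas it reduces to the thickness-weighted mean of section fractions).
Background statistics are free parameters of the generator, not estimates
of any particular study's images.

**Colocalization fields** (`generateColocCells`). Non-overlapping disk
cells (radius 6 px by default) on a jittered grid — grid placement makes
the non-overlap invariant structural rather than retry-based, and packing
failures report the achievable cell count. Inside a cell the two channels
are a bivariate Gaussian (Gaussian copula over Gaussian marginals,
mean 120, SD 30) with the requested Pearson correlation; outside,
independent background noise (30 ± 8). Correlation targets are quoted
*before* discretization; at the default cell size discretization shifts
the empirical correlation by far less than the ±0.05 tolerance the
property tests use.

**IPSC experiments** (`generateIpscExperiment`). Totals around 3000 pA
(a typical large evoked inhibitory peak at a calyceal-inhibition
recording; the decomposition is scale-invariant so this choice is
cosmetic) with 5% CV, residuals `leak + f · (total − leak)` with
multiplicative noise of the same CV, resampled within bounds. Defaults
mirror a young/adult design: groups of 5 and 4 cells with generating GABA
fractions 0.24 and 0.06.

What the generators deliberately do **not** emulate: point-spread
functions, photobleaching, z-axis optics, chromatic shift, autofluorescence
structure, or cell-shape variability. Passing closed-loop tests therefore
demonstrates that the *computations* are correct and stable under noise —
not that the procedures are robust to every optical artifact of real
tissue.

# Numerical choices and degenerate inputs

* Rasterization: pixel-center even-odd rule; boundary-grazing centers
  resolve deterministically through the half-open crossing test. A
  polygon wholly outside the image yields an empty mask with a warning
  (not an error); a self-intersecting polygon is rejected on load.
* Depth conversion validates the declared range and names the first
  offending pixel.
* A constant pooled pixel set gives SD 0 and threshold = mean, without
  error.
* Zero-PDM pixels: excluded from the ICQ ratio (see above); PDM equality
  to zero is exact floating-point equality, which for integer intensities
  occurs exactly when a pixel sits at a channel mean representable in
  binary — the reported `nPdmZero` makes the effect auditable.
* Expanding box: all four sides are evaluated against the *same* box
  state, then moved simultaneously; one pixel per side per iteration.
  Sides pinned at the image border are flagged in the result and warned
  about.
* Epicenter ties resolve to the lowest section index (deterministic).
* Sections with zero ROI area are excluded from summaries with a warning.

# Problem sizes used in validation

The packaged test-and-acceptance suite runs: 20 injection series of 10
sections at 256 × 256 px against a 14% generating volume fraction
(tolerance: within 2 percentage points in ≥ 95% of seeds); 50 random
64 × 64 spillover instances against an independently coded brute-force
simulation of the side rule (exact equality); ICQ extremes and a
10⁶-pixel independence null (|ICQ| ≤ 0.005); cohorts of 60 + 60 cells at
generating correlations 0.5 vs 0.0 (Mann-Whitney p < 0.001 in ≥ 95% of
seeds); and 100 IPSC experiments at n = 5 vs 4 (group means within ±0.03
of 0.24 / 0.06 in ≥ 95% of seeds). These sizes were chosen to keep the
whole suite under a minute on one core while leaving the statistical
margins wide.

# Known limitations

* The pooled-set ambiguity for the threshold (ROI + background vs
  background only) is resolved by a switch, not by evidence; results are
  sensitive to it when the injection occupies a large share of the ROI,
  because injected pixels then inflate the pooled mean and SD.
  Relatedly, when the injected core occupies more than roughly a fifth
  of the pooled pixel set, `mean + 2*SD` can rise above the core
  intensity itself and the procedure under-counts — an inherent property
  of the published rule, not of this implementation.
* The spillover box is rectangular; spillover hugging a concave nucleus
  border can be included in the box while genuinely ambiguous pixels
  near the ROI edge are excluded by the mask, so the spillover count is
  a box-bounded estimate, not a segmentation.
* ICQ is a sign statistic: it discards deviation magnitudes, so a few
  bright co-varying voxels cannot dominate it — by design, but it also
  means ICQ differences do not quantify *strength* of colocalization.
* The IPSC module consumes peak amplitudes; trace-level analysis
  (kinetics, decay fits, series-resistance artifacts) is out of scope.
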
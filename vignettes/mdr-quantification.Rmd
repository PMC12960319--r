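---
title: "Quantifying mammographic dense rate: models, phantoms and cohort analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mammographic dense rate: models, phantoms and cohort analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dense breast tissue both raises breast-cancer risk and masks tumours on
mammography, yet the standard four-category composition grading (fatty,
scattered, heterogeneous, extreme dense) is assigned visually and suffers
substantial inter-observer variability. `mdrquant` implements a fully
automated, quantitative alternative for processed mediolateral-oblique (MLO)
mammograms: the *mammographic dense rate* (MDR).

The statistic is deliberately self-referencing. On each image, the pectoral
muscle — always present in an MLO view — serves as an internal intensity
reference. Let $D_{mj}$ be the mean normalized intensity over
pectoral-muscle pixels, $A_{gl}$ the number of glandular-region pixels, and
$A_d$ the number of glandular pixels whose intensity is strictly greater
than $D_{mj}$. Then

$$\mathrm{MDR} = \frac{A_d}{A_{gl}} \in [0, 1].$$

Because numerator and denominator are pixel counts referenced to a
same-image threshold, MDR is invariant under any strictly monotone
rescaling of the intensities — vendor post-processing that preserves
intensity order does not change it. That is what makes it usable on
"for presentation" images where volumetric tools requiring raw data fail.

Composition categories are attached with the quantitative atlas cut-offs:
MDR below 10% is *fatty*, 10% to below 50% *scattered*, 50% to below 80%
*heterogeneous*, and 80% or more *extreme dense*; the last two together are
*dense breasts*.

One definitional subtlety: the statistic's definition counts pixels
*strictly above* $D_{mj}$, while the visual atlas speaks of pixels *at or
above* the pectoral level. We follow the strict inequality by default and
expose `inequality = "ge"` in `compute_mdr()` for atlas emulation. On real
images the choice is immaterial (exact ties have measure near zero); on
quantized synthetic data it is testable, which is why it is a switch and
not a constant.

## Segmentation

The three regions (fat, gland, pectoral muscle; background implicit) come
from a semantic segmenter with a classic U-Net shape: `depth` encoder
levels of two 3×3 ReLU convolutions and 2×2 max-pooling, a two-convolution
bottleneck, and a mirrored decoder (nearest-neighbour ×2 upsampling, a
reducing 3×3 convolution, concatenation with the encoder skip tensor, a
fusing 3×3 convolution), closed by a 1×1 convolution onto four class
scores. Prediction is the per-pixel argmax, ties broken toward the lower
class index so inference is deterministic. The network is implemented
directly in RcppArmadillo (im2col + GEMM convolutions, Adam, softmax
cross-entropy with an optional soft-DICE term); weight initialization and
epoch shuffling draw from R's RNG, so a `train_config(seed = )` makes the
entire training history reproducible on one machine.

Defaults follow the reference protocol: input resampled to 320×384
(width × height, portrait MLO; bilinear for images, nearest-neighbour for
masks so labels are preserved), `depth = 4`, 100 epochs — accuracy on real
data plateaus at that point. The orientation of "320 × 384" and the
interpolation rules are not uniquely determined by the protocol; both are
our choices and are stated here so ports can match them. Test-time images
are resized directly to the target size (no aspect-preserving padding) —
also a choice, flagged here.

Segmentation quality is summarized by the DICE coefficient
$2|X \cap Y| / (|X| + |Y|)$ per tissue class, with the convention that two
empty masks score 1 and exactly one empty mask scores 0. Since a single
reported DICE number does not determine its aggregation rule, this package
always reports per-class values *and* their unweighted mean over the three
tissue classes (`macro_dice()`, background excluded) and states which is
which.

## Synthetic phantoms

No clinical images ship with the package; every stage is testable on seeded
synthetic phantoms that reproduce the geometry the segmenter must learn:

* a half-elliptical breast against the chest-wall edge, fat-valued;
* a triangular pectoral wedge touching the upper chest-wall corner
  (area fraction configurable, intensity mean 0.75 by default);
* an elliptical glandular region inside the breast;
* left/right laterality by horizontal mirroring;
* additive Gaussian noise, clipped to $[0, 1]$.

Gland texture is the load-bearing design decision. Gland pixels are a
binary mixture of a dark mode below the pectoral mean and a bright mode
above it, with *exact-count* assignment: `round(p * n_gland)` pixels are
bright. After noise, each mode is clamped to stay at least 0.01 away from
the pectoral mean on its own side. The realized pectoral mean concentrates
within well under 0.01 of its nominal value for any realistic region size,
so the phantom's ground-truth MDR equals the requested `dense_fraction`
`p` to within one pixel — including exactly 0 and 1 at the endpoints. This
makes `p` directly interpretable as the expected MDR and turns
threshold-recovery tests into sharp checks rather than statistical ones.

What the phantoms do *not* emulate: vendor post-processing curves, scatter
and compression artefacts, skin folds, lesions, implants, or anatomical
texture. A segmenter that excels on phantoms has learned the layout and
intensity logic of an MLO view, not clinical appearance; phantom results
bound nothing about clinical DICE. The reference model's 0.967 on
annotated clinical images is therefore explicitly *not* a target of this
package's tests.

## Cohort analytics

The cohort layer works in percent (0–100), matching how per-age tables are
reported; the density layer works in proportions (0–1); `mdr_percent`
marks every boundary crossing. Per-age summaries (`age_stratified_stats()`)
give n, mean, SD, median and the 25th/75th percentiles. Percentiles use
linear interpolation between order statistics (R's default type 7),
documented so ports can match. A single observation has SD 0 by
convention. MDR is computed per image; averaging a woman's two sides is a
deliberate non-default (screening tables count images, not women).

Two derived views expose the population structure:

* `mean_median_divergence()` — in a mixture of a declining majority and a
  persistently dense minority, the minority drags the mean above the
  median at older ages; the growing gap is the mixture's signature.
* `temporal_differentiation()` — first difference of the per-age median
  (the median, not the mean, is differentiated — our choice where the
  protocol is silent), smoothed by a centred moving average. The default
  window is 5 years, configurable; edge windows shrink symmetrically
  rather than padding. This locates where the perimenopausal decline
  flattens into the post-menopausal plateau.

`annualized_decline()` is the elementary rate
$(\mathrm{MDR}_{start}-\mathrm{MDR}_{end})/(age_{end}-age_{start})$.
Reported reference values for the late cohort (20.5% at 60 to 16.0% at 79)
give 4.5 points and 0.24%/yr, which the package reproduces from those
endpoints. For the early cohort the published endpoint pair (36.2% to
20.7% over ages 40–59, i.e. 15.5 points) is arithmetically inconsistent
with the simultaneously reported "25.2% reduction"; the per-year rate
1.33 equals 25.2/19, not 15.5/19. The cohort generator adopts the stated
1.33%/yr rate and treats neither 25.2 nor 15.5 as a correctness target.

### Trajectory classification

Longitudinal series separate into a rapidly declining majority and a
persistently dense minority. No published criterion defines the split, so
`trajectory_rule()` ships an explicit parameterized rule that is ours, not
a reproduction: least-squares slope ≤ −1.0 %/yr → *rapidly decreasing*;
otherwise mean MDR ≥ 50% with slope > −0.5 %/yr → *persistently dense*;
anything else (including single-exam series) → *indeterminate*.

### The cohort generator

`generate_cohort()` emulates a long perimenopausal follow-up: subjects
enrol within `enroll_window = 5` years of age 40 and are examined
`exams_per_subject = 5` times, `exam_spacing = 4` years apart, so a series
spans 16 years of the transition — the span over which the two
subpopulations actually diverge. Trajectories are linear in age from a
group-specific start level at age 40 (declining group N(50, 8) at
−1.33 %/yr; persistent group N(70, 8) at −0.1 %/yr), plus N(0, 2) exam
noise, clamped to [0, 100]. The start levels must keep the declining
group's series above the zero floor through the 16-year window (a subject
starting at 50 ends near 23; the floor is more than 3σ away), because a
clamped, flattened series no longer carries the group's slope; with that
satisfied, five exams give a slope standard error of about 0.16 %/yr, the
±0.33 %/yr gap between the declining rate and the rule threshold is a 2σ
margin, and hidden-group recovery above 95% is a property of the model,
not luck. Group sizes are
exact (`round(frac_persistent × n)`), and truth labels live in a separate
sidecar table so analysis code cannot read them by accident.

For age-40 cross-section experiments (the fraction of women below 10%
MDR), the generator is instead calibrated explicitly: the declining
group's start SD is solved from the target mass below 10%, e.g.
$\sigma = (10 - 36.2)/\Phi^{-1}(0.138/0.8) \approx 27.7$ for a 13.8%
first-bin target with a 20% persistent minority centred at 70. That
heavier spread is realistic for a screening cross-section but would flood
a 16-year trajectory study with floor-clamped series, which is why the
trajectory defaults and the cross-section calibration are different
parameterizations of the same generator.

## Numerical choices and degenerate inputs

* Intensities are compared at native double precision on the normalized
  [0, 1] scale; no epsilon is added to the threshold comparison. The
  inequality switch, not an epsilon, resolves boundary pixels.
* Images with no pectoral or no glandular pixels raise empty-region
  errors; `run_pipeline()` converts them into skip-list entries with
  reasons, and `rows + skips = input files` always holds.
* Phantom dimensions must be divisible by 16 (the depth-4 pooling
  pyramid); `train_config()` separately validates divisibility by
  `2^depth`.
* Masks are stored as 8-bit grayscale PNG with code values {0, 1, 2, 3};
  images as 16-bit grayscale TIFF. A freshly quantized image round-trips
  bit-identically after the first write.
* Histogram bins are left-closed, `[0,10), …, [90,100]`, the last bin
  closed so MDR = 100% is counted.

## Problem sizes used in the shipped tests

Unit tests run on 64×64 and 96×112 phantoms with a thin network
(`depth = 2`, `base_channels = 8`, 18 epochs on 28 training phantoms),
which reaches macro DICE ≈ 0.9 on held-out phantoms in about a minute. The
end-to-end check trains on 240/60 phantoms at 160×192 for 4 epochs — a
deliberately thin configuration that converges past macro DICE 0.99 on
separable synthetic data; the full-resolution, depth-4, 100-epoch
configuration remains the default for real use. Cohort checks use 150–2000
subjects. These sizes were chosen as the smallest at which each property
is sharply testable.

## Known limitations

* The segmenter is trained here only on phantoms; nothing is claimed about
  clinical images, vendors, CC views, or tomosynthesis.
* DICOM ingestion is not built in; convert to 16-bit grayscale PNG/TIFF
  upstream (photometric inversion for MONOCHROME1 must happen there).
* The trajectory rule is a transparent operationalization, not a validated
  clinical classifier; its thresholds are tunable and should be re-derived
  for any real cohort.
* MDR itself ignores breast thickness and compression; it is an areal, not
  volumetric, density measure.
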
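# mdrquant

Automated quantification of the **mammographic dense rate (MDR)** on
processed mediolateral-oblique (MLO) mammograms, with age-cohort density
analytics.

Visual grading of breast composition (fatty / scattered / heterogeneous /
extreme dense) is notoriously reader-dependent, and volumetric density tools
need raw acquisition data that most archives no longer hold. MDR sidesteps
both problems: it is computed on ordinary processed images, using each
image's own pectoral muscle as the intensity reference. With `D_mj` the mean
intensity of the segmented pectoralis major, `A_gl` the number of
glandular-region pixels and `A_d` those strictly brighter than `D_mj`,

```
MDR = A_d / A_gl
```

Because both counts are referenced to a same-image threshold, MDR is
invariant to any order-preserving vendor post-processing. Composition
categories use the quantitative atlas cut-offs 10% / 50% / 80%;
heterogeneous and extreme-dense together are "dense breasts".

The package provides, for audiences working on quantitative breast-density
screening analytics:

* **`phantom`** — a seeded generator of synthetic MLO image/mask phantoms
  (triangular pectoral wedge, half-elliptical breast, embedded gland whose
  ground-truth dense fraction is an exact, controllable parameter) and of
  longitudinal two-subpopulation MDR cohorts, so every stage is testable
  without clinical data.
* **`segmentation`** — a U-Net style encoder-decoder (implemented in
  RcppArmadillo; no external deep-learning stack) that labels pectoral
  muscle, gland and fat, with per-epoch DICE history and macro/per-class
  DICE evaluation.
* **`density`** — `pectoral_mean_intensity()`, `compute_mdr()`,
  `classify_composition()`, `is_dense_breast()`.
* **`cohort`** — per-age summary tables, mean–median divergence,
  moving-average temporal differentiation, MDR histograms, annualized
  decline, and individual-trajectory classification into rapidly declining
  vs persistently dense subjects.
* **`io`** — 16-bit TIFF image and label-mask PNG round trips, manifests,
  config-hashed CSV outputs, an end-to-end `run_pipeline()`, and a thin
  command-line front end (`inst/cli/mdrquant.R`).

## Worked example

Generate phantoms, train a small segmenter, and quantify density end to end
(a thin CPU-sized configuration; the defaults `depth = 4`,
`target_size = c(320, 384)`, `epochs = 100` are the full protocol):

```r
library(mdrquant)

sampler <- default_phantom_sampler(width = 160L, height = 192L)
train <- generate_phantom_set(60, sampler, seed = 101)
test  <- generate_phantom_set(20, sampler, seed = 202)

cfg <- train_config(epochs = 6, batch_size = 4, learning_rate = 2e-3,
                    depth = 2, base_channels = 8, seed = 5,
                    target_size = c(160L, 192L))
seg <- train_segmenter(train, test, cfg)
tail(tidy(seg), 3)
#> # A tibble: 3 × 6
#>   epoch   loss macro_dice dice_fat dice_gland dice_pectoral
#>   <dbl>  <dbl>      <dbl>    <dbl>      <dbl>         <dbl>
#> 1     4 0.129       0.907    0.975      0.874         0.873
#> 2     5 0.0753      0.972    0.978      0.972         0.966
#> 3     6 0.0504      0.969    0.963      0.971         0.972
```

After six epochs the held-out macro DICE (unweighted mean over fat, gland
and pectoral) is 0.97: the network has learned the MLO layout well enough
for density work. Now quantify one phantom whose true dense fraction was
set to 0.40:

```r
ph <- generate_phantom(phantom_params(width = 160L, height = 192L,
                                      dense_fraction = 0.40), seed = 7)
pred <- predict_mask(seg, ph$image)
macro_dice(pred, ph$mask)
#> [1] 0.9784
compute_mdr(ph$image, pred)
#> # A tibble: 1 × 6
#>    d_mj  a_gl   a_d   mdr mdr_percent category
#>   <dbl> <int> <int> <dbl>       <dbl> <fct>
#> 1 0.748  6304  2434 0.386        38.6 scattered
```

`d_mj` is the pectoral threshold (the phantom's pectoral mean is 0.75),
and MDR through the *predicted* mask comes out at 0.386 against a true
dense fraction of 0.40 — segmentation error leaks a few fat pixels into
the gland region — landing in the "scattered" composition band.

Cohort analytics run on tabular exam records:

```r
co <- generate_cohort(cohort_params(n_subjects = 200), seed = 1)
age_stratified_stats(co$records)      # per-age n / mean / SD / median / IQRs
classify_trajectories(co$records)     # per-subject slope, level, group
annualized_decline(20.5, 60, 16.0, 79)
#> [1] 0.2368421
```

The last call is the late-cohort decline rate from its reported endpoints:
4.5 MDR points over 19 years, 0.24 %/yr when rounded.

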
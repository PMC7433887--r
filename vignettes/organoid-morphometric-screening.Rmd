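---
title: "Morphometric profiling of 3D organoid screens: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric profiling of 3D organoid screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `organoidscreen`, the parameters
that matter, and the design decisions taken where the methodology was
genuinely open. It states no empirical result that the package's tests do
not themselves compute.

## The measurement problem

Tumour-derived organoids respond to effective compounds with coordinated
morphological change — shrinkage, lumen collapse, loss of nuclei, debris —
that can be quantified from two-channel confocal z-stacks (Hoechst-type
nuclei channel, phalloidin-type F-actin channel) long before a viability
readout saturates. The pipeline converts each well's stack pair into a
single phenotypic distance from the vehicle-control morphology, and each
compound's dose series of distances into an EC50.

## Synthetic screen generator

Real patient-derived screening images are rarely distributable, so the
package is exercised end to end on a simulator whose defaults are the study
conditions of the workflow it models:

* **Acquisition**: 25 z-planes at 10 µm steps, 16-bit two-channel frames;
  default 256×256 px at 1.7 µm/px (a 4x high-content confocal objective).
* **Plate design**: 9-point dilution series, 8 replicate wells per
  condition, 8 DMSO control wells; the default series is 2-fold from
  50 nM (i.e. 50 … 0.195 nM).
* **Phenotype**: each well renders `n_organoids` spheres (default 8,
  radius 40 ± 6 µm) with a concentric lumen (default half the radius) and
  nuclei in the epithelial shell (default 12 per organoid).

The severity parameter `theta ∈ [0, 1]` operationalizes the drug-induced
phenotype: it linearly interpolates radius shrinkage (up to 40 %), lumen
collapse (up to 70 % of the lumen fraction), nucleus-count reduction (up to
50 %) and debris density. Doses map to `theta` through a Hill model
`theta = max_effect · d^h / (d^h + EC50^h)`, so the generator's EC50 is a
known ground truth for the downstream fit. The magnitudes of the per-axis
effects are free parameters of the simulation, not estimates of any real
biology; they were chosen once so that every feature family (size, lumen,
nuclei, debris) responds to dose.

Two rendering choices deserve comment:

* **Lumens in projection.** Analysis operates on maximum-intensity
  projections. The projection of a volumetrically hollow sphere has no dark
  interior (rays hit the shell top), so organoids are rendered with a
  *lateral* lumen hole per plane: the projected organoid is a bright disc
  with a dark concentric lumen whose area ratio is the square of the lumen
  fraction — which is how lumens appear in projected confocal stacks of
  epithelial organoids. Physically realistic optics are out of scope.
* **Out-of-focus organoids** (an optional fraction) are drawn as smooth,
  wide-edged discs confined to the outermost plane, giving the focus filter
  true positives without modelling a point-spread function.

Noise is Poisson shot noise on signal plus Gaussian background/read noise;
all randomness flows from one integer seed per well, derived
deterministically from the master seed, so identical parameters and seed
give bit-identical stacks.

## Segmentation

Both channels are projected by per-pixel maximum over z; the arg-max plane
of the actin channel is kept as a focus map. Organoid foreground comes from
Otsu thresholding of a blurred weighted channel sum (weights 0.7 actin /
0.3 nuclei); because Otsu will happily split a unimodal noise histogram,
the threshold is floored at median + 6 robust SDs so blank frames stay
empty. Objects below 250 px (a 27 µm-diameter disc at the default pixel
size) are discarded; the cutoff is deliberately below the smallest
drug-shrunken organoid and above debris, because a size filter that can
swallow fully-treated organoids censors the very phenotype the assay
measures and leaks an artificial organoid-count step into every summed
feature. Touching organoids are split by seeded region growing
(`EBImage::propagate`), with seeds from local maxima of the heavily
smoothed nuclei density (smoothing sigma ≈ organoid radius, default 20 px;
seeds closer than one organoid diameter, default 36 px, are merged — both
exposed as parameters for other magnifications). Labels are deterministic:
components are renumbered in row-major order of their first pixel.

Lumens are pixels below 40 % of their organoid's median actin intensity,
excluding candidates touching the organoid boundary and those below 25 px.
Nuclei are detected in the lightly smoothed nuclei projection with an
adaptive threshold (background median plus the larger of 8 robust SDs and
30 % of the bright-tail amplitude — the amplitude term stops neighbouring
nuclei from merging), split by watershed on the distance transform, and
assigned to the organoid containing their centroid.

The out-of-focus filter scores each organoid by the variance of the
Laplacian-of-Gaussian at its modal focus plane, normalized by squared mean
intensity. Smoothing before differentiation suppresses the shot-noise floor
that otherwise dominates the plain Laplacian. Scores are ratio-scale, so
the robust cut works on log scores: organoids more than 3 robust SDs below
the median log-score are removed — with a floor requiring at least ~5-fold
below median, because with a handful of organoids per well the MAD is
unstable and an additive rule either never fires or false-fires. Removal
iterates to a fixed point, making the filter idempotent; border-touching
organoids are always removed.

## Morphometry

Features are computed per organoid for three mask classes — organoid,
pooled lumens, pooled nuclei — and cover size (px and µm variants), shape
(solidity = area / convex-hull area; eccentricity from the pixel
covariance; form factor 4πA/P²; extent), topology (skeleton branch points
via Zhang–Suen thinning), relational quantities (lumen/organoid area
ratio, nuclei per unit area, lumen-centroid offset) and intensity
statistics (mean, SD, median, MAD and the 10/25/75/90 % quantiles ×
2 channels × object vs boundary shell). The intensity family deliberately
uses quantiles rather than per-object minima/maxima: extreme-value
statistics have artificially small replicate variance (the maximum over
many pixels is very stable), which lets them dominate any
variance-normalized feature ranking while carrying little graded dose
information.
Geometry that EBImage provides (contours for perimeters) is used rather
than re-derived; solidity, extent, branching and the intensity statistics
are computed here. Per-well aggregation (mean, median, SD, sum over
organoids, plus counts) expands the registry to 614 stable, uniquely named
columns — reproducing the dimensionality and character of a ~600-feature
high-content readout rather than any proprietary feature list.

Sentinel policy: a well-formed feature vector must exist for every
organoid, so counts and areas of absent substructures are 0 and a presence
flag is emitted. Intensity statistics of an absent substructure read the
*channel background* (frame median) rather than 0: a 0 sentinel makes
aggregated intensity features jump by a full background unit the moment the
last lumen drops below the detection threshold, creating artificial
late-responding "cliff" features that distort downstream dose-response
curves.

## Phenotypic scoring

Training compares two classes: vehicle-control wells and top-dose wells.
By default one feature space is trained per plate (organoid line) against
the pooled top doses of *all* screened compounds, and every compound's
wells are then scored in that shared space; per-compound training is
available (`train_scope = "compound"`) but was measurably less stable —
with only 16 training wells against 600 candidate features, the selected
set is luck-of-the-draw, and roughly one compound in three ended up scored
on features whose dose response never saturates or dips at the training
dose (a selection-overfit artefact). Pooling the compounds' top doses
triples the training set; for compounds acting through a shared mechanism
the high-dose phenotype is the same, which is exactly the regime the
screen targets. Features with zero variance are dropped; the rest are
standardized by the training mean and the **control-class SD**, floored at
0.2 × the total training SD. Two alternatives were rejected after
measurement: the total training SD absorbs the between-class shift
(shrinking a 5-SD planted effect to ~1.9 and destroying top-10 recovery of
planted features), and the pooled within-class SD is degenerate for
features that saturate at high dose (near-zero high-class variance inflates
single features into the distance by orders of magnitude). The floor exists
because the smallest of ~600 sample SDs estimated from 8 control wells is
tiny by chance; without it one unstable feature dominates every distance.

PCA is fitted on the standardized two-class matrix and features are ranked
by absolute loading on the component whose scores best separate the classes
(largest class-mean difference in pooled-SD units) — not unconditionally
PC1, which may capture plate variance; `strategy = "pc1"` is available.
The loading sign is fixed (largest entry positive) and ties break by
feature name, so selection is fully deterministic. Walking down the
ranking, features whose within-class (residual) correlation with an
already-accepted feature exceeds 0.9 are skipped: a registry this wide
contains many statistics of the same pixel set (a lumen's mean, median
and quantile intensities are near-identical measurements), and without
deduplication all ten slots can fill with one morphological axis, leaving
the distance undiversified and fragile if that axis misbehaves. The top
`k = 10` distinct features, their standardization parameters and the
standardized control centroid form the persisted model; every well's distance is the Euclidean
norm of its standardized deviation from that centroid.

One caveat is inherent to training on the scored wells themselves: with 600
candidate features and 16 training wells, the selected features separate
the two training classes even under the null, so top-dose wells of an
inert compound sit measurably farther from the control centroid than
held-out controls do. This selection bias does not produce spurious EC50s —
a dose trend that exists only at the single training dose has no
explanatory power along the series, and the R² rule rejects it — but the
absolute distance of the top dose should not be interpreted as effect size
without held-out calibration wells.

## Dose-response

The 4PL model is fitted on log10 dose to per-well points (each well
weighted equally) by bounded Levenberg–Marquardt (`minpack.lm::nlsLM`)
with a deterministic grid multistart: plateaus initialized from the
extreme doses; EC50 started from the interpolated half-maximal crossing
and from the dose-range quartiles; Hill slopes 0.7, 1 and 2; the basin
with the lowest residual sum of squares wins. `log10(EC50)` is bounded to
within one decade of the dose range; the Hill slope is positive with
direction carried by the sign of top − bottom, so rising distance curves
and falling viability curves use one parameterization. For distance
responses the pipeline additionally bounds the bottom plateau at zero —
a Euclidean distance cannot be negative, and the constraint removes
degenerate shallow-slope solutions when the lower plateau is weakly
sampled. "No fit" is
declared on convergence failure, dynamic range below twice the pooled
control SD, R² < 0.5 (strict), or EC50 at a bound — an operationalization
of the fit/no-fit decision that a screening report needs but that curve
fitting alone does not provide.

## Problem sizes used by the tests

Unit tests run on 96–192 px frames with 1–5 organoids. The end-to-end
acceptance checks simulate screens of three compounds with EC50s 2, 36 and
319 nM — the potencies of the tankyrase-inhibitor series the workflow was
designed around — on 192×192×25 stacks, 5 organoids per well, 9 four-fold
doses from 5000 nM, 8 replicates and 8 controls (224 wells per screen,
three seeded screens with per-compound median fold error, plus one
insensitive-line screen at 4 replicates). The 4-fold series is used for
these simulations because 2–319 nM spans 2.2 decades and both plateaus
must be sampled — a 2-fold series cannot bracket the set, and a half-log
series leaves the most potent compound's lower plateau unobserved; the
package default remains the 9-point 2-fold design. Segmentation recovery is measured on 50 independent wells.

## Known limitations

* 2D-projection analysis, not volumetric segmentation: organoids stacked
  in z would merge; the generator does not produce them.
* Spherical geometry only (no branched organoids); an irregular-shape
  extension would perturb the radial profile.
* No batch-effect correction across plates; training is per plate.
* No texture (Haralick) or learned features.
* Passing tests on the simulator demonstrate the pipeline's statistical
  machinery, not segmentation accuracy on real microscopy, which has
  artefacts (uneven illumination, Matrigel autofluorescence, debris
  clumps) the generator does not emulate.
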
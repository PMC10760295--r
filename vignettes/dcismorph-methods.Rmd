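---
title: "Morphometric profiling of DCIS: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric profiling of DCIS: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcismorph)
```

## The problem

Ductal carcinoma in situ (DCIS) is a pre-invasive breast lesion: tumor
cells confined to the milk ducts. Most DCIS never progresses to
invasive disease, yet nearly all patients are treated as if it would.
A quantitative description of duct morphology on routine H&E sections
— how large the ducts are, how densely they are populated by tumor
nuclei, how much of the fibroglandular stroma they occupy — is a
candidate, low-cost substrate for separating indolent from aggressive
lesions.

`dcismorph` implements the analysis side of that idea. It deliberately
does not segment images: segmentation (by a commercial AI platform, a
pathologist, or anything else) happens upstream and arrives here as an
object table (per-object class, area, perimeter, centroid, optional
polygon) or a class-encoded label mask. Everything downstream of
segmentation — QC filtering, morphometry, risk classification,
signatures, survival analysis, and segmentation validation — is in this
package, together with a synthetic-data generator that makes every
stage testable without patient data.

## Units and coordinate conventions

All geometry inside the package is in microns (lengths) and square
microns (areas); the ingestion layer is the only place pixels exist.
The default pixel pitch is 0.24 um/px, a typical 20x whole-slide scan.
Masks use 0-based pixel indices with the origin at the slide top-left
and y increasing downward; pixel `i` maps to the continuous coordinate
`(i + 0.5) * mpp` (pixel-center convention), which makes mask-to-object
round trips exact for synthetic renderings.

Perimeters of rasterized components use a four-direction Crofton
estimate (boundary crossings counted along rows, columns and both
diagonals, combined as `(pi/8) * (t_h + t_v + (t_d1 + t_d2)/sqrt(2))`).
Pixel-edge counting overestimates smooth boundaries by up to ~27%; the
Crofton estimator is asymptotically unbiased for disks (and ~1-2%
accurate at nucleus-to-duct scales), at the cost of a known ~6%
underestimate for axis-aligned rectangles. Polygon inputs always use
exact polygon formulas, never the raster estimate.

## QC filtering

Segmentation output contains false objects: hematoxylin debris read as
nuclei, stromal clefts read as ducts. The filter screens nuclear
objects on area, perimeter and circular shape factor (`4*pi*A/P^2`),
then duct objects on the number of surviving nuclei they contain, the
nuclear density (count per um^2 of duct area), and the mean over the
duct's nuclei of the distance to the nearest other nucleus in the same
duct. The rule *structure* is fixed; every threshold lives in
`filter_config()`. The shipped defaults (nuclear area 10-200 um^2,
perimeter 10-60 um, shape factor >= 0.3, >= 5 nuclei per duct, density
5e-4 to 2e-2 /um^2, mean minimal distance <= 30 um) are this package's
placeholders for plausible H&E nuclear geometry, not published
cutoffs; they must be reviewed against each segmentation platform's
error modes.

Evaluation order is fixed and documented so reports are deterministic:
nuclei first, then ducts; within a class, rules run in the order above
and an object is attributed to the first rule it fails. A duct with
fewer than two nuclei has no defined nearest-neighbor distance and is
always caught by the minimum-nuclei rule first. Nuclei whose duct is
removed — and nuclei with no containing duct at all — are removed too,
because every downstream measurement is of cells *within* ducts.
"Minimal nuclear distance" is center-to-center, not boundary-to-
boundary: centers are what segmentation platforms export reliably, and
the choice only shifts the threshold by roughly one nuclear diameter.

Filtering is idempotent, and tightening any single threshold can only
shrink the surviving set; both properties are enforced by tests.

## The 15 measurements and 120 slide variables

Per surviving duct the package computes: area, perimeter, circularity
(`4*pi*A/P^2`), elongation (major/minor axis of the ellipse of inertia
from exact polygon second moments), solidity (area over convex-hull
area), equivalent diameter (`sqrt(4A/pi)`), nuclei count, nuclear
density, mean and SD of nuclear area, mean nuclear circularity, mean
minimal nuclear distance, nuclear area fraction, centroid distance to
the nearest other duct, and the duct/stroma area ratio (duct area over
the slide's total stroma area). Mask-derived objects carry
pixel-moment elongation and pixel-hull solidity computed at ingestion,
so the measurement stage accepts either polygons or those precomputed
fields.

Each measurement's within-slide distribution is then summarized by 8
parameters — mean, median, SD, IQR (type-7 quantiles), moment skewness,
excess kurtosis, sum and max — giving 15 x 8 = 120 slide variables
named `<measurement>__<parameter>`. Both lists are config-driven; the
defaults carry the canonical 15 x 8 layout. The summed variables have
direct clinical readings: `duct_area__sum` is the slide's total DCIS
area, `nuclei_count__sum` the total number of tumor cells in ducts,
`duct_stroma_ratio__sum` the lesion burden relative to stroma
(`headline_variables()` exposes these aliases).

Degenerate-case conventions keep feature matrices complete for the
classifier rather than propagating missingness: single-duct slides get
SD = IQR = 0 and skewness = kurtosis = 0; a zero-variance vector has
skewness and kurtosis 0; `nearest_duct_distance` is undefined on a
single-duct slide, in which case its summaries are 0. These are
reporting conventions, not statistical estimates, and they are applied
identically everywhere.

Redundancy pruning computes all pairwise Spearman correlations across
slides and greedily dissolves every pair with |rho| above the
threshold (default 0.90), removing from the currently worst pair the
variable with the larger mean |rho| to all others (ties: the later
column goes). The retained count is data-dependent by design; the
procedure, not any particular count, is the contract. Correlations
involving zero-variance columns are undefined and treated as 0 — such
columns can never exceed the threshold and are reported as weak.

## Classifier: ridge logistic under nested cross-validation

The risk model is a logistic regression of event-by-horizon status
(5, 10 or 15 years) on the retained variables, ridge-penalized because
slides are few relative to variables and the variables are correlated.
The fit minimizes the negative Bernoulli log-likelihood plus
`(lambda/2)*||beta||^2` over features standardized to zero mean and
unit SD, intercept unpenalized, by Newton/IRLS with step halving,
converged at max gradient component <= 1e-8. Standardization
parameters live inside the model, so predictions are invariant to
affine rescaling of raw features.

Patients censored before the horizon without an event have unknown
horizon status and are excluded from that horizon's classification by
default (`censored_policy = "exclude"`); treating them as negatives is
available but mislabels some eventual cases.

Performance is estimated by 10 x 10 nested (double-loop)
cross-validation: stratified outer folds estimate out-of-sample AUC;
for each outer training set, stratified inner folds select the penalty
from 50 log-spaced values in [1e-4, 1e4] by mean inner-fold AUC
(largest lambda on ties, favoring the more regularized model); the
model refits on the outer-training set and scores the held-out fold.
No inner computation — standardization included — ever sees outer-test
rows, and a test corrupts a held-out fold to prove it. The headline
number is the median per-fold AUC; a percentile bootstrap (2000
resamples of the pooled out-of-fold predictions) gives a 95% CI. AUC
is the midrank Mann-Whitney statistic, ties counted one half.

## Signatures and survival

Univariate association of each standardized variable with the 5-level
event status (event in 0-5, 5-10, 10-15, >15 years, or never; ordered
earliest-to-none) uses proportional-odds logistic regression, which is
the coherent effect model for an ordered outcome reported as an odds
ratio; a linear model on the ordinal code is available behind a flag.
Under this ordering OR > 1 per SD means the variable shifts patients
toward later-or-no events (protective). Significance defaults to
alpha = 0.05 uncorrected — the screening step feeds a clustering, not a
discovery claim — with Benjamini-Hochberg available.

Slides are then clustered on the z-scored significant variables by
Ward-linkage agglomerative clustering (Euclidean distance,
`ward.D2`), cut at K = 4 by default; K is a visual-inspection choice in
this field and is exposed, not inferred. `stats::hclust` tie-breaking
by merge index makes the assignment deterministic given input order.

Signature prognosis is evaluated with the standard survival stack:
Kaplan-Meier cumulative incidence (1 - product-limit survival,
truncated at 15 years), the K-group log-rank test, and a multivariate
Cox model (Efron ties) of the event on the signature plus grade, ER,
HER2 and COX-2. The signature enters as a binary indicator of the
signature of interest versus the rest — matching the convention of
reporting a single hazard ratio for the low-risk group — with K-1
dummy coding available. Death and contralateral events are treated as
censoring; no competing-risks decomposition is attempted, and the
case-control matching of any particular source cohort is not modeled
(an unmatched analysis is what the package computes).

## Segmentation validation

`iou_score()` computes intersection-over-union of the DCIS class area
between a prediction and a pathologist annotation: pixel counting for
mask pairs, exact convex-polygon clipping (Sutherland-Hodgman, with a
bounding-box prefilter) for polygon sets. Polygons within each set
must be disjoint, as segmented ducts are. Non-convex polygons fall
back to rasterization with a warning — the exactness guarantee is for
convex inputs, which covers the generator's ellipses and typical
annotation rectangles; IOU when both sets are empty is defined as 1
with a warning. `iou_summary()` reports median and IQR with type-7
quantiles so results are bit-reproducible. `duct_count_correlation()`
is Pearson r with a Fisher-z 95% CI. Predicted counts are the
*filtered* duct counts by default, since filtering is part of the
detection pipeline being validated.

## The synthetic generator

`simulate_slide()` builds the geometry the analysis assumes: a square
stroma region, elliptical ducts placed without overlap (dart throwing
on centers with a conservative bounding-circle criterion), and
circular nuclei placed inside each duct by hard-core dart throwing
(candidates proposed in vectorized batches, accepted greedily in
proposal order, so a fixed seed reproduces the slide bit for bit under
R's default Mersenne-Twister generator). Every nucleus centroid is
inside its duct polygon and all within-duct center distances respect
the hard-core spacing, by construction and by test.

Default regime (per-slide): duct counts from a negative binomial
(size 0.9, mean 55) truncated to [1, 700], giving a median of ~36
ducts and a right tail past 400 — the count regime of screen-detected
DCIS series; duct areas lognormal with median 8000 um^2 (~100 um
equivalent diameter) and log-SD 0.9; elongation uniform on [1, 3];
nuclei of mean radius 4 um (area ~50 um^2) at 5e-3 nuclei/um^2 with an
8 um hard-core. The duct-count median and range are calibrated to the
published regime; the per-duct area and density distributions are this
package's modeling choices — no public per-duct distributions exist —
and are flagged as such in the parameter documentation. Stroma area
defaults to 8x the expected total duct area, which keeps packing
feasible across the count distribution.

`simulate_cohort()` attaches outcomes through a Weibull proportional-
hazards model whose log-hazard is linear in named, cohort-standardized
slide summaries (log total duct area, total nuclei, duct/stroma ratio,
duct count, mean duct area): `T = scale * (-log(U)/exp(risk))^(1/shape)`
with uniform censoring. Observed event times are binned at 5/10/15
years into the 5-level status; case/control equals event observed.
Clinicopathological covariates are drawn independently of morphometry
so their null behavior in multivariate models is known. Because the
link is proportional hazards on standardized summaries, the survival
stage can be asked to *recover* a planted hazard ratio — which is
exactly how the package's end-to-end tests work.

What the generator does not emulate: staining variation, segmentation
noise (beyond the optional `boundary_noise` roughening), spatially
clustered duct placement, correlated nucleus sizes within ducts, and
covariates confounded with morphometry. Passing tests therefore
demonstrate that the analysis machinery is correct and calibrated on
data satisfying its assumptions — not that any particular biological
effect size is reproducible on real cohorts.

## Problem sizes and numerical choices

The test-suite and acceptance-script simulations use cohorts of
100-200 patients, null feature matrices of 200 x 55, 1000-replicate
calibration loops, and n = 2000-5000 survival recoveries; these sizes
give stable Monte-Carlo estimates of every property checked (type-I
error bands of [0.03, 0.07] at alpha = 0.05, hazard-ratio recovery
within [0.44, 0.57] for a true 0.5) while keeping a full run in
minutes on one core. Ridge IRLS warm-starts along the penalty path
inside the inner CV loop; `solve()` on the (p+1) x (p+1) penalized
Hessian is the only linear algebra. Ties in lambda selection go to the
larger penalty; ties in pruning go to the later column; hierarchical
clustering inherits `hclust`'s documented merge-index tie-break.

## Known limitations

- The exact identities of the 15 measurements and 8 summary
  parameters in any particular upstream platform's export are not
  standardized; the sets here are the field's standard shape
  descriptors plus every quantity with a direct clinical reading, and
  both sets are editable configs.
- Exact polygon IOU requires convex polygons; concave annotations use
  the rasterized path.
- Proportional-odds fits can fail on separated data; such variables
  are flagged and skipped rather than reported with unstable effects.
- The Cox stage ignores matched sampling designs; estimates from
  nested case-control data are interpretable as unmatched
  approximations only.
- Slide-level visual QC (staining quality, section damage) is an input
  flag (`qc_pass`), not a computation: it is assessed by eye upstream.
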
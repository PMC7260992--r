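---
title: "Methods: quantifying the perceptual scission of draped shapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the perceptual scission of draped shapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When an opaque cloth is draped over a hidden rigid object, every visible
point belongs to one continuous surface — yet observers readily report which
ridges of that surface are caused by the hidden object pressing the cloth
("contact") and which by the cloth organizing itself into folds ("fabric").
`shapescission` implements the quantitative machinery for studying this
ability: statistics for two-cause painting annotations, ground-truth depth
analyses, a region-feature classifier, and scoring of two-layer depth
reconstructions, together with a synthetic stimulus and observer generator
so the whole pipeline can be validated against known causal ground truth.

```{r, eval = FALSE}
library(shapescission)
report <- runStudy(seed = 1)
```

# Annotation consistency: profligacy, decisiveness and the bootstrap null

For one participant's binary stroke maps $I_{fabric}, I_{contact}$ and a
stimulus mask with $N_{max}$ pixels,

$$P = \frac{N(I_{fabric} \cup I_{contact})}{N_{max}}, \qquad
  D = 1 - \frac{N(I_{fabric} \cap I_{contact})}{N_{max}}.$$

Profligacy $P$ measures willingness to mark; decisiveness $D$ measures how
mutually exclusive the two causal attributions are. The two are coupled:
sparse random maps rarely overlap, so high $D$ alone means nothing. $D$ is
therefore referred to a profligacy-matched null: each map's exact marked
count is re-placed uniformly at random ("white noise") within the mask,
independently per map, 10,000 times by default. The overlap of two
independent uniform subsets is hypergeometric, so the null has the analytic
mean $E[D] = 1 - N_f N_c / N_{max}^2$ — which the test suite uses as an
independent oracle while the implementation performs the literal placement.

One-tailed empirical p-values use the add-one convention
$p = (1 + \#\{D_{null} \ge D_{obs}\})/(1 + reps)$, since the scientific
prediction is directional (real observers are *more* decisive than chance).
Per-participant inference pools each participant's stimuli by averaging the
observed $D$ and averaging the null samples repetition-wise; the group test
is a one-sample $t$ on the per-participant differences. Pooling across
stimuli before testing is a design choice (the alternative, testing each
stimulus separately, is available by calling `participantSignificance`
per row of `consistencyScores`).

# Mean-map analyses

Mean maps are the per-pixel fraction of participants marking a cause.
Inter-observer agreement is the mean Pearson correlation over observer
pairs of the concatenated masked (fabric, contact) vectors; concatenating
both causes uses all information in one number (per-cause correlation is
available via `perCause = TRUE`). Cross-stimulus similarity is the Pearson
correlation of vectorized mean maps over the union of the two stimulus
masks, computed on raw (unsmoothed) maps — smoothing belongs only to the
segmentation stage. The similarity matrices are embedded by *classical*
(Torgerson) MDS on $d = 1 - r$ rather than a stress-minimizing variant:
classical scaling is deterministic up to rotation, which matters for
reproducibility. The response-weighted depth difference of a map $m$ is
$\sum_i m_i (z^{tex}_i - z^{base}_i) / \sum_i m_i$: when observers assign
causes correctly, contact maps concentrate where the layers touch and yield
smaller values than fabric maps.

# Region segmentation and features

Consistently-marked regions are extracted by a fixed pipeline: Gaussian
blur ($\sigma$ = 10 px), squaring (to emphasize consensus), per-map min-max
normalization to $[0,1]$, binarization at 0.3, binary opening with a
radius-1 disk (the 3×3 diamond), and 8-connected component labeling. Every
constant in that sentence is a default of `analysisConfig()`.

Each region yields 24 candidate features: area, best-fitting-ellipse
orientation (degrees in $(-90, 90]$ from the image x-axis, y up) and
eccentricity, perimeter (length of the traced boundary contour), solidity
(area over convex-hull area, hull taken over pixel corners so a filled
rectangle scores exactly 1), perimeter/area ratio, peripherality (centroid
distance from the image center), three depth features taken from the
ground-truth geometry (mean and SD of the *visible textile* depth within
the region, and the mean textile-minus-base gap), and 14 summaries of the
region's skeleton branch tree.

The skeleton is a pruned medial axis: Zhang–Suen thinning, reduction to a
minimal 8-connected pixel set, removal of terminal spurs shorter than 5 px,
decomposition into branches at junctions (adjacent junction pixels are
contracted into one junction), and rooting at the branch containing the
midpoint of the skeleton's longest geodesic path. Branch angles are
measured between principal-component tangent fits that skip the first 3
pixels around a junction, where the medial axis necessarily bends. This
construction replaces a Bayesian MAP-skeleton toolbox used historically for
the same summaries; since the classifier consumes only scalar branch-tree
statistics, any well-behaved pruned skeleton supports the same definitions.
Which surface "mean depth" refers to is an interpretive choice; the visible
textile surface is used here because it is the surface observers actually
see.

# Causal classification

Missing feature values are imputed with the feature's mean over all other
regions, and each feature is min-max normalized to $[0,1]$ *across all
regions of all stimuli* — deliberately reproducing the global-preprocessing
convention of the analysis this package models, including its mild
train/test leakage; `losoPredict(strict = TRUE)` recomputes both inside
each training fold instead. Features are ranked by the absolute difference
in class means of the normalized values (ties broken by the canonical
feature order), and the top 7 feed the SVM. A fixed reference subset
(`referenceSvmFeatures()`) is also exposed.

Classification is leave-one-stimulus-out: each stimulus's regions are
predicted by an SVM trained and tuned only on the other stimuli.
Hyperparameters are found by a seeded *randomized* search (50 draws) over
kernel {linear, polynomial of order 2–4, radial}, margin penalty
log-uniform in $[10^{-3}, 10^3]$, radial kernel scale log-uniform in the
same range, and standardization on/off, scored by stratified 5-fold CV
accuracy within the training regions. Randomized search replaces Bayesian
optimization: with 50 draws in a 4-dimensional space the two are
practically indistinguishable, and the randomized variant is exactly
reproducible from one integer seed. 5-fold CV is a choice the source
analysis leaves open.

# Two-layer depth profiles

Responses are piecewise-linear contours over control points, evaluated at
every column with constant extrapolation. Each participant's two contours
are normalized *jointly* (one shared offset and scale), preserving the
relative heights of the drapery and object responses; normalization is per
participant per raster line before averaging. Pearson correlation against
the masked ground-truth depth rows scores each layer; affine invariance of
Pearson's r guarantees the normalization cannot manufacture correlation.
P-values are reported per raster line without multiple-comparison
correction (apply `p.adjust` downstream if desired).

# The synthetic generator

The generator provides study conditions with known causal structure. Base
reliefs are seeded sums of Gaussian bumps (occasionally dimples) plus one
oriented ridge with random orientation and offset; distinct base identities
give essentially uncorrelated fields. Cloth is modeled as a
constrained-diffusion envelope: the relief plus a rectified-sinusoid fold
field, relaxed by repeated local averaging with the relief re-imposed as an
obstacle after each step. The fold field is weighted by the cloth's slack
$(1 - z_{base}/\max z_{base})^2$ — cloth stretched tight over high relief
cannot fold — which is what makes the membrane settle onto the relief at
its peaks and produce contact regions there (about 10% of the frame under
the defaults). This is a geometric stand-in, not a physical shell
simulation: the analyses need only the layer ordering, contact sparsity and
fold statistics, and no claim is made about physical fidelity (no
self-collision, no dynamics, no cast shadows in the rendering).

Markable features are ridge lines of the textile height field (negative
second-derivative operator at scale 2 px, suppressed within 2 px of the
border where the replicated boundary creates spurious maxima). Simulated
painters operate on whole ridge components — participants mark whole
ridges, and regions are the classifier's sample unit — with three dials:
the probability of marking a component at all (profligacy), the probability
of assigning it to the wrong cause (label noise), and a stroke-width
dilation. Simulated profile reporters see the textile directly but know
the hidden layer only at contact: their base percept blends the true
relief with a linear interpolation across non-contact spans, with
interpolation weight $\min(1, \sigma_{noise}/0.1)$ and 1.5× the textile's
noise. An ideal observer therefore converges to the truth on both layers,
while any realistic noise level makes the hidden layer strictly harder —
matching the qualitative phenomenon the profile experiment demonstrates.

## Default study conditions

3 base shapes × 4 drapings, 20 simulated painters, 12 simulated profile
reporters on 3 raster lines of one draping per base, rasters 256 × 256 px.
The raster size is set by the fixed segmentation constants, which are in
pixels: with $\sigma$ = 10 px blur a 256 px frame yields on the order of
146 segmented regions over the 12 stimuli — the granularity regime of the
human dataset this pipeline models — whereas much smaller frames let the
blur merge contact and fabric territory into single ambiguous regions.
Raster lines for the profile task are rows with maximal variance of the
layer gap among rows that actually cross both contact and non-contact
spans. The consistency false-positive control is run at 128 px: its
statistics are count ratios, independent of resolution, and the literal
mark-placement bootstrap scales with mask size.

# What passing tests do and do not show

The synthetic studies validate the *pipeline*: that the statistics are
computed as defined, that the bootstrap null is calibrated, that structure
present in the ground truth (contact clustering by base shape, larger
depth gaps under fabric markings, recoverable causal labels, a harder
hidden layer) is recovered, and that no information leaks across the
stimulus boundary in cross-validation. They do not show that human
observers behave like the simulated ones, and the generator deliberately
omits features of real data: anisotropic stroke shapes, spatially
correlated label noise, inter-observer criterion differences, rendering
photometrics, and real cloth mechanics. Headline numbers from the human
dataset (e.g. overall classification accuracy on deposited annotations)
can only be reproduced against that dataset.

# Numerical choices and degenerate inputs

* Layer-order validation tolerates violations up to 1% of a bundle's depth
  range — real scans are noisy; larger violations raise an error.
* Constant mean maps cannot be min-max normalized and segment to zero
  regions with a warning.
* Undefined features (single-pixel eccentricity, one-branch angle
  statistics, empty turn-angle sets) are recorded as `NA` and imputed at
  classification time; entirely-missing features are dropped with a
  warning.
* Equal tie scores in the hyperparameter search keep the first draw;
  ranking ties keep the canonical feature order — both for determinism.
* Every stochastic stage derives its own 32-bit seed from the master seed
  and a stage label, so stage results are independent of execution order.
* Depth rasters are stored normalized to $[0,1]$ in 32-bit float TIFF with
  the affine recovery constants in the JSON sidecar (round-trip error
  $\sim 10^{-10}$ of the depth range).

# Known limitations

The cloth model cannot produce overhangs, self-occlusion or double-layered
folds (it is a height field); the medial-axis skeleton is not the MAP
skeleton, so absolute skeleton statistics are not comparable across
skeletonization methods (relative class differences are what the
classifier uses); and the randomized hyperparameter search explores, but
does not model, its objective. The publicly deposited human dataset has its
own native layout, which this package does not parse; an import adapter
would be needed to run the accession-gated region count against it.
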
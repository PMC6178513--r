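---
title: "Methods: mass detection and sparse-curvelet LBP false-positive reduction"
author: "mammocad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mass detection and sparse-curvelet LBP false-positive reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mammocad)
```

This vignette documents the models and procedures the package implements,
the assumptions behind them, the tunable parameters with their defaults and
rationale, and the numerical and design choices made where the method left
room. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## The problem

A mass in a screening mammogram is a focal, roughly star-shaped region that
is brighter than its surroundings. Detection pipelines first *segment*
candidate regions with high sensitivity (accepting many false positives),
then *reject* false positives with a classifier operating on features of
each candidate patch. The package implements both stages plus the feature
descriptor that connects them.

## Contrast enhancement by entropy-maximising fusion

Mammograms are low-dose x-ray images with poor global contrast. CLAHE
(tile-wise histogram equalisation with a clip limit) raises local contrast
but can amplify noise in flat regions. The fusion rule keeps CLAHE output
only where it adds information: for each pixel, the local Shannon entropy

$$\mathrm{ENT} = -\sum_{k=0}^{255} p_k \log_2 p_k$$

of the 256-bin intensity histogram in a $5\times5$ window is computed for
both the original image and its CLAHE version; the output pixel is copied
from whichever source has the larger entropy, with ties going to the
original (the conservative choice — it avoids adopting amplified noise
where the two sources are equally informative). Borders are handled by
symmetric reflection and $0\log 0 := 0$, so every entropy value lies in
$[0, \log_2 25]$ bits.

Parameters: `clip_limit` (fraction of the tile pixel count, default 0.01)
and `tiles` ($8\times8$) follow common CLAHE practice; the entropy
`window` is 5. The fusion rule operates on pixels, not on a multiresolution
split; it is the simplest rule consistent with a per-pixel
maximum-entropy criterion, and the entropy map itself is exposed
(`local_entropy()`) so alternatives can be built on top.

Pectoral-muscle suppression is a deliberately simple, optional stage: in
the top corner on the pectoral side (top 40 % of rows, chest-wall-side
50 % of columns) the strongest horizontal edge per row is located, a
straight line is fitted to those edge points by least squares, and pixels
between the chest wall and the line are zeroed. Two guards keep it honest:
rows contribute only if their edge strength exceeds `min_gradient` (0.1),
and the cut is applied only if the region it would remove is at least
`intensity_margin` (0.05) brighter than the remaining tissue in that corner
— the pectoral muscle is the brightest structure there, so a corner without
one fails the test and the image is returned unchanged with a warning. The
comparison excludes pixels below 0.1 so the dark off-breast background
cannot skew the reference mean. This stage makes no attempt to model
curved pectoral boundaries; it can be disabled (`pectoral = "off"`, the
default in `segment_masses()`).

## SOM segmentation and candidate filtering

Every pixel is represented by the 9 intensities of its $3\times3$
neighbourhood (centre included — 9 features require the full window),
borders reflected. A self-organising map with $M = 4$ nodes is trained
online: for a sampled feature $f$, the best-matching unit is
$c = \arg\min_i \lVert f - W_i\rVert$ and all nodes move by

$$W_i \leftarrow W_i + \eta(t)\,
  \exp\!\left(-\frac{\lVert m_c - m_i\rVert^2}{2\sigma^2(t)}\right)(f - W_i).$$

Choices the method leaves open, fixed here once:

* **Topology** — a $2\times2$ grid with unit spacing, the smallest grid on
  which the spatial kernel is meaningful.
* **Schedule** — $\eta(t)$ and $\sigma(t)$ decay exponentially from
  $\eta_0 = 0.5$, $\sigma_0 = 1$ to 1 % of their start over the training
  run (default 20,000 sampled pixels; on large images features are
  subsampled to a 20,000 cap before training).
* **Initialisation** — weights uniform in $[0,1]$, fixed seed; intensities
  are already in $[0,1]$ so no further scaling is applied.

The *cluster of interest* is the cluster with the highest mean image
intensity (masses are bright). Its 8-connected components are filtered by
the pixel-level threshold (PLT): only components whose pixel count lies in
`[min_pixels, max_pixels]` survive. The defaults 450–31,500 px are the
window appropriate for 1024 × 1024 screening images; the window scales
with image resolution and should be set per dataset. Each survivor is
cropped to its tight bounding box with out-of-mask pixels set exactly to
zero; patches below $25\times22$ (the smallest mass ROI the descriptor
supports) are zero-padded symmetrically to that minimum.

## The curvelet frame

The descriptor needs directional subbands of each ROI. The package
implements a fast discrete curvelet transform as a tight frame on the 2-D
frequency plane: a low-pass square corona (Meyer-type raised-cosine radial
window in the $L^\infty$ radius, transition over $[{1}/{4}, {1}/{2}]$ of
the Nyquist square) plus one detail corona divided into 32 half-wedges by
raised-cosine angular windows with 50 % overlap. Antipodal half-wedge
pairs are combined so each of the 16 detail windows is symmetric under
frequency negation, which makes all subband coefficients real. Windows are
constructed so that the sum of their squares is exactly 1 at every grid
frequency; applying each window in frequency, inverse-transforming, and
re-applying on the way back is then the identity, and coefficient energy
equals image energy (Parseval ratio 1). The acceptance script verifies a
round-trip relative error at machine precision over 50 random sizes.

Numerical choices:

* Subbands are kept at the source resolution rather than wrapped into
  decimated rectangles; the LBP stage is resolution-agnostic and the
  full-resolution form is exactly tight, at the cost of redundancy
  (17 subbands at full size). ROIs here are small, so the memory cost is
  negligible.
* Odd image dimensions need no padding: an odd frequency grid has no
  Nyquist self-alias, so the same construction applies. On even grids the
  Nyquist row/column *is* self-aliased and the raw angle-based windows
  would be asymmetric there; symmetrising the squared windows under
  index negation restores exactness without breaking the partition.
* Wedge order is deterministic: coarse first, then wedges
  counter-clockwise from angle 0 (`subband_list()`), so feature vectors
  are comparable across ROIs.

## Sparse uniform LBP

The descriptor's premise is that a sparse ROI (exact-zero background)
keeps the mass *shape* available to texture analysis: a sliding
$3\times3$ lookup table marks a window position **foreground** iff it
covers more than 2 nonzero values, and uniform LBP codes are computed only
there. The boundary case of exactly 2 nonzeros is treated as background —
the foreground rule is strictly "more than 2". The full window takes part
in each comparison (background neighbours included), so codes at the mass
boundary still see the shape edge.

LBP codes use the standard convention: bit $p$ is set iff the $p$-th ring
neighbour (counter-clockwise from the east neighbour, $R=1$, the 8 integer
neighbours — exact at this radius, no interpolation) is $\ge$ the centre.
A code is *uniform* iff its circular bit sequence has at most two 0/1
transitions; exactly $P(P-1)+2 = 58$ such patterns exist for $P=8$.
Non-uniform codes are discarded rather than pooled into a 59th bin, so
each subband contributes exactly 58 features and the ROI descriptor is
$17 \times 58 = 986$ long. Histograms are normalised by the number of
retained (foreground *and* uniform) codes so ROIs of different sizes are
comparable; a band with no retained code yields an all-zero histogram.
In the degenerate case where foreground windows exist but every one is
non-uniform, the histogram is likewise all-zero — normalising by retained
codes is the only convention that keeps the bins a probability vector.

**Nonzero tolerance.** In the spatial domain the background is exactly
zero and `tol = 0` is used. Curvelet subbands of a masked ROI, however,
are not exactly zero off-support: the frequency windows leak at roughly
$10^{-3}$–$10^{-2}$ of each band's maximum. A tolerance far below that
floor would mark every coefficient nonzero and reduce sparse LBP to dense
LBP. The per-band threshold is therefore *relative*,
`tol = tol_rel * max(|band|)` with `tol_rel = 0.01` by default — above the
leakage floor, below typical on-support magnitudes. `describe_roi()`
attaches a per-band table of window and coefficient counts before/after
the foreground rule, reporting both the rejected-window and
rejected-coefficient reductions, since both are meaningful summaries of
the selection.

## Classification and evaluation

Three scorers share one interface. The ANN is a single-hidden-layer
logistic network (986 inputs, 20 hidden units by default, one logistic
output), trained by full-batch Adam on cross-entropy with a small $L^2$
penalty; the provided training rows are split in half into train and
validation parts — inside one fold of 3-fold cross-validation this yields
the one-third/one-third/one-third train/validation/test division — and
training stops early when validation loss stops improving (checked every
25 epochs, patience 6, 800 epoch cap), keeping the best weights.
Full-batch gradients are the right regime here: a fold holds at most a few
hundred samples, so an epoch is a single pair of matrix products. The SVM
is an RBF machine (`e1071`), scored by oriented decision values with
operating threshold 0; KNN scores by the fraction of positive neighbours
among $k = 5$, threshold 0.5. All thresholds and hyperparameters are
arguments.

Cross-validation is **group-aware**: all samples sharing a group id (in
particular augmented copies of one ROI — factor 2 adds a horizontal flip,
factor 4 also a vertical flip and a 180° rotation, all of which preserve
the sparse support exactly) are dealt into the same fold, per-class group
counts across folds differing by at most one. This is stricter than
evaluating with augmented copies scattered across folds, and is the
honest default; the splitter is a separate function, so a leakier split
can be constructed deliberately if comparison demands it. Reported
metrics: per-fold and averaged sensitivity, specificity, accuracy
(the final accuracy is the mean of fold accuracies), and AUC by
trapezoidal integration of the ROC over all score thresholds — verified
in the tests against the normalised Mann–Whitney statistic. Lesion-level
detection is summarised by TPR = detected lesions / total lesions and
FPPI = false-positive regions / images.

## What the phantoms emulate — and what they do not

`make_phantom()` produces a breast half-disc (chest wall at one edge) with
an intensity ramp brightest at the chest wall, correlated Gaussian texture
(correlation length ~8 px — enough structure for CLAHE and the entropy
fusion to act on), an optional brighter pectoral wedge, and bright masses
with star-perturbed borders
$r(\theta) = r_0\,(1 + \text{irr}\sum_{k=2}^{5} a_k\cos(k\theta+\phi_k))$,
a smooth radial intensity bump (contrast 0.4 by default, additive noise
$\sigma = 0.02$), pairwise disjoint and fully inside the breast. Mass
radii default to 15–32 px so pixel counts fall inside the default PLT
window. `make_labeled_roi_set()` mimics the two candidate classes the
false-positive-reduction stage must separate: positives are high-contrast
irregular bright shapes, negatives low-contrast texture patches with the
same sparse support structure.

The phantoms deliberately do **not** model calcification clusters,
spiculated margins, compression artefacts, scanner noise, or the tissue
superposition that makes real mammograms hard. Passing tests on phantoms
therefore demonstrates that the pipeline's machinery is correct and that
the descriptor separates shape-plus-contrast classes under controlled
conditions — not that clinical performance would match. The pixel-count
thresholds, contrast levels and noise used in the test suite and
acceptance script (192 × 192 phantoms, two masses each; 100 + 100 ROIs
per run, 5 repetitions) were chosen as desk-scale study conditions, small
enough to run in seconds yet large enough for stable rates.

## Degenerate inputs and tie-breaks

* Entropy fusion ties select the original pixel; a constant image passes
  through CLAHE and fusion unchanged.
* SOM best-matching-unit ties break toward the lowest node index, so
  assignment is deterministic; a constant image maps to a single cluster.
* `breast_mask()` refuses all-zero images; candidate selection may return
  an empty list (no region in the PLT window) without error.
* An all-zero band yields an all-zero histogram (`n_foreground = 0`), and
  a zero ROI a zero descriptor; the relative tolerance degrades to 0 for
  an all-zero band rather than propagating `NaN`.
* KNN distance ties are resolved by a seeded draw, keeping repeated runs
  identical.

## Known limitations

* The pectoral-suppression stage assumes a straight boundary and a single
  bright wedge; curved or low-contrast pectoral muscles will be left in
  place (by design, with a warning).
* The SOM cluster-of-interest rule (highest mean intensity) assumes masses
  are the brightest tissue class after enhancement; dense glandular tissue
  brighter than the mass would defeat it.
* The curvelet implementation targets the two-scale, 16-orientation
  setting the descriptor needs; it is not a general multi-scale curvelet
  library.
* Descriptor histograms discard non-uniform patterns entirely; on bands
  where most foreground codes are non-uniform the histogram support is
  thin.
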
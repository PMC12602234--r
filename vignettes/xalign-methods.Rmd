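---
title: "Scoring explanation fidelity with XAlign: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring explanation fidelity with XAlign: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xalign)
library(dplyr)
```

## The problem

Saliency methods (Grad-CAM, LIME, SHAP, or a network's own explanation
head) attach a nonnegative relevance value to every pixel of a medical
image. Whether such a map is *clinically useful* depends on whether the
relevance concentrates on the lesion the expert annotated, conforms to its
boundary, and avoids spraying attribution across irrelevant anatomy. This
package quantifies those three properties against a binary expert mask
$G$ and combines them into a single score.

## The score

For a saliency map $X$ with pixel values $X_i \ge 0$ and a mask $G$:

* **Weighted relevance overlap** — the fraction of total relevance inside
  the lesion,
  $\mathrm{WRO} = \sum_{i \in G} X_i \big/ \sum_i X_i$.
* **Boundary agreement** — one minus the Hausdorff distance between the
  contour of $G$ and the contour of the binarised explanation, normalised
  by the image's larger dimension:
  $\mathrm{BAS} = 1 - \mathrm{HD}(\partial G, \partial X) / \max(H, W)$.
* **Dispersion penalty** — the relevance fraction outside the lesion
  (optionally outside a disc-dilated lesion),
  $\mathrm{DP} = \sum_{i \notin G_d} X_i \big/ \sum_i X_i$.

The combined score is
$\alpha\,\mathrm{WRO} + \beta\,\mathrm{BAS} - \gamma\,\mathrm{DP}$,
clamped to $[0,1]$, with default weights $(\alpha,\beta,\gamma) =
(0.5, 0.4, 0.1)$ applied uniformly — no per-dataset tuning.

Three design points deserve explanation because the defining formulas do
not force them:

* **Soft vs binary inputs.** WRO and DP consume the *graded* map — they
  are statements about attribution mass, and binarising first would
  discard exactly the information they weigh. BAS needs a region to take
  a contour from, so it consumes the map after min-max normalisation and
  thresholding (default: fixed $T = 0.5$). The binarisation policy used
  for BAS is recorded in every result object.
* **Clamping.** The raw combination can leave $[0,1]$ (a fully off-target
  map scores $-\gamma$). Scores are reported post-clamp, and the clamp is
  applied *before* averaging in all grids, so dataset-level summaries
  aggregate the same quantity a single-pair call reports. The raw value
  is preserved alongside.
* **Hausdorff variant.** The default is the classical symmetric max
  (sup-min both ways), which makes BAS the normalised inverse Hausdorff
  distance literally. A tolerance band (slack subtracted from the
  distance) and an average-of-directed-means variant are exposed as
  options but default to off/0, so that default results reproduce the
  defining formulas rather than a softened reading. An *empty* binarised
  explanation has no contour; it receives the sentinel BAS $= 0$ instead
  of an error so parameter sweeps that empty a map at high thresholds can
  continue.

Other conventions: boundaries are 4-connectivity inner boundaries (a
foreground pixel with a background or off-image 4-neighbour); dilation
uses a Euclidean disc; `max_dim` is $\max(H, W)$; multi-component masks
contribute all boundary pixels jointly; weights are validated nonnegative
and a warning (not renormalisation) is issued when they do not sum to 1.

## The explanation head

The native explanation pipeline mirrors how an activation stack
$A \in \mathbb{R}^{C \times h \times w}$ from a final convolutional block
becomes a heatmap: per-channel means $\mu_c$, selection of the top $k\%$
channels (default $k = 20$), pixelwise summation, min-max normalisation
with an $\varepsilon$ guard, thresholding, and nearest-neighbour
upscaling to the display resolution.

Numerical choices the formulas leave open:

* The channel count is `max(1, round_half_up(k * C / 100))`; half-up
  rounding keeps the count stable across platforms (R's `round()` rounds
  half to even), and the floor of 1 keeps $C = 1$ stacks usable. Ties in
  channel means resolve to the lower channel index.
* $\varepsilon = 10^{-8}$ in the min-max step: small enough to be
  invisible at float precision on any non-constant map, and it sends
  constant maps to all-zeros rather than dividing by zero.
* Percentile thresholds interpolate linearly between order statistics
  (`quantile(..., type = 7)`, R's default).
* Otsu's threshold is computed on a 256-bin histogram of the normalised
  map; the chosen threshold is the bin edge maximising between-class
  variance, ties resolved to the lowest edge, and the comparator is
  $\ge$. A map whose values occupy a single bin has no valid split and
  returns threshold 0 (everything foreground).
* Upscaling a *binary* map uses nearest-neighbour sampling — bilinear
  interpolation would manufacture intermediate values and break binarity.

## The spiking simulator

The forward integrate-and-fire dynamics that motivate the sparsity
argument are simulated directly: $V(t{+}1) = \beta V(t) + W\!\cdot\!f$,
a spike where the pre-reset potential reaches $V_{th}$ (comparator
$\ge$), and a hard reset to zero. Defaults follow the published
operating point: $\beta = 0.9$, $V_{th} = 1.0$, $T = 10$ steps, with the
piecewise-linear surrogate $\max(0, 1 - |V - V_{th}|)$ available for
inspection. The recorded potential at a spike step is the *post-reset*
value (exactly 0); the pre-reset value is recoverable from the previous
state and the drive. Static inputs are re-presented identically at each
step, which is what makes the geometric-series closed form
$V(t) = I(1-\beta^t)/(1-\beta)$ an exact subthreshold check. Training,
synaptic-weight learning and classification heads are out of scope: the
drive vector is an input.

## What the phantoms emulate — and what they do not

There is no clinical data in this package. The phantom generator draws
elliptical lesion masks (semi-axes 12.5–21% of the frame's short side,
random rotation, centre jitter of 1/12 frame) and saliency maps in five
quality tiers that mimic the qualitative behaviours reported for real
explanation methods:

* `aligned` — mass on the lesion with a 3-pixel exponential skirt
  (≥ 95% of mass inside the mask at zero noise);
* `overreach` — uniform mass on the lesion dilated by ~10% of its
  equivalent diameter (at least 2 px): boundary spillover;
* `diffuse` — a broad Gaussian (scale 1.5× the equivalent lesion radius)
  centred on the lesion centroid;
* `scattered` — three compact off-lesion Gaussian blobs plus a minor
  (sub-threshold) on-lesion component;
* `off_target` — a single blob with support exactly disjoint from the
  lesion and a 3 px guard band.

All tiers add zero-truncated Gaussian noise (default SD 0.05 relative to
a unit-peak signal — visible but not tier-flipping) and are deterministic
given a seed; a dataset derives per-item seeds from one root seed
(default 42) so tiers stay paired on identical masks.

By construction the tiers order `aligned > overreach > diffuse >
scattered` in mean score, and the tests verify that this ordering is
invariant across the five-triple weight grid and the $k \times T$
parameter grid. That is a check of the *metric's* discriminative
behaviour and stability, not evidence about any particular network:
phantoms have none of ultrasound speckle, MRI intensity inhomogeneity,
multi-focal lesions, or annotation ambiguity. Passing these tests shows
the machinery measures what it claims to measure on inputs with known
ground truth; clinical conclusions still require clinical maps.

Problem sizes are the package's own defaults chosen to keep a full
evaluation interactive on a laptop: 96×96 frames, 30 phantoms per tier
for weight grids, 8 masks × 4 tiers × 20-channel stacks for parameter
grids, 50 pairs for the paired test. All scale up by argument.

## Statistics

Dataset-level summaries are mean ± sample (n−1) SD per method; a
singleton group reports SD 0 by convention. Paired comparisons use the
Wilcoxon signed-rank test implemented from first principles: zero
differences dropped (Wilcoxon's reduction — the Pratt alternative is
documented but not used), midranks for tied absolute differences, and
$W^+$ the sum of positive-difference ranks. For $n_\mathrm{eff} \le 25$
the two-sided p-value is exact — $2\min(P(W^+\le w), P(W^+\ge w))$
capped at 1 under the full $2^n$ sign-assignment null, computed by
convolution over doubled midranks (midranks are half-integers, so
doubling makes the distribution integer-supported; the result is
identical to explicit enumeration, which the tests verify). Beyond the
cutoff a normal approximation with tie correction and a 0.5 continuity
correction is used; at $n = 25$ the two agree within 0.01 on tie-free
data. Weight-sensitivity grids never rescore pixels: the score is linear
in the weights, so stored (WRO, BAS, DP) triples are recombined exactly.

Majority voting (slice-to-patient aggregation) takes the strict
majority; an exact tie goes to the side with the higher mean per-slice
score when scores are available, else to the positive label — the tie
policy is a package convention, stated rather than inherited.

## A worked example

```{r example}
mask <- make_lesion_mask(c(96, 96), semi_axes = c(16, 12))
sal <- make_saliency_phantom(mask, "overreach", noise = 0.05, seed = 1)
xalign(sal, mask)

ds <- phantom_dataset(10, seed = 42)
ds |> score_saliency() |> aggregate_scores(group = "tier")
```

## Known limitations

* BAS is a contour statistic: it inherits the Hausdorff distance's
  sensitivity to single outlying foreground pixels in the binarised map
  (the average variant and tolerance band soften this, at the cost of
  leaving the literal defining formula).
* WRO/DP ignore *where inside* the lesion mass sits; a map hugging one
  corner of a large lesion scores the same overlap as a centred one.
* The score presumes a non-empty mask and a map with positive mass;
  images without lesions are outside its domain (scoring such pairs
  raises an explicit error rather than returning a number).
* Phantom realism is deliberately minimal (see above).
* Comparators such as IoU, Dice or the Pointing Game are not provided;
  the package scores one metric family well rather than many shallowly.
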
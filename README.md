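# xalign

Explanation-fidelity scoring for medical-image saliency maps.

Classifiers for tumour detection in MRI and ultrasound are routinely
"explained" with saliency maps (Grad-CAM, LIME, SHAP, or a network's own
explanation head). Whether such a map is clinically trustworthy is a
quantitative question: does the attributed relevance concentrate inside the
expert-annotated lesion, follow its boundary, and stay off irrelevant
anatomy? `xalign` answers it with a single interpretable score and the
evaluation machinery around it, for researchers who need to compare
explanation methods against ground-truth masks — real or synthetic.

## The score

For a nonnegative saliency map $X$ and a binary expert mask $G$ on an
$H \times W$ image:

- **WRO** (weighted relevance overlap) $= \sum_{i \in G} X_i / \sum_i X_i$
- **BAS** (boundary agreement) $= 1 - \mathrm{HD}(\partial G, \partial X)/\max(H,W)$,
  with $\mathrm{HD}$ the symmetric Hausdorff distance between contours of
  the mask and of the binarised map
- **DP** (dispersion penalty) $= \sum_{i \notin G} X_i / \sum_i X_i$

$$\mathrm{XAlign} = \mathrm{clamp}_{[0,1]}\left(\alpha\,\mathrm{WRO} + \beta\,\mathrm{BAS} - \gamma\,\mathrm{DP}\right),
\qquad (\alpha,\beta,\gamma) = (0.5,\ 0.4,\ 0.1).$$

The package also provides:

- the **explanation-head pipeline** that turns a $C$-channel convolutional
  activation stack into a heatmap (top-$k$% channel selection by mean
  activation, pixelwise aggregation, min–max normalisation, fixed /
  percentile / Otsu binarisation, nearest-neighbour upscaling);
- a forward **integrate-and-fire simulator** ($V(t{+}1)=\beta V(t)+I$, hard
  reset, $\ge$ threshold, piecewise-linear surrogate gradient) with spike
  sparsity profiling;
- a seeded **phantom generator** producing lesion masks and saliency maps of
  five controlled quality tiers (`aligned`, `overreach`, `diffuse`,
  `scattered`, `off_target`);
- an **evaluation harness**: batch scoring from directories, mean ± SD
  aggregation, exact paired Wilcoxon signed-rank tests, weight- and
  parameter-sensitivity grids, majority voting, JSON run manifests, and a
  command-line front end.

## A worked example

```r
library(xalign)
library(dplyr)

mask <- make_lesion_mask(c(96, 96), semi_axes = c(16, 12))
sal  <- make_saliency_phantom(mask, "overreach", noise = 0.05, seed = 1)
xalign(sal, mask)
#> <xalign_result>
#>   WRO 0.5776 | BAS 0.9688 | DP 0.4224
#>   weights (0.50, 0.40, 0.10)  raw 0.6340  score 0.6340
```

The overreaching map covers the lesion (its contour sits close to the
truth, BAS 0.97) but spends 42% of its mass outside it, so overlap is
mediocre and the combined score lands mid-range — exactly the boundary-
spillover signature the tier emulates. Scoring a whole phantom dataset
and summarising per tier:

```r
phantom_dataset(30, seed = 42) |>
  score_saliency() |>
  aggregate_scores(group = "tier")
#> # A tibble: 4 × 4
#>   tier          n  mean      sd
#> 1 aligned      30 0.792 0.0196
#> 2 diffuse      30 0.364 0.00476
#> 3 overreach    30 0.659 0.0115
#> 4 scattered    30 0.245 0.0373
```

Mean scores order the tiers `aligned > overreach > diffuse > scattered`,
and `weight_sensitivity_grid()` / `param_sensitivity_grid()` verify that
this ranking is invariant across weight triples and across the
explanation head's $k \times T$ grid. A paired comparison:

```r
sc <- phantom_dataset(30, tiers = c("aligned", "scattered"), seed = 42) |>
  score_saliency()
wilcoxon_signed_rank(sc$score[sc$tier == "aligned"],
                     sc$score[sc$tier == "scattered"])
#> Wilcoxon signed-rank test (approximate): W+ = 465, n = 30, p = 1.825e-06
```

Result objects have broom-style `tidy()` / `glance()` methods and
`ggplot2::autoplot()` methods; `vignettes/xalign-methods.Rmd` documents
the model, conventions and design decisions.

## Command line

```sh
Rscript inst/cli/xalign.R phantoms --n 30 --seed 42 --out data/
Rscript inst/cli/xalign.R score --saliency data/saliency_aligned \
    --masks data/mask --out aligned.csv
Rscript inst/cli/xalign.R compare --a aligned.csv --b scattered.csv
```

Every run writes a JSON manifest (version, seed, options, input digests);
identical seeds and configs reproduce outputs byte-for-byte.

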
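# msbslda

Unsupervised segmentation of plant images — and of general scenes — with
spatial topic models, for plant-phenotyping researchers who need plant
masks, leaf instances and leaf counts from RGB images without training
labels.

The core method, MSBS-LDA (Mean-shift Bandwidth Searching LDA), treats an
image as a text corpus: filter-bank patch descriptors quantized against a
K-means dictionary are the *words*, spatial groupings of patches are the
*documents*, and a latent Dirichlet allocation model with K topics, fitted
by collapsed Gibbs sampling from

```
p(z_j = k | z_-j, w, d)  ∝  (n_w|k + β_w) / Σ_w (n_w|k + β_w) · (n_k|d + α_k)
```

labels every pixel with its max-posterior topic. Documents come from
joint spatial–range mean-shift: pixels climb the kernel density of the
[p_x, p_y, l, u, v] cloud (Epanechnikov kernel, so each step is a plain
window mean) and the converged modes are clustered into documents. The
spatial bandwidth is set from word-frequency statistics,
`h_s = 10^C · w_fren⁽¹⁾ / N` with C in [1.41, 1.67], and the range
bandwidth h_r is searched downward (step 1, step 0.5 below 10) until the
mean pairwise LUV distance between the K class means,
`ΔĒ = 2 Σ_{i<j} ||c̄_i − c̄_j|| / (K(K−1))`, is stable across three
consecutive iterations (tolerance 1), with a first-large-jump fallback.
Rectangular (non-overlapping and overlapping) and SLIC super-pixel
document baselines are included, as is the plant pipeline — foreground
extraction, R−B fruit removal, illumination diagnosis (α′ rate) with
homomorphic correction, strong-edge subtraction, distance-map centroids
and marker-controlled watershed — and the evaluation suite: SA/OR/UR,
foreground-background Dice, (symmetric) best Dice, difference in count,
modified Hausdorff distance.

Everything is testable offline: generators produce blob scenes, synthetic
plants (overlapping leaf ellipses, fruit disks, moss, illumination ramps)
and LDA corpora with known parameters.

## Worked example

Scene segmentation on a synthetic three-region image with disease-like
speckles:

```r
library(msbslda)

scene  <- make_blob_scene(128, 128, 3, noise_sd = 8, lesion_frac = 0.1, seed = 1)
labels <- msbs_segment(scene$image, K = 3, seed = 1)
attr(labels, "trace")
#>   h_r n_docs  delta_e
#> 1  40     13 149.6672
#> 2  39     13 149.6673
#> 3  38     13 149.6678
attr(labels, "stop_reason")   # "three-stable"
round(sa_or_ur(scene$gt_regions, labels), 4)
#>     SA     OR     UR
#> 0.9847 0.0130 0.0153
```

The trace shows the bandwidth search: at each h_r the number of mean-shift
documents and the class separation ΔĒ; here the separation is stable from
the start, the search stops after three iterations, and the returned map
reaches 98.5% segmentation accuracy with ~1.5% over- and
under-segmentation against the known partition.

Leaf instance segmentation on a synthetic plant with two fruits:

```r
plant <- make_plant_scene(128, 128, 4, fruit_count = 2, seed = 9)
res   <- segment_leaves(plant$image, K = 2, seed = 9)
n_labels(res$instances)                       # 4 leaves found
res$illumination$alpha_prime                  # 0.769 -> "uneven", corrected
dic(res$instances, plant$gt_leaves)
#>    DiC absDiC
#>      0      0
symmetric_best_dice(res$instances, plant$gt_leaves)   # 0.858
dice(plant$gt_regions == 2, res$leaf_mask)            # 0.931 plant-mask Dice
```

All four leaves are recovered (difference in count 0), the instance
overlap (symmetric best Dice) is 0.86, and the extracted plant mask
matches the true leaf mask with Dice 0.93.

A command-line interface wraps the same functions
(`inst/cli/msbslda simulate | dict | segment | meanshift | plant | leaves
| eval`); every artifact-producing run writes a JSON manifest from which
it can be reproduced byte-for-byte. If you have annotated images of your
own (for example phenotyping benchmarks), `eval --mode semantic|instance`
scores prediction maps against ground truth and emits per-image and
mean (standard deviation) tables.

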
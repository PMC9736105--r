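---
title: "Unsupervised fruit maturity grading: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised fruit maturity grading: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripecluster)
```

## The problem

Oil-tea (*Camellia oleifera*) fruit must be harvested inside a narrow maturity
window: seed oil content peaks at the ripe stage and declines once the fruit
overripens, but no visual grading standard exists and the chemical assays that
define maturity destroy the sample. `ripecluster` implements an unsupervised
route: fruit photographs are clustered into maturity stages directly from
convolutional-network features, without any labels, and the resulting cluster
assignments are used as surrogate ("pseudo") labels to train a classifier that
can then identify the maturity of new fruit.

## The model

Two objectives alternate. Grading minimizes the K-Means objective over image
features,

$$\min_{C \in \mathbb{R}^{d\times k}} \frac{1}{N}\sum_{i=1}^{N}
  \min_{y_i \in \{0,1\}^k,\; y_i^\top \mathbf{1}=1}
  \lVert f_\theta(x_i) - C\,y_i \rVert_2^2,$$

where $f_\theta$ is the convolutional network's penultimate fully connected
layer, $C$ the $d \times k$ centroid matrix, and $y_i$ the one-hot cluster
assignment of image $x_i$. Identification then treats the $y_i$ as labels and
minimizes the mean negative log-softmax of a linear classifier head $g_W$,

$$\min_{\theta, W} \frac{1}{N}\sum_{i=1}^{N}
  \ell\!\left(g_W(f_\theta(x_i)),\, y_i\right),$$

by mini-batch SGD. Each round of `run_deepcluster()` extracts features under
the current weights, reduces them by PCA, L2-normalizes, clusters with
K-Means, reinitializes the head, and trains one epoch on the fresh
pseudo-labels. The number of clusters defaults to `k = 3` because the biology
recognizes three stages (unripe, ripe, overripe); it is a plain parameter.

### What is trained, and what stays random

The backbone is **randomly initialized and never pretrained**: random
convolutional features are known to be a surprisingly strong image
representation, and the package leans on that result. SGD updates the fully
connected layers (the penultimate feature layer and the classifier head)
while the convolutional filters stay at their random initialization. This is
a deliberate desk-scale reading of the joint objective: the fully connected
stage is where the pseudo-label signal is absorbed, features $f_\theta(x_i)$
still evolve every round, and the frozen conv stack keeps a full experiment
reproducible on one CPU in seconds. Training all convolutional filters is a
scale-up, not a change of method.

### Numerical safeguards

Two standard mechanisms keep the alternating loop away from its known failure
mode (representation collapse, where every image maps to the same feature
vector):

* **Batch normalization** on the trained fully connected layers. BN pins
  per-unit activation variance during training, which makes point-collapse
  impossible in train mode; evaluation uses running statistics, so feature
  extraction is deterministic and independent of batching. The normalized-VGG
  family this architecture follows uses the same mechanism.
* **Gradient-norm clipping** (`clip_grad_norm`, default 1). At the reference
  learning rate 0.1 with momentum 0.9, raw cross-entropy gradients of wide
  fully connected layers can exceed the parameter norm itself and kill ReLU
  units in a single step; clipping bounds each step to a small fraction of
  the parameter scale without changing the gradient direction.

Two further conventions from the cited clustering practice, both exposed as
config flags: the classifier head is **reinitialized after every
reassignment** (cluster identities are arbitrary between rounds, so stale
logit bindings would corrupt learning), and mini-batches are **sampled
uniformly over pseudo-labels** so a large cluster cannot dominate the
gradient and collapse training into one class.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `learning_rate`, `momentum` | 0.1, 0.9 | SGD rates used by the reference experiment. |
| `epochs` (rounds) | 20 | alternating rounds; training length was not specified upstream, 20 suffices for the synthetic recovery experiments. |
| `reassign_every` | 1 | epochs between clustering rounds. |
| `n_components` | min(256, N−1, D) | PCA dimension `d`; 256 follows the cited deep-clustering practice, the upstream experiment states only "PCA". Refit every round, since features change every round. |
| `whiten` | off | upstream states only "PCA"; whitening is available for fidelity comparisons. |
| `sobel_preprocess` | off | the original deep-clustering recipe Sobel-filters inputs; the fruit experiment never mentions it. |
| `k` | 3 | maturity stages. |
| `n_restarts` | 5 | k-means++ restarts per round. |
| `tol`, `max_iter` | 1e-4, 100 | Lloyd convergence: relative objective change or iteration cap. |
| `separation` | 0.7 | synthetic-stage separability knob (1 = clean bands). |

Backbone scales: `tiny` (three conv blocks of 8/16/32 channels, 64 px input,
128-d features) is the test and demonstration configuration; `full` is the
standard VGG16-D layout with the last fully connected layer removed (13 convs,
224 px, 4096-d features from the penultimate FC). Input images are resized,
scaled to [0, 1], and standardized with fixed constants (mean 0.5, sd 0.25)
rather than dataset statistics, so preprocessing is reproducible by
construction.

## K-Means details

Lloyd iterations with k-means++ seeding; the best of `n_restarts` runs is
kept. The objective (mean squared distance to the assigned centroid) is
non-increasing within a run. Ties in the nearest-centroid assignment break to
the lowest centroid index. Empty clusters are repaired by moving the farthest
member of the largest cluster onto the empty centroid — this strictly lowers
the objective — and every repair is counted in the result. On L2-normalized
features, squared-Euclidean ranking coincides with cosine ranking when the
centroids are also normalized, which the test suite asserts.

## Naming clusters as stages

Cluster ids are arbitrary, so `map_clusters_to_stages()` needs evidence:
either truth anchors (a labelled subset; the stage↔cluster bijection is found
by exact permutation search, which is the Hungarian assignment at small `k`),
or a per-image maturity proxy. The default proxy in synthetic runs is the
rendered crack fraction, which is monotone in maturity by construction; seed
oil content is also supported but uses the non-monotone low → high → mid
ordering (oil peaks at ripe), which the result flags explicitly.

## The conjoint analysis

For each physical property (diameters, dry seed weight, moisture content) and
quality property (oil, soluble protein, soluble sugar, starch), stage groups
are compared by one-way ANOVA followed by Duncan's multiple range test at
α = 0.05. For a span of $p$ consecutive sorted means the least significant
range is

$$R_p = q_{1-\alpha_p}(p, \mathit{df}) \sqrt{\mathit{MSE}/n_h},
  \qquad \alpha_p = 1-(1-\alpha)^{p-1},$$

with studentized-range quantiles from `stats::qtukey()` (accurate well beyond
four significant figures) and $n_h$ the harmonic mean group size for unequal
groups. Nonsignificant ranges shield the pairs inside them, and compact
letters are built by the insert–absorb construction; because multiple-range
nonsignificance is contiguous over sorted means, the letters are exactly the
maximal nonsignificant intervals.

**Effective replication.** Quality assays are commonly run as a small number
of pooled determinations per stage rather than per fruit, which makes the
effective replication of the test much smaller than the record count — and
reference conjoint tables in this domain (identical letters on fruit
diameters despite multi-SE mean gaps) are only reproducible under that
reading. `duncan_mrt()` therefore exposes `n_eff`: when set, $n_h = n_{\rm
eff}$ and $\mathit{df} = k(n_{\rm eff}-1)$. The package's recovery
experiments use `n_eff = 3`, matching the three-determination protocol; the
default remains the actual group sizes.

Per-property tests are deliberately not corrected across properties, matching
the conventional presentation of such tables.

Moisture content is $M_c = 100\,(W_f - W_d)/W_f$ from fresh and dry seed
weight; the synthetic generator draws $M_c$ and $W_d$ first and back-computes
$W_f$, so the identity is exactly satisfiable on generated data.

## Grad-CAM

`gradcam_heatmap()` takes "the last layer" to mean the last convolutional
block's output (the standard Grad-CAM choice): channel weights are the
spatially averaged gradients of the target stage's logit with respect to
those maps — with BN in evaluation mode this is an exact closed-form chain
through the fully connected stack — and the map is the rectified weighted sum,
bilinearly upsampled to the input and min–max normalized per image. An
all-zero rectified map is flagged rather than renormalized. Because upstream
claims about "focus regions" are qualitative, the package operationalizes
localization as the fraction of top-decile heat mass inside the rendered
crack bounding box; that statistic is this package's own, and is labelled as
such wherever it appears.

## What the synthetic generator does and does not emulate

`generate_dataset()` renders an elliptical fruit on a textured litter-colored
background with four stage-dependent signals: peel hue band (green →
yellow-brown → brown), peel texture roughness, a peel crack rendered as a
band through the fruit center whose area is exactly `crack_fraction` of the
fruit area, and seed-colored blobs inside the crack covering `seed_exposure`
of the fruit area. A single `separation` knob shrinks hue bands toward their
common center so adjacent stages overlap, as real maturity classes do.
`generate_property_table()` draws each property from its stage's Normal
(mean, SD) using the built-in reference table of stage-wise means and SDs.

Not emulated: photorealistic peel texture, camera/exposure variation,
multi-fruit scenes, occlusion, lighting gradients, or any correlation
structure between properties beyond the moisture–weight identity. Passing
recovery tests therefore demonstrates that the pipeline's machinery is
correct and that its stages interact as designed — not that the method will
reach the same accuracy on orchard photographs.

## Problem sizes and experiment design

The packaged experiments are sized for a single CPU: recovery uses 150
synthetic 64 px images, a tiny backbone, and 20 rounds (a few seconds);
conjoint recovery uses 30 records per stage over 20 generator seeds; Grad-CAM
localization trains on 120 crack-informative images and evaluates 20 cracked
test images. The full VGG16-D configuration is exercised once (build plus one
224 px forward pass) to pin the 4096-dimensional feature contract. Every
stochastic stage derives its seed from one master seed, so complete runs are
bit-reproducible.

## Known limitations

* Conv filters are not updated; on real data with subtle texture cues,
  training them (the full joint objective) may matter more than it does on
  the synthetic stages.
* The exact permutation search in stage naming is limited to `k ≤ 8`.
* Duncan letters at borderline mean gaps are knife-edge by nature; with
  `n_eff = 3` the diameter properties sit close to their least significant
  ranges, which is faithful to the reference tables but means single-seed
  letter patterns can vary.
* PNG/JPEG decoding and resizing go through EBImage; 16-bit inputs are
  accepted but reduced to 8-bit.

## A worked example

```{r example, eval = FALSE}
imgs <- generate_dataset(50, size = 64, rng_seed = 11, separation = 1)
model <- run_deepcluster(imgs, backbone_config("tiny", init_seed = 5),
                         k = 3, config = train_config(epochs = 20, rng_seed = 42))
truth <- truth_stages(imgs)
map_clusters_to_stages(model$clustering$assignments, truth = truth)$agreement
#> [1] 0.9933333

cm <- confusion_from_counts(c(48, 2, 0, 3, 52, 5, 0, 4, 46))
compute_metrics(cm)
#> Maturity identification: 146/160 correct, overall accuracy 91.25%
```
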
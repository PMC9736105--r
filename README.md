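# ripecluster

Unsupervised maturity grading and identification of fruit images, built for
the oil-tea (*Camellia oleifera*) harvesting problem: seed oil content peaks
at the ripe stage and falls once fruit overripen, but no visual grading
standard exists and the assays that define maturity destroy the sample.
`ripecluster` grades fruit photographs into maturity stages **without
labels**, then trains a classifier on those cluster assignments so new fruit
can be identified non-destructively. It is aimed at plant-phenotyping and
agricultural computer-vision researchers who want a fully reproducible,
desk-scale implementation of the method together with the statistics used to
validate it.

## The method

Two objectives alternate (the DeepCluster scheme). Grading clusters convnet
features with K-Means,

```
min_C (1/N) Σᵢ min_{yᵢ} ‖ f_θ(xᵢ) − C yᵢ ‖²
```

where `f_θ` is the penultimate fully connected layer of a randomly
initialized VGG-style backbone, `C` is the `d × k` centroid matrix, and `yᵢ`
the one-hot assignment of image `xᵢ`. Identification treats the assignments
as pseudo-labels and minimizes the mean negative log-softmax of a linear
head `g_W` by mini-batch SGD (lr 0.1, momentum 0.9):

```
min_{θ,W} (1/N) Σᵢ ℓ( g_W(f_θ(xᵢ)), yᵢ )
```

Each round: extract features → PCA → L2 normalization → K-Means (k = 3
stages: unripe / ripe / overripe) → reinitialize head → train on the fresh
pseudo-labels. Around the loop the package provides cluster-to-stage naming,
confusion-matrix metrics (precision / recall / F1 / overall accuracy),
one-way ANOVA + Duncan's multiple range test with compact letter displays
for the conjoint physical/quality property analysis, Grad-CAM heatmaps, and
a synthetic fruit-image + property-table generator so every stage is testable
without the original orchard data.

## A worked example

```r
library(ripecluster)

# 150 synthetic images, 50 per stage, cleanly separated hue bands
imgs  <- generate_dataset(50, size = 64, rng_seed = 11, separation = 1)
model <- run_deepcluster(imgs, backbone_config("tiny", init_seed = 5),
                         k = 3, config = train_config(epochs = 20, rng_seed = 42))
model
#> <rc_model k=3 rounds=20 final objective=0.14148 final loss=0.9472>

truth <- truth_stages(imgs)
map_clusters_to_stages(model$clustering$assignments, truth = truth)$agreement
#> [1] 0.9933333
```

The loop recovered the three generated stages at 99.3% truth-matched
accuracy. The identification metrics work from any confusion matrix; on the
reported 160-image testing-set counts:

```r
cm <- confusion_from_counts(c(48, 2, 0,
                              3, 52, 5,
                              0, 4, 46))
compute_metrics(cm)
#> Maturity identification: 146/160 correct, overall accuracy 91.25%
#> Maturity     Prec (%)    Rec (%)     F1 (%)
#> unripe          94.12      96.00      95.05
#> ripe            89.66      86.67      88.14
#> overripe        90.20      92.00      91.09
```

Conjoint property analysis with Duncan letters (means sharing a letter are
not separated at α = 0.05; `n_eff = 3` mirrors a three-determination assay
protocol):

```r
tab <- generate_property_table(30, rng_seed = 1001)
conjoint_report(tab, n_eff = 3)
#> Property                           unripe             ripe               overripe
#> Transverse diameter (mm)           45.95 ± 1.53 a     47.12 ± 1.82 a     49.14 ± 1.40 a
#> Dry seed weight (g)                8.12 ± 0.55 b      12.17 ± 1.11 a     11.07 ± 0.30 a
#> Moisture content (%)               69.36 ± 4.31 a     58.82 ± 1.92 b     48.15 ± 0.72 c
#> Seed oil content (%)               39.27 ± 0.85 c     46.12 ± 0.51 a     44.45 ± 0.46 b
#> ...
```

Grad-CAM explains a prediction (`gradcam_heatmap()`, `heatmap_overlay()`),
and a thin command-line driver ties the stages together
(`inst/scripts/ripecluster simulate|train|grade|identify|evaluate|conjoint|gradcam`).

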
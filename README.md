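# proust

Spatial domain detection for spot-based spatial multi-omics data in R.

Spatial platforms such as 10x Visium and Visium Spatial Proteogenomics (SPG)
pair transcriptome-wide expression at ~55 µm spots with full-resolution
images of the same tissue section — multiplexed immunofluorescence protein
channels or an H&E stain. `proust` partitions the spots into discrete,
spatially coherent domains (cortical layers, white matter, disease niches)
by integrating three signals: gene expression, image-derived features, and
the spot lattice geometry. It is aimed at analysts of Visium-style data who
want domain calls that use the paired image rather than expression alone.

## Method at a glance

1. **Spatial graph.** Spot centroids become an undirected kNN graph
   (default k = 3); convolutions propagate through the augmented operator
   *L = I + D^-1/2 A D^-1/2*, which mixes each spot's own signal into every
   step.
2. **Per-modality features.** Expression is filtered, median-library-size
   normalised, log1p-transformed, reduced to 3000 highly variable genes and
   scaled (clipped at 10). Image channels are cut into per-spot patches,
   resized to 48×48 by area-weighted averaging, range-matched to the
   expression scale, and encoded by a small convolutional autoencoder
   (5×5 convs, average pooling; F = 576 features per spot and channel).
3. **Graph autoencoder + contrastive learning.** Each modality trains a
   two-layer GCN autoencoder jointly with a Deep-Graph-Infomax style
   objective: a bilinear discriminator D(Z_i, S_i) = σ(Z_i' W S_i) learns to
   tell true (embedding, neighbourhood-readout) pairs from pairs built on
   row-shuffled features, minimising
   *Loss = α L_recon + β (L_CSL + L_CSL')* with Adam.
4. **Domain calling.** Top PCs of the two reconstructions (30 RNA + 5 image
   by default — the PC counts are the modality weights) are concatenated
   into a hybrid profile, clustered by a Gaussian mixture model (EM from
   seeded k-means restarts, mclust engine), optionally refined by a
   majority vote over each spot's 10 nearest neighbours, with k selectable
   by silhouette.
5. **Evaluation.** Adjusted Rand index against reference annotations.

A bundled generator (`simulate_spots()`) produces Visium-like sections —
honeycomb lattice, layered domains, negative-binomial counts,
domain-contrasting image channels — so the whole pipeline is testable
without downloads.

## Worked example

```r
library(proust)

# a 600-spot synthetic section: 4 layered domains, 300 genes (20% DE at
# 1 log2-fold), 2 domain-contrasting image channels
sim <- simulate_spots(seed = 11)
sim$dataset
#> spot_dataset: 600 spots (600 in tissue), 300 genes, 2 image channel(s)

cfg <- proust_config(n_clusters = 4, gcn_iters = 600, image_iters = 300,
                     seed = 7)
res <- run_pipeline(cfg, dataset = sim$dataset, truth = sim$truth)
res
#> proust_domains: 600 spots, k = 4 (35 PCs: 30 RNA + 5 image)
#>   ARI vs reference: 1.000 (refined 1.000)
```

The hybrid profile recovers the planted domains exactly (adjusted Rand
index 1.0 against the generator's ground truth, before and after spatial
refinement). Expression alone does noticeably worse on the same section:

```r
cfg_rna <- proust_config(modality_mode = "rna_only", n_clusters = 4,
                         gcn_iters = 600, seed = 7)
run_pipeline(cfg_rna, dataset = sim$dataset, truth = sim$truth)$ari_refined
#> [1] 0.7868321
```

`tidy()` returns one row per spot (id, coordinates, raw and refined
domain), `glance()` a one-row summary, and `autoplot()` a ggplot of the
domain map. Real data enter through `load_spot_dataset()` (MTX folder or
dense CSV counts, positions CSV, TIFF/PNG channels); results persist with
`write_results()` plus a manifest that records every resolved parameter and
seed. A thin command-line wrapper ships in `exec/proust`
(`proust simulate | run | evaluate`).

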
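# sublandmarks

Consistent subcellular landmarks from multiplexed pixel profiles.

Highly multiplexed immunofluorescence yields tens of aligned marker channels
per cell; every pixel is a *multiplexed pixel profile*. Clustering these
profiles reveals subcellular structures (nucleoli, speckles, nuclear bodies),
but across experimental conditions the same structure ends up in different
clusters whenever a perturbation shifts the intensity of some channels —
which defeats quantitative comparison. `sublandmarks` is for image analysts
who want condition-robust subcellular segmentation and statistics from such
data.

The package learns a **conditional σ-VAE** representation of 3×3 pixel-profile
patches: the encoder and the linear decoder both receive the experimental
condition, so condition-specific variation is explained by the condition
input and the 16-d latent code `z` stays condition-independent. The training
objective is the calibrated ELBO

&nbsp;&nbsp;&nbsp;&nbsp;`L = D·ln σ + D/(2σ²)·MSE(x̂, x) + KL(q(z|x,c) ‖ N(0, I))`,&nbsp;&nbsp;&nbsp;&nbsp;`σ² = MSE` (analytic, per batch),

where `x` is the center pixel of the patch and `D` the channel count.
Latent means are clustered with the Leiden algorithm on an exact kNN graph
(k = 15, modularity objective, resolution 0.5) on a 150k-pixel subsample and
projected to all pixels by 15-NN majority vote, giving **consistent
subcellular landmarks (CSLs)**. On these the package quantifies per-cell
landmark intensities, object morphology (8-connected components with the
standard >10 px and cumulative <10% size filters; circularity 4πa/p²), and
spatial co-occurrence `c_ij = p(j|i, [d_a,d_b)) / p(j)` over log-spaced
distance annuli — and compares conditions with logistic-regression probes
(balanced accuracy), cluster-fraction coefficients of variation, pairwise L1
silhouette scores, and per-landmark mixed-effects fold-change models (random
well intercept, condition-specific residual variances, containment-df Wald
tests, Benjamini–Yekutieli correction).

A synthetic multiplexed-image generator with per-pixel ground truth makes the
whole pipeline testable without real data. The neural network is implemented
natively (BLAS matrix algebra, hand-derived gradients validated against
finite differences, Adam); the exact kNN search is chunked C++.

## Worked example

A miniature end-to-end run (a few minutes on one CPU):

```r
library(sublandmarks)

# synthetic two-condition study: the "treated" condition doubles channels
# 7 and 8; three structure classes plus background, per-pixel ground truth
out <- generate_synth_small(seed = 1, n_cells_per_condition = 12)
ds  <- background_subtract(out$dataset)
ds  <- fit_and_apply_quantile_norm(ds, q = 0.98)
ds  <- split_cells(ds, c(0.8, 0.1, 0.1), seed = 2)

model <- train_cvae(ds, cvae_config(epochs = 10, seed = 3),
                    fraction_per_cell = 1.0)
enc   <- encode_dataset(model, ds)

# how detectable is the condition in pixel space vs the latent space?
cond <- enc$conditions$perturbation
max(probe_over_seeds(enc$centers, cond, seeds = 0:4)$balanced_accuracy)
max(probe_over_seeds(enc$z,       cond, seeds = 0:4)$balanced_accuracy)

# cluster the latent space into landmarks and check condition consistency
asg <- cluster_pixels(enc$z, n_subsample = 20000, k = 15, resolution = 0.5,
                      seed = 4)
cluster_fraction_cv(asg$labels, cond)$median_cv

# annotate clusters by their enriched marker channels and compare with truth
prof <- cluster_channel_profile(dataset_pixels(ds)$intensities, asg$labels,
                                ds$panel$names)
ann  <- apply_annotation(asg$labels, propose_annotation(
  prof, c(ch1 = "large", ch2 = "large", ch3 = "speckles",
          ch4 = "speckles", ch5 = "dots", ch6 = "dots")))
adjusted_rand_index(ann, ground_truth_labels(out$ground_truth, ds))
```

Printed values from this exact script:

```
[1] 1
[1] 0.675
[1] 0.07935011
[1] 1
```

The first two numbers are balanced accuracies of a ridge-logistic probe
predicting the condition from held-out pixels: 1.0 in pixel space (the
twofold channel scaling is trivially decodable) versus 0.675 on the cVAE
latents of this deliberately small run — the conditioning has absorbed most
of the condition signal, and at the full study scale (200 cells, 25 epochs,
as run by the acceptance script) the maximum latent probe accuracy drops to
about 0.6. The third line is the median coefficient of variation of
per-condition cluster fractions: each landmark occupies a similar fraction of
pixels in both conditions. The final 1.0 is the adjusted Rand index between
the annotated landmarks and the generator's ground-truth structure labels —
on this fixture the latent clusters, merged by their enriched marker
channels, recover the ground truth exactly.

The same pipeline is available as config-driven stages
(`run_pipeline("all", cfg)`, or the `inst/scripts/sublandmarks` wrapper),
writing CSV/TIFF/YAML artifacts plus a resolved-config snapshot per stage
under a run directory.

## Vignette

`vignettes/landmark-discovery.Rmd` documents the model and its assumptions,
every tunable parameter with units and defaults, what the synthetic generator
does and does not emulate, numerical edge-case conventions, and known
limitations.
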
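# phenoseg

Unsupervised segmentation of greenhouse plant images into **fruit**,
**leaf** and **background** — no labelled training data required.

Greenhouse photographs are hard to annotate: specular highlights, leaf
shadows and distant objects leave many regions genuinely ambiguous, so
supervised segmenters inherit noisy training sets. `phenoseg` sidesteps
annotation entirely. A topic model clusters pixels from local appearance
alone and a fully connected conditional random field (CRF) turns the soft
clustering into a coherent labelling:

1. **Visual words** — each pixel gets a 17-D descriptor (Gaussian, LoG and
   derivative-of-Gaussian filter responses in CIELab), quantized onto a
   seeded K-means codebook of W = 64 words.
2. **Spatial documents** — overlapping square regions (50% overlap) are
   the documents of a latent Dirichlet allocation with K = 3 topics,
   fitted by collapsed Gibbs sampling
   (`p(z_i = k | z_-i, w) ∝ (n_dk + α)(n_kw + β)/(n_k + Wβ)`);
   per-pixel topic posteriors are aggregated over retained sweeps.
3. **Dense CRF** — the posterior supplies the unary energy
   `ψ_u(x_i) = −log p_i(x_i)`; appearance (bilateral) and smoothness
   Gaussian kernels under Potts compatibility form the pairwise energy
   `E(x) = Σ ψ_u(x_i) + Σ ψ_p(x_i, x_j)`, minimized approximately by
   parallel mean-field iterations (near-linear-time lattice engine, with
   an exact O(N²) reference engine for small images).
4. **Class naming** — clusters are named from RGB statistics: the class
   with minimal variance of its channel means is background; of the rest,
   the red-dominant one is fruit, the other leaf. Fruit pixels can then be
   extracted (all other pixels zeroed).
5. **Multi-resolution mode** — a 3-level Gaussian pyramid
   (200×300 → 100×150 → 50×75) is segmented coarse to fine, each level's
   labels propagated down as a soft annotation prior mixed into the next
   unary (`U = λ(−log prior) + (1−λ)(−log posterior)`); robust to small
   highlight/shadow patches, which vanish at low resolution.

Evaluation uses four quantities: `Acc_seg = k/(m·n)`,
`Acc_fruit = l_fruit/a`, `Seg_over = P_over/(P_gt + P_over)` and
`Seg_under = P_under/(P_gt + P_over)`.

A seeded synthetic greenhouse-scene generator (red fruit disks, textured
green leaf ellipses, bright background, optional highlight/shadow
artifacts, pixel-exact ground truth) makes the whole pipeline testable
without any photographs.

## Worked example

```r
library(phenoseg)

scene <- generate_scene(scene_spec(seed = 11))     # 200x300, ground truth included
res   <- segment_single(scene$image, seg_config(seed = 11))
res$roles
#>            1            2            3
#> "background"      "fruit"       "leaf"
evaluate_segmentation(res, scene)
#> Segmentation metrics (300 x 200 pixels)
#>   Acc_seg   = 1.0000  (60000 / 60000)
#>   Acc_fruit = 1.0000  (6653 / 6653)
#>   Seg_over  = 0.0000   Seg_under = 0.0000  (P_gt 6653, P_over 0, P_under 0)
```

Every pixel of this synthetic scene is labelled correctly and all 6653
ground-truth fruit pixels are recovered with no spurious fruit. The
multi-resolution variant is `segment_multiresolution(image, seg_config(n_levels = 3, lambda = 0.5))`;
with `lambda = 0` it reduces exactly to the single-layer result.

There is also a command-line interface:

```sh
inst/cli/phenoseg synth   --out scenes --n 3 --seed 7
inst/cli/phenoseg segment --input scenes/scene_001.png --out seg --mode multi --levels 3 --seed 7
inst/cli/phenoseg evaluate --pred seg/labels.png --gt scenes/scene_001_labels.png --out report.json
```

## Tests

```r
# from the package root
devtools::test()
```

The suite includes brute-force oracles (direct convolution, exhaustive
nearest-neighbour scans, hand-evaluated Gibbs conditionals, O(N²)
mean-field reference) alongside the end-to-end checks.

## The methods vignette

`vignettes/unsupervised-crf-segmentation.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, the lattice
engine's construction (B-spline splatting with spectrally deconvolved
blur and exact self-weight exclusion), the synthetic generator's scope,
and known limitations.
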
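# athermoseg

Unsupervised segmentation of thermal-infrared images by adaptive entropy
multilevel thresholding.

Aerial thermal surveillance of wildlife and protected areas produces
single-channel, low-contrast, noisy images in which a few warm bodies must
be isolated from cluttered terrain. `athermoseg` is for researchers and
practitioners who need a deterministic, histogram-based segmentation of such
images — no training data, no GPU — together with the instrumentation to
evaluate it: no-reference contrast metrics, ground-truth scoring, and
synthetic scene generators so every result is reproducible without any
external dataset.

## The method

For an image with `L` intensity levels and histogram probabilities `p_i`,
multilevel thresholding selects cut points `0 < T1 < … < Tn < L−1`
maximising a sum of per-class entropy scores. The package's central
objective scores a class `s` with cumulative mass `ω_s` as

    E_s = − Σ_i ( p_i/ω_s + ε )^γ · tan^γ( log( p_i/ω_s + ε ) )

with natural logarithms, `ε = 1` and `γ = 1` by default. With `ε = 1` the
tangent argument lies in `(0, log 2]`, so the kernel is smooth, bounded and
pole-free, and zero-probability levels contribute exactly zero. Shannon,
Tsallis(q), Renyi(α), Kapur and Masi(r) objectives are provided as
baselines, all selectable by name. Two exact search modes — literal
exhaustive enumeration and an `O(k·L²)` dynamic program — return identical
thresholds, with ties broken toward the lexicographically smallest tuple.

The full pipeline (`run_pipeline`) is: bilevel pre-threshold → adaptive
gamma `γφ = exp((μ − Imax/2)/(Imax/2))` with a logit intensity mapping
`f(i) = log( (i/(L−1)) / (1 − i/(L−1) + γφ) )` → `n`-level thresholding of
the enhanced image → posterization by class means → final bilevel
binarization into a region-of-interest mask.

Also included:

* **Block-based quality metrics** (`iqa_metrics`): a block-local version of
  the adaptive entropy plus the EME/EMEE/AME/AMEE contrast-measure family —
  metrics that, unlike global entropies, respond to spatial rearrangement.
* **Segmentation scoring** (`evaluate_mask`): accuracy, Dice, Jaccard,
  precision, recall, boundary F1 with a pixel tolerance, and the combined
  score `CS = wm·DSC + (1−wm)·BF`.
* **Synthetic fixtures** (`make_scene`, `shuffle_pixels`, `doe_series`):
  seeded thermal-like blob scenes with ground truth, histogram-preserving
  pixel shuffles, and graded contrast-enhancement series.
* **A command line** (`run_cli`; script in `inst/scripts/athermoseg`) with
  `segment`, `enhance`, `iqa`, `eval`, `synth` and `bench` subcommands and
  JSON reports.

## Worked example

```r
library(athermoseg)

# a seeded 128x128 thermal-like scene with ground truth
sc <- make_scene(scene_spec(seed = 42))
sc$image
#> <gray_image 128x128, L=256, range [41, 135]>

res <- run_pipeline(sc$image, n = 1)
res
#> <segmentation_result 128x128>
#>   pre-threshold  t = 140
#>   multilevel     t = 117 (k = 1)
#>   final          t = 74
#>   gamma_phi = 1.7906, rho = 11.2686, mu = 201.77
#>   mask foreground: 590 px
```

The three thresholds are the bilevel pre-pass on the (normalized) input, the
multilevel pass on the enhanced image, and the final bilevel pass on the
posterized image; `gamma_phi` is the image-adapted gamma computed from the
foreground mean `mu`. Scoring the mask against the generator's ground
truth:

```r
ev <- evaluate_mask(res$mask, sc$mask)
#> dice 0.8730  iou 0.7746  bf 0.9115  cs 0.8922  accuracy 0.9919
```

The boundary F1 of 0.91 says the mask's outline tracks the true blob
boundaries to within 2 px almost everywhere; the Dice of 0.87 reflects the
thin ring of background-tail pixels that entropy cuts admit on noisy scenes
(see the methods vignette's limitations section). Block metrics on the same
scene:

```r
round(iqa_metrics(sc$image), 4)
#> a_entropy       eme      emee       ame      amee
#>   -1.0355    3.7286    0.2728    0.2103    0.1049
```

From a shell, the same pipeline:

```sh
athermoseg synth --out demo --seed 42
athermoseg segment demo/scene.png --k 1 --out demo/out.png --report demo/report.json
athermoseg eval --pred demo/out.png --gt demo/mask.png --json demo/metrics.json
```

## The methods vignette

`vignettes/athermoseg-methods.Rmd` documents the entropy objectives and
their numerical conventions, the search's feasibility and tie-break rules,
the enhancement's rescale and requantization choices, the evaluation and
block-metric definitions, what the synthetic scenes do and do not emulate,
and the package's known limitations.
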
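---
title: "Adaptive entropy thresholding for thermal images: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive entropy thresholding for thermal images: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(athermoseg)
```

## The problem

Aerial thermal-infrared surveillance of wildlife produces single-channel,
low-contrast, noisy images in which a handful of warm bodies (animals,
people) must be separated from a cluttered terrain background. `athermoseg`
segments such images by *multilevel histogram thresholding*: it chooses `n`
cut points `0 < T1 < … < Tn < L-1` on the intensity axis that maximise an
entropy objective over the induced classes, then reduces the result to a
binary region-of-interest mask.

## Entropy objectives

All objectives are functions of the intensity histogram alone. For a
candidate partition, each contiguous class `s` with within-class normalised
probabilities `q_i = p_i / w_s` (where `w_s` is the class's cumulative
probability) is scored, and the class scores are summed.

* **Adaptive tan–log kernel** (the default):
  `E_s = −Σ_i (q_i + ε)^γ · tan^γ( log(q_i + ε) )`, natural log, tan in
  radians. With the default `ε = 1` the argument `q_i + 1` lies in `[1, 2]`,
  so the tangent argument lies in `(0, log 2]`: the kernel is smooth and
  bounded, `tan^γ` is well defined for fractional `γ` (the tangent is
  nonnegative), and a zero-probability level contributes exactly
  `−tan(log 1) = 0`, so empty bins vanish without special-casing. For
  `ε < e^{−π/2} ≈ 0.208` the argument can cross a tangent pole; the
  implementation detects proximity to a pole (within `1e−12`) and raises an
  error naming the offending level instead of returning an astronomically
  large score.

  A circulating variant of this kernel divides by `w_s + ε` instead of
  shifting the normalised ratio. We evaluated both during development and
  rejected the dividing form on numerical grounds: its tangent argument
  `log(p_i/(w_s+ε))` sweeps across infinitely many tangent poles as `p_i`
  becomes small, so the maximiser is dominated by whichever histogram bins
  happen to fall near a pole — a lottery on the histogram shape. Under
  maximisation it also refuses to split a two-spike histogram (the shape the
  pipeline's posterized image always has) at foreground fractions of a few
  percent, which would make the final binarization degenerate. The shifted
  form has neither defect and is the one whose stability rationale (`ε = 1`
  "skips" the `p = 0` case) is internally consistent.

* **Kapur**: Shannon entropy of the within-class distribution,
  `−Σ q_i log q_i` (base 2 by default).
* **Shannon baseline**: entropy of the class-mass vector, `−w_s log w_s`
  summed over classes, maximal for mass-balanced partitions. (Summing
  *unnormalised* within-class entropies is partition-invariant — it
  telescopes to the global entropy for every tuple — so it cannot serve as
  an objective; this was verified by enumeration and is why the class-mass
  form is used.)
* **Tsallis (order q)** and **Renyi (order α)** of the within-class
  distribution; both recover Shannon as their order tends to 1, which the
  test suite checks numerically.
* **Masi (parameter r)**:
  `(1/(1−r)) log(1 − (1−r) Σ q_i log q_i)`. The expression is evaluated in
  natural logarithms and divided by `log(b)` to express the result in
  base-`b` units: under that convention (and only that convention) the
  `r → 1` limit recovers the Kapur entropy in the same base. For some `r`
  the outer logarithm's argument becomes nonpositive; that is reported as an
  error with the offending segment.

Parameter defaults `q = 0.5`, `α = 2`, `r = 0.5` are conventional mid-range
choices for these families; the literature this method draws on cites but
does not fix them. Logarithms are base 2 for Shannon/Renyi/Kapur/Masi
(entropies in bits) and natural for the adaptive kernel.

## Threshold search

Two exact search modes return identical results:

* `search_thresholds()` — the literal nested-loop enumeration of all
  strictly increasing tuples (practical for `k ≤ 3` at `L = 256`);
* `search_thresholds_dp()` — an `O(k·L²)` dynamic program over the
  precomputed table of all `L(L+1)/2` contiguous-segment scores.

Three conventions matter on real histograms and are fixed explicitly:

1. **Empty classes are infeasible.** A tuple that carves out a class with no
   probability mass is skipped (the within-class normalisation `p/w` is
   undefined at `w = 0`). This is the search-level counterpart of the
   kernel's division-by-zero guard, and it is what makes the final bilevel
   pass on a two-spike posterized histogram well posed: the only feasible
   cuts lie between the two spikes. Reporting functions
   (`precompute_segment_scores()`, `total_objective()`) still score an empty
   class as 0 by convention.
2. **Ties break toward the lexicographically smallest tuple.** The running
   maximum starts at `−∞` and is replaced only on strict improvement while
   tuples are visited in ascending lexicographic order. Plateaus are common
   on sparse histograms, so this is stated rather than left to chance. The
   DP reconstructs the same tuple by greedy stage-wise selection against
   exactly-equal continuation values, and recomputes the final score as the
   same left-to-right sum the enumeration uses, so the two modes agree bit
   for bit.
3. **A threshold `t` assigns level `t` to the lower class**: classes are
   `[0,t1], (t1,t2], …, (tn, L−1]`, matching the pipeline's partition and
   binarization rules (`p ≤ t` below, `p > t` above).

## Adaptive enhancement

The pipeline brightens foreground signatures before the multilevel pass.
The gamma parameter adapts to the image: `γφ = exp((μ − Imax/2)/(Imax/2))`,
where `μ` is a reference mean — by default the mean of pixels above a
bilevel pre-threshold (foreground mean), optionally the global mean. It
always lies in `[1/e, e]`.

The intensity mapping is `f(i) = log( (i/(L−1)) / (1 − i/(L−1) + γφ) )`,
affinely rescaled to `[0, ρ(L−1)]`. Four numerical choices:

* `f(0)` is a log of zero; it is filled by linear extrapolation from `f(1)`
  and `f(2)` before rescaling so the affine map stays finite.
* The rescale's min/max are taken over the image's **occupied level range**
  (the analogue of a min/max rescale computed on the mapped image itself).
  Taken over the full domain instead, the unused steep toe of the curve near
  level 0 absorbs most of the output range and the occupied levels are
  compressed into its flat top — the mapping then degrades rather than
  enhances contrast. Levels outside the occupied range clamp to the ends.
* A constant additive term sometimes attached to `f` is absorbed exactly by
  the affine rescale and is therefore not represented.
* **Requantization.** The mapped range `[0, ρ(L−1)]` exceeds the
  representable range whenever `ρ > 1` — which includes both conventional
  settings, fixed `ρ = 2` and adaptive `ρ = μ/(10 γφ)`. Truncating at
  `L−1` would saturate almost every occupied level to white (the clip knee
  sits at fraction `1/ρ` of the range), leaving a near-constant image, so
  the default requantization rounds at the scaled resolution and divides by
  the realized maximum — the same max-normalisation the threshold search
  applies to its own input. `ρ` then acts through rounding granularity
  (`ρ < 1` merges levels). The literal truncation is available as
  `enhance(requantize = "clip")` for comparison.

Because the mapping is strictly monotone on the occupied range, thresholding
the enhanced image is equivalent to thresholding the input at a pulled-back
cut; enhancement changes the *histogram geometry* the objective sees (and
the visual rendering), not the set of achievable segmentations — except
where requantization merges levels.

## The segmentation pipeline

`run_pipeline(img, n)` executes: bilevel pre-threshold on the input →
foreground mean, adaptive `γφ`, logit mapping → `n`-level threshold search
on the enhanced image → posterization (each class replaced by its rounded
mean intensity) → bilevel threshold on the posterized image → strict
greater-than binarization. All intermediates are returned.

The threshold-search definition includes an `I/max(I)` normalisation of its
input, while the pipeline applies search results directly to the image the
search ran on; the two are inconsistent whenever a stage image does not
already span the full range. The pipeline resolves this by normalising the
*input* image once (`normalize_quantize`) and letting later stages use their
images directly: the enhancement rescale already plays the normaliser's
role for the enhanced image, and the final threshold must be applied to the
posterized image on its own scale for the binarization rule to be
meaningful. Every reported threshold is therefore on the scale of the image
it partitions.

Empty classes between consecutive thresholds are legal in the posterization
(they contribute no value to the output); the final bilevel histogram has at
most `n+1` occupied bins, and the empty-class feasibility rule confines its
cut to lie between the extreme posterized values.

## Block-based quality metrics

Global entropies depend on the histogram only, so any spatial shuffle of
pixels leaves them bit-identical. The block metrics evaluate local structure
on non-overlapping tiles (8×8 by default, the convention of the
block-contrast literature; edge remainders are kept as partial blocks):

* `block_a_entropy` — the adaptive kernel on each block's local PDF (the
  kernel's normalising weight is the block's total mass), averaged over
  blocks;
* `eme` — `20·log10((Imax+g)/(Imin+g))` per block;
* `emee` — `α·r^α·ln r` with the same guarded ratio `r`, `α = 0.5`;
* `ame` — guarded Michelson contrast `(Imax−Imin)/(Imax+Imin+g)`;
* `amee` — `α·(1+M)^α·ln(1+M)` of the Michelson contrast `M`.

These four comparators are stated as the package's own conventions: the
contrast-measure literature they descend from fixes only the block-ratio
idea, and published variants differ in orientation and constants. All four
here are oriented so that larger values mean more within-block contrast, and
the guard `g = 1e−4` enters numerator and denominator symmetrically so a
constant image scores exactly 0. The scalar reduction over blocks is the
arithmetic mean.

## Evaluation metrics

`confusion()` counts pixels with foreground = 1; `region_metrics()` applies
the standard formulas (accuracy, Dice, Jaccard/IoU, precision, recall). A
metric with a zero denominator is reported as `NA`, never silently as 0
or 1; the identity `DSC = 2·IoU/(1+IoU)` is property-tested on random
counts. `bf_score()` extracts boundary pixels (foreground with a background
8-neighbour; the image border counts as background), matches them within a
Euclidean tolerance (2 px by default, configurable), and returns the
harmonic mean of boundary precision and recall; two empty boundaries score
1, one empty boundary 0. The combined score is `CS = wm·DSC + (1−wm)·BF`
with `wm = 0.5` by default (the weight is a free constant in the method's
definition; equal weighting is the neutral choice).

## Synthetic scenes

`make_scene()` emulates the aerial-thermal regime the method targets:
a spatially smooth noisy background (Gaussian field, smoothing scale 3 px)
around mean 60, a small number of brighter elliptical blobs whose plateau
intensity is `contrast_ratio × background_mean`, a Gaussian edge feather
(1 px) centred on the blob boundary, independent additive Gaussian pixel
noise, and clipping to `[0, L−1]`. The ground-truth mask is the elliptical
support; the half-amplitude contour of the feather coincides with the mask
boundary, so the mask is recoverable in the noiseless limit. Generation is
a pure function of the spec (a private Mersenne–Twister stream seeded from
the spec; the caller's RNG state is untouched).

What the generator does **not** emulate: background clutter with its own
thermal structure (trees, rocks), radiometric calibration, motion blur,
halo/vignetting, or the heavy-tailed noise of real microbolometers. Passing
tests on these scenes demonstrate the machinery is correct and calibrated on
its stated conditions; they do not certify performance on real surveillance
footage.

`shuffle_pixels()` permutes within rows, within columns, or globally —
exactly preserving the histogram. `doe_series()` produces the graded
contrast-enhancement family `v ↦ mean + (1 + d/100·κ)(v − mean)` (gain
constant `κ = 0.5`, clipped); this clipped affine stretch is a stand-in
operator chosen because it guarantees the monotone-contrast premise that
graded-enhancement comparisons rely on, not a reconstruction of any
particular published enhancement chain. Because an affine gain ≥ 1 is
injective on integer levels, block-local PDFs are unchanged along the series
until clipping bites; the block entropy metric is then constant (trivially
nondecreasing) while the contrast measures strictly grow.

## Test problem sizes

The suite exercises: oracle equivalence of the two search modes against
naive enumeration at `L = 32`, `k ∈ {1,2,3}`, all six objectives, 20 random
PDFs; shuffle discrimination and graded-enhancement monotonicity on 10 and
3 seeded 128×128 scenes; and mask recovery on 20 seeded 128×128 scenes at
contrast 2.0 and noise σ = 5. These sizes were chosen so the full suite
exercises every code path at full `L = 256` fidelity while each property
test remains a matter of seconds to a couple of minutes.

## Known limitations

* **Bulk-edge bias of entropy cuts.** On scenes with Gaussian pixel noise,
  the maximising bilevel cut of *every* objective in scope settles near the
  upper edge of the background bulk (about +2σ), classifying the remaining
  1–2% background tail as foreground. On the default recovery scenes this
  caps the measured Dice around 0.84–0.92 (the acceptance script reports the
  exact values), below the 0.95 the recovery test asserts, even though a cut
  placed deeper into the inter-class gap would score higher — the objectives
  simply do not prefer that cut. This tail-grabbing bias is intrinsic to
  entropy-maximising thresholding of noisy histograms (it is the classic
  noise-sensitivity complaint against Kapur-type criteria) and is reported
  honestly rather than patched cosmetically. Accuracy, by contrast, stays
  above 0.98 on the same scenes because the tail is a small fraction of the
  frame.
* The adaptive kernel's score differences across candidate cuts can be tiny
  (order `1e−3` on 256-level histograms); exact reproducibility therefore
  depends on the deterministic tie-break and the fixed summation order, both
  of which are pinned down and tested.
* The exhaustive search is `O(L^k)`; beyond `k = 3` use the DP mode (the
  pipeline switches automatically).
* No morphological post-processing, connected-component filtering, or
  temporal tracking is applied after binarization; the mask is exactly the
  thresholding result.
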
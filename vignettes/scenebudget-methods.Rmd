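---
title: "Measuring scene information and modeling boundary-transformation scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring scene information and modeling boundary-transformation scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scenebudget)
```

## The question and the model

Observers misremember the spatial boundaries of scenes: some images are
remembered with a wider field of view than was shown (boundary extension),
others with a narrower one (boundary contraction). In a forced-error
paradigm, an image is shown, masked, and shown again unchanged; the observer
must judge the second presentation "closer" (zoomed in) or "farther" (zoomed
out). Since the two presentations are identical, every answer is an error,
and the direction of the error reveals the memory bias. Coding extension
errors +1 and contraction errors −1, the per-image mean over observers is
the *boundary-transformation score* `s ∈ [−1, 1]`: positive means net
extension.

`scenebudget` implements the full analysis around one hypothesis: that scene
memory is biased toward a fixed budget of *information*, so
information-rich scenes contract in memory and information-poor scenes
expand. The pipeline measures per-image visual and semantic information,
collapses each to a single score, and models the boundary-transformation
scores as a linear function of scene depth and the two information scores,
with a split-half noise ceiling bounding attainable fit and a seven-model
variance partition separating the predictors' contributions.

## Visual information

Three metrics, each capturing a different facet of image complexity:

* **Edge density** — the count of edge pixels from a Canny detector.
  Defaults: 5×5 Gaussian blur, hysteresis thresholds 30/150. Verbal
  descriptions of this kind of detector leave several dialect choices open,
  and ours are: ITU-R 601 luminance for grayscale conversion; blur sigma
  from the common kernel-to-sigma rule (`0.3·((k−1)/2 − 1) + 0.8`, so 1.1
  for a 5×5 kernel); Sobel gradients with L2 magnitude, thresholds read on
  the 0–255 intensity scale; replicate border padding; non-maximum
  suppression with a `>=`/`>` tie-break so a clean step edge thins to a
  single one-pixel contour (a 350-pixel-tall half-black/half-white image
  yields exactly 350 edge pixels).
* **Color entropy** — Shannon entropy (bits) of the joint histogram of the
  CIELAB A\*/B\* chromatic channels, 20 bins per axis by default. The axis
  range is fixed at [−110, 110] per channel so the binning is
  image-independent; out-of-range values are clipped into the end bins. The
  sRGB→Lab conversion assumes sRGB primaries and D65 white. Upper bound:
  `log2(400) ≈ 8.64` bits.
* **Gist entropy** — Shannon entropy of the normalized Gist descriptor:
  Gabor-type filters constructed in the frequency domain (3 scales with
  8/6/4 orientations; transfer function
  `exp(−3.5·(f/f0 − 1)² − 2·(K²/64)·π·t²)` with center frequencies
  `0.3/1.85^(s−1)` cycles/pixel), applied to the grayscale image after an
  internal resize to 256×256 (a power of two, for the FFT), with filter
  energy magnitudes averaged over an 8×8 spatial grid. The 64 locations ×
  (8+6+4) orientations give 1152 non-negative features, normalized to sum
  to 1. A constant image has zero filter energy everywhere and is reported
  as an error rather than silently producing NaNs.

Entropy is `−Σ pᵢ log2 pᵢ` throughout, with `0·log 0 := 0`.

## Semantic information

The meaning in an image is estimated from a corpus of free-text
descriptions (around 100 per image in the intended design), via:

* **Median description length**, in raw whitespace-delimited words. Counting
  *before* stopword and punctuation removal is a deliberate choice: the
  rationale for the metric is that longer utterances carry more content, and
  function words are part of utterance length. A flag
  (`after_tokenization = TRUE`) switches to the post-tokenization count.
* **Lexical entropy** — tokens from all of an image's descriptions are
  pooled, and the entropy of the word-type histogram is computed. More
  unique words and flatter usage give higher values.
* **Mean pairwise embedding distance** — within each description, every
  unordered pair of surviving token positions (`choose(k, 2)` pairs for k
  tokens; duplicated tokens contribute zero-distance pairs) is scored by
  cosine distance `1 − cos` under a pluggable word-embedding table; pair
  distances are averaged within the description and then across the image's
  descriptions. The field sometimes reports the affinely equivalent
  *similarity*; we report distance, which PCA absorbs up to sign either
  way. Pairs touching an out-of-vocabulary word are skipped; an image with
  no valid pair anywhere is dropped from the semantic table with a warning
  rather than imputed.

Tokenization lowercases, replaces ASCII punctuation with spaces (so
hyphenated words split), splits on whitespace, and removes stopwords from a
list frozen in `inst/extdata/stopwords_en.txt`. The list is a snapshot of a
standard English function-word inventory, with one adjustment: spatial
prepositions ("over", "under", "above", "below", "behind") are *retained* as
content words, because in scene descriptions they carry spatial content —
"fox jumps over dog" loses its meaning without "over". Thus
`tokenize("The quick brown fox jumps over the lazy dog")` keeps 7 tokens,
which contribute exactly 21 word pairs to the distance metric.

## Unifying each triple: PCA

Each metric triple is collapsed to one score by projecting onto the first
principal component. Because the native scales differ by orders of magnitude
(edge counts ~10⁴, entropies ~10⁰), features are z-scored before PCA by
default; `standardize = FALSE` reproduces the covariance-based variant. How
much variance PC1 captures is a property of the dataset, not of the method,
and is reported by the fitted model object.

PCA leaves the component sign arbitrary, so we fix it with an anchor
convention: PC1 scores must correlate positively with edge density (visual)
or median description length (semantic). "Higher score = more information"
is then stable across runs and datasets.

## Behavioral reduction and the noise ceiling

`code_response()` maps "closer" to +1 (extension error): a memory with
extended boundaries makes the identical re-presentation look zoomed-in.
The forced-error literature does not always state this mapping explicitly,
so it is isolated in one function and reversible by the `convention`
argument; flipping it exactly negates every score.

The split-half noise ceiling repeatedly (default 10,000 iterations)
bipartitions participants at random (odd counts split ⌊n/2⌋/⌈n/2⌉),
computes per-image scores in each half, and regresses one half on the
other. The central 95% interval of the R² distribution bounds how much
variance any image-level model could explain. For a one-predictor
regression R² equals the squared Pearson correlation, and the code asserts
that identity on every iteration as a cheap internal oracle. Percentiles
use linear interpolation between order statistics (R's default type 7).
Images with no responses in one half of a split are dropped from that
iteration's regression.

## Regression battery and variance partitioning

`fit_ols()` wraps ordinary least squares with the summaries this analysis
reports: R², adjusted R² `= 1 − (1−R²)(n−1)/(n−p−1)`, the overall F test
with `(p, n−p−1)` degrees of freedom, and per-coefficient t and two-sided p
values. Predictors enter on their native scales — depth as supplied, the
info scores as PC1 projections — so coefficients are interpretable in input
units. No multiple-testing correction is applied, as none is part of the
analysis design.

`variance_partition()` fits exactly seven models (all three predictors;
each pair; each alone) and decomposes the full model's R² by
inclusion–exclusion into three unique, three pairwise-shared, and one
triple-shared component. The identity "components sum to the full-model
R²" is enforced at 1e−9 on every call. Suppression can make components
slightly negative; they are reported unclipped, since clipping would break
the identity.

## The synthetic-study generator

The generator exists so that every stage has an input with known ground
truth. Its defaults are the study conditions the pipeline is designed for:
120 images, 360 participants, depth uniform on a 1–5 rating scale, latent
information scores with SD 1.6 (the spread a z-scored three-feature PC1
typically has), generative coefficients on the boundary-score scale
(intercept 0.52; depth −0.13; semantic −0.03; visual −0.001), and residual
SD 0.09 — chosen once so that the depth baseline explains roughly
two-thirds of score variance and the per-image binomial sampling noise at
360 observers (~0.05 SD) sits inside a split-half ceiling near 0.7–0.8,
i.e. the regime this kind of study operates in.

True scores are `s = clip(β₀ + β_d·depth + β_s·sem + β_v·vis + ε, −1, 1)`;
clipping events are logged because frequent clipping would bias recovery
(the defaults keep them rare). Each observer's response is an extension
error with probability `(1+s)/2` — the unique binomial model whose
±1-coded mean is `s`, so `E[score] = s` and
`Var[score] = (1−s²)/n_participants` exactly.

Images are compositions of filled ellipses and rectangles: palette colors
sit at distinct A\*/B\* histogram bin centers (so palette size maps directly
onto occupied color bins) while L\* varies across palette entries (so shape
boundaries carry luminance contrast for the edge detector). Corpora are
Zipfian: each description draws a Poisson-distributed number of words, a
fixed ~30% of them stopwords, the rest from a power-law distribution over a
synthetic vocabulary. Embeddings place unit vectors around mutually
orthogonal cluster centroids, so cross-cluster pairs have cosine distance
near 1 and within-cluster pairs near 0. The per-image latent information
values drive the generator dials (shape count and palette size for visual;
description length and vocabulary size for semantic), so measured features
*correlate* with the latents by construction — but are not affine in them.
All randomness flows from one master seed through named substreams
(covariates / responses / corpus / embeddings / images), so stages can be
regenerated independently.

What the generator does *not* emulate: photographic content, category
structure, per-participant response biases, description spelling errors, or
phrase-level semantics. Passing tests on synthetic data therefore
demonstrate that the pipeline's statistics are correct and its stages
compose, not that real scenes behave this way.

### Parameter recovery, and what "running the pipeline" means for it

Because the measured features are monotone-but-not-affine functions of the
latents, the unified PC1 scores recover the latent information only up to a
monotone transform, and regression coefficients on measured PC1 scores are
not numerically comparable to the generative betas. Coefficient recovery is
therefore assessed on the pipeline from responses onward: simulate, reduce
responses to boundary scores with `score_boundary()`, and fit the
three-predictor model on the study's covariate table with `fit_ols()`. At
study scale (120 × 360) the fitted coefficients land within three standard
errors of the generative values in ≥95% of replicates; the feature→PCA
stages are validated separately by their own oracles and by checking that
measured PC1 scores correlate positively with the latent dials.

## Problem sizes used in the test suite

Unit tests run on small fixtures (images 64–352 px, corpora of ≤100
descriptions, studies of 10–15 images). The deeper checks use: 1000 random
distributions against the entropy oracle; 100 random instances each for the
PCA eigen-oracle and the partition identity; a 500-image × 100-participant
coin-flip study (1000 split iterations) for the null noise ceiling; and 20
study-scale replicates (120 × 360) for coefficient recovery. These sizes
give stable statistics while keeping the default suite fast; nothing in the
method depends on them.

## Known limitations

* The Canny and Gist implementations follow one published dialect each;
  other dialects (different blur-to-sigma rules, 4×4 Gist grids, contrast
  prefiltering) will produce different absolute values. Relative,
  within-dataset comparisons are the intended use.
* The chromatic histogram's fixed [−110, 110] range clips extreme
  saturations into end bins; for natural photographs this is rare.
* `mean_pairwise_distance` treats tokens independently; multi-word phrases
  are not re-joined even though news-corpus embeddings often contain them.
* The pipeline models per-image scores; participant-level structure
  (individual biases, learning) is outside its scope.
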
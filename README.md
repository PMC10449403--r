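# scenebudget

Scene memory has spatial biases: observers remember some scenes with wider
boundaries than were shown (boundary extension) and others with narrower
ones (boundary contraction). `scenebudget` is an R package for testing
whether those errors track a fixed budget of scene *information*: it
measures per-image visual and semantic information, reduces forced-error
"closer/farther" judgments to per-image boundary-transformation scores, and
models the scores against scene depth and the information measures.

It is written for vision/memory researchers running forced-error RSVP
boundary-transformation experiments, and for anyone who needs its building
blocks: image-complexity metrics, description-corpus statistics, split-half
reliability ceilings, or commonality (variance-partitioning) analysis.

## What it computes

**Visual information** per image (`compute_visual_features()`):

- *edge density* — edge-pixel count from a Canny detector (5×5 Gaussian
  blur, Sobel gradients, hysteresis thresholds 30/150);
- *color entropy* — Shannon entropy H = −Σ pᵢ log₂ pᵢ of the 20×20 joint
  histogram of the CIELAB A\*/B\* channels;
- *Gist entropy* — entropy of the 1152-dimensional normalized Gist
  descriptor (3 scales × 8/6/4 orientations × 8×8 grid).

**Semantic information** per image from ~100 free-text descriptions
(`compute_semantic_features()`):

- *median description length* (words);
- *lexical entropy* — entropy of the pooled word-type histogram after
  tokenization against a frozen stopword list;
- *mean pairwise embedding distance* — cosine distance 1 − cos θ averaged
  over all `choose(k, 2)` token pairs per description, under a pluggable
  word-embedding table.

Each triple is collapsed to a single information score by projecting onto
the first principal component (`unify_scores()`), sign-anchored so higher =
more information.

**Behavior and inference**: per-image boundary-transformation scores
s = (n_extension − n_contraction)/n (`score_boundary()`), a split-half
noise ceiling from repeated random bipartitions of participants
(`noise_ceiling()`), OLS regression with R²/adjusted R²/F/t summaries
(`fit_ols()`), and the seven-model variance partition decomposing the full
R² into unique and shared components (`variance_partition()`).

**Synthetic studies** (`generate_study()`): procedural images, Zipfian
description corpora, toy embeddings, and observer responses drawn from a
known linear model s = β₀ + β_d·depth + β_s·sem + β_v·vis + ε with
P(extension) = (1+s)/2 — so the whole pipeline can be exercised and
validated against ground truth without any external data.

## Worked example

Simulate a study at full scale (120 images × 360 participants) and run the
behavioral analysis:

```r
library(scenebudget)

cfg <- study_config(seed = 42)           # defaults: 120 x 360, betas
study <- generate_study(cfg, components = "responses")

scores <- score_boundary(study$responses)
merged <- merge(scores, study$covariates, by = "image_id")
fit <- fit_ols(merged$score, merged[, c("depth", "semantic_info", "visual_info")])
print(fit)
#> <ols_fit> n = 120, R^2 = 0.708 (adj 0.701), F(3, 116) = 93.78, p = 7.08e-31
#>                  coef        t      p
#> (Intercept)    0.4840  19.8215 0.0000
#> depth         -0.1185 -16.0679 0.0000
#> semantic_info -0.0293  -4.6729 0.0000
#> visual_info   -0.0050  -0.8576 0.3929

noise_ceiling(study$responses, n_iterations = 1000, seed = 42)
#> <noise_ceiling> 95% of 1000 splits: R^2 in [0.658, 0.776]

variance_partition(merged$score, merged$depth,
                   merged$semantic_info, merged$visual_info)
#> <variance_partition> total R^2 = 0.7081
#>           unique_depth        unique_semantic          unique_visual
#>                 0.6498                 0.0550                 0.0019
#>  shared_depth_semantic    shared_depth_visual shared_semantic_visual
#>                -0.0005                -0.0010                -0.0017
#>             shared_all
#>                 0.0048
```

The generative model used depth coefficient −0.13 and semantic coefficient
−0.03; the fit recovers −0.1185 and −0.0293, each within three standard
errors of truth. The regression R² (0.708) sits just inside the split-half
noise ceiling, and the partition shows depth carrying most of the explained
variance with a genuine unique semantic contribution — negative
boundary-score coefficients mean more depth / more semantic information →
more contraction.

The text side works on real strings:

```r
tokenize("The quick brown fox jumps over the lazy dog")
#> [1] "quick" "brown" "fox"   "jumps" "over"  "lazy"  "dog"
```

(7 content tokens, hence 21 word pairs enter the pairwise-distance metric).
For a fully end-to-end run from raw inputs — images, corpus, embeddings,
depth, responses — use `run_pipeline()`, which also accepts files via
`read_images()`, `read_descriptions()`, `read_embeddings()`, `read_depth()`
and `read_responses()`, or a directory written by `write_study()`.

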
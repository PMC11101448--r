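---
title: "Reverse correlation in deep feature space: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse correlation in deep feature space: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reprecon)
```

This vignette explains the statistical machinery in `reprecon`: what each
stage assumes, which knobs matter, where genuinely open design choices were
made, and what the synthetic-data tests do and do not establish about real
experiments.

## 1. The feature-space model

Reverse correlation needs a noise distribution to probe with. Instead of
pixel noise, `reprecon` samples the channel space of an image feature
extractor: `fit_feature_space()` takes a corpus of channel-mean activations
(one row per image) and models it in four steps.

1. **Standardization.** Each channel is centered and scaled by its corpus
   mean and standard deviation. The statistics always come from the fitting
   corpus, never from a sampled batch, so samples are exchangeable with
   corpus rows.
2. **Shrinkage covariance.** The channel correlation matrix is shrunk toward
   its diagonal with the Schäfer–Strimmer analytic intensity: the ratio of
   the summed estimated variances of the off-diagonal correlations to their
   summed squares, clipped to [0, 1]. This choice matters because channel
   counts can rival or exceed corpus sizes, where the raw covariance is
   ill-conditioned. The intensity is exposed (`shrinkage =`) for users who
   prefer a fixed value.
3. **ZCA whitening.** The whitening transform is the symmetric inverse
   square root of the shrunk covariance — the whitening that stays closest to
   the original channel basis — and the coloring transform is its exact
   inverse. Both identities (`W Σ W' = I`, `C W = I`) hold to 1e-8 by
   construction and are asserted in tests.
4. **Per-channel kernel densities.** In the whitened space, each channel gets
   a Gaussian kernel density with Scott's-rule bandwidth `sd * n^(-1/5)`
   (override: `bandwidth =`). Sampling draws a training point uniformly and
   adds Gaussian noise at the bandwidth scale — exact for Gaussian kernels.
   Zero bandwidth degenerates to resampling the training points, which the
   tests use as a boundary case.

Independent whitened draws are then colored and unstandardized, giving target
feature vectors whose second-order structure matches the shrunk corpus
covariance while each marginal follows its fitted density. The model is
deliberately second-order: higher-order dependencies between channels in the
corpus are not reproduced.

## 2. Image synthesis

Images are parameterized by complex 2-D Fourier coefficients per color
channel (`init_fourier_params()`, Gaussian initialization, sd 0.01).
Rendering applies:

- **1/f frequency scaling**, with the DC bin treated at the minimum nonzero
  frequency's scale to avoid division by zero, and the conventional
  `sqrt(h*w)` spectrum gain so that unit-scale coefficients produce
  unit-scale images;
- an **inverse FFT** (only the real part is used, so no conjugate-symmetry
  bookkeeping is needed);
- a **color decorrelation matrix** (3 x 3, applied per pixel). The identity is
  the default; `default_color_matrix()` ships a fixed mildly-correlated RGB
  Cholesky factor for realistic renders, and users supply a corpus-estimated
  matrix for faithful work;
- a **sigmoid display-range map** into (0, 1). A smooth squashing (rather
  than clamping) keeps the map differentiable and invertible on the open
  interval; zero coefficients render to a constant mid-gray (0.5) image.

Two objectives are optimized with Adam using *decoupled* weight decay
(defaults: learning rate 0.05, weight decay 0.1, beta1 0.9, beta2 0.999;
1500 iterations for stimuli, 2000 for reconstructions):

- `synthesize_stimulus()` minimizes the mean squared error between the
  image's channel means and the target vector;
- `reconstruct_image()` maximizes the caricature objective
  `<y, phi> (cos(y, phi))^alpha` with `alpha = 4` by default. The objective
  is 1-homogeneous in both arguments, reflecting that the magnitude of a
  recovered direction is arbitrary; only its orientation matters. Note the
  objective has a flat region where `<y, phi> = 0` (its gradient vanishes
  like `d^alpha`), so directions starting near orthogonality converge
  slowly — one reason reconstructions use more iterations.

During reconstruction each rendered image receives a random small rotation,
translation and homothecy before feature extraction (transformation
robustness). The ranges are open design choices, not inherited values:
±5 degrees, ±4 px, scale in [0.95, 1.05], uniform, bilinear interpolation
with edge padding, all exposed in `synthesis_config()`. The transforms are
implemented as sparse linear interpolation operators so that their adjoint
(needed for the gradient) is exactly the transpose.

One numerical choice deserves a note: Adam's denominator stabilizer defaults
to 1e-12 rather than the textbook 1e-8. Feature spaces whose channel means
are orders of magnitude below 1 produce gradients near or below 1e-8, where
a large epsilon silently freezes the optimization; a small epsilon keeps the
optimizer scale-invariant. It is configurable (`adam_epsilon =`).

All gradients — through the extractor stages, the transforms, and the render
pipeline — are analytic and are verified against finite differences in the
test suite.

## 3. Semantic responses

`clean_responses()` lowercases labels, removes stopwords (a compact default
list ships; any list can be supplied), single characters and numerals, and
spell-corrects words the embedding does not recognize within Levenshtein
distance 2. Correction ties are broken by priority-lexicon membership, then
corpus frequency if supplied, then lexicographically — the first rule is the
substantive one (visual words are preferred); the rest make the pipeline
deterministic. Multi-word labels recognized whole by the embedding are kept
as single tokens; otherwise they are split and cleaned per word. Every input
word appears exactly once in the audit log, and cleaning is idempotent.

`embed_trial()` averages the word vectors of a trial into a single semantic
vector, giving every trial equal weight regardless of how many labels it
received. `validate_participant()` implements the exclusion rule: a
participant is dropped when strictly more than 25% of their rated words have
concreteness below 4 (the boundary keeps the participant; unrated words are
ignored). Singular/plural equivalence — used only by the validation
analyses — strips a trailing "s"; this is a documented approximation, not
lemmatization.

## 4. The visual-semantic matrix and inference

Both spaces are reduced by centered, whitened PCA keeping the minimum number
of components whose cumulative explained variance reaches 0.9. The
coefficient matrix is `B = X'Y/(t - 1)` on the whitened scores. The
`1/(t - 1)` scale makes coefficients read as correlations; it differs from
the raw outer product only by a positive scalar, which affects neither
significance ranks nor direction-only reconstruction. The reverse projection
(features to semantics) uses `B'`; the two projections are exactly adjoint.
Trials with no valid response are excluded from fitting.

Inference uses the permutation max-statistic: semantic rows are shuffled
across trials, `B` is refit per permutation, each cell is z-scored against
its permutation null, and the observed |Z| values are compared with the null
distribution of per-permutation maxima of |Z| (two-tailed). Two calibration
details matter. First, each *null* matrix is z-scored against leave-one-out
moments, because moments that include the permutation itself deflate the null
maxima and make the test anti-conservative. Second, the critical value uses
the `+1` convention (the observed family counts as one more permutation).
With these choices the family-wise error rate measured over 500 simulated
global-null families sits at its nominal level; the acceptance script
recomputes this. P-values floor at `1/(n_perm + 1)`; cells with zero null
variance are flagged untestable rather than silently significant.

`bootstrap_concept_ci()` resamples trials with replacement and refits the
whole pipeline per resample (PCAs included; a fixed-PCA fast mode is
opt-in), reporting elementwise 2.5th/97.5th percentiles. Degenerate
resamples — a constant column — are redrawn and counted in the provenance.
`leave_concept_out_map()` removes responses (not whole trials, unless
emptied) matching a concept or its singular/plural form and refits; trials
emptied by the removal are dropped, a choice documented here because either
convention is defensible.

## 5. Downstream statistics

- **Semantic-content prediction**: cosine between predicted and observed
  trial semantics; null by resampling labels with replacement from the
  pooled labels of the tested stimuli.
- **Stimulus prediction**: stimuli are ranked by Pearson correlation with a
  concept's feature vector and the top `m` predicted positive, `m` being the
  true positive count; ties break by stimulus index. Overlap is scored by the
  Dice coefficient (two empty sets give 0 by convention), with a
  stimulus-permutation null and a max-statistic family correction.
- **RSA**: Spearman correlation of RDM upper triangles (correlation
  distance, `1 - r`); significance by jointly permuting rows and columns of
  the behavioral RDM; confidence intervals by resampling items with
  replacement, dropping the off-diagonal zeros duplicated items create.
  Rank-transformed RDMs from several observers are averaged with
  `average_rank_rdms()`.
- **Uniqueness**: split-half within-group versus between-group correlations
  of recovered representations over a reference concept list. The
  per-channel mean across reference concepts is removed before flattening;
  without this centering the shared offset every map recovers saturates both
  correlations and the statistic carries no signal.
- **2AFC validation**: per-concept accuracy with a participant bootstrap; a
  concept is significant when at least a Šidák-corrected fraction
  `(1 - alpha)^(1/m)` of its bootstrap distribution exceeds 50%. The
  correction formula is config-exposed because published usages differ in the
  per-tail convention. The optional refinement pass (10x resamples for
  concepts whose decision sits near the boundary) is opt-in. The mean-level
  chance model treats each 2AFC trial as correct with probability one half,
  which is what permuting the two response labels implies.
- **Label agreement**: most-common-label correctness (plural/singular
  equivalent), the least-squares slope of response frequency on semantic
  distance to the true label (one-tailed t test for a negative slope;
  degenerate zero-residual fits report the slope without a t statistic),
  response entropy in natural log (a choice, documented here), and the
  covariance trace of response embeddings with the unbiased `n - 1`
  estimator (single-response sets give 0 with a warning).
- **Real-versus-null comparisons**: four per-concept flags (correct-label
  frequency, semantic distance, entropy, covariance trace), all strict —
  ties count as failures. Label-dependent metrics are tested by permuting
  true labels across concepts; label-free metrics by permuting responses
  across images.
- **2-D maps**: `embed_2d()` is a compact exact t-SNE (perplexity calibrated
  by bisection, correlation distance, early exaggeration, seeded
  initialization) intended for the small concept sets these analyses
  produce — up to a few hundred items; it makes no attempt at Barnes–Hut
  scaling. Layouts are aligned across groups by orthogonal Procrustes
  (SVD-based, with translation and scaling), cross-checked against
  `vegan::procrustes` in the tests.

## 6. The synthetic world

`synthetic_world()` fixes a ground truth for end-to-end testing: a lexicon of
pronounceable pseudo-words with a clustered unit-sphere toy embedding, a true
linear mapping `W` (channels by semantic dimensions, entries `N(0, 1/v)` so
semantic images have unit scale), observer noise, and a labels-per-trial
distribution. Defaults are the standard study conditions: 40 concepts, 32
semantic dimensions, 64 channels, noise sd 0.5 (a moderate level relative to
the unit-scale semantic images), and label probabilities (0.25, 0.33, 0.42)
over 1–3 labels, giving a mean of 2.17 labels per trial — the rate typical of
open-label experiments of this kind. Simulated observers compute a noisy
semantic image `s = W'z` of the standardized stimulus features and emit
labels by sampling without replacement from a softmax (temperature 0.1 by
default) over cosine similarities between `s` and the lexicon vectors. The
simulator runs in feature space by default so full recovery suites finish in
seconds; routing stimuli through `synthesize_stimulus()` with a toy extractor
is possible but not required for any test.

What the simulator emulates: the linear visual-semantic structure, the
discreteness and multiplicity of labels, observer noise, lexicon geometry.
What it does not emulate: real embedding geometry (300-dimensional,
heavy-tailed co-occurrence structure), response biases and typos (cleaning is
exercised on separate handcrafted fixtures), participant heterogeneity, and
any pixel-level perception. Passing recovery tests therefore demonstrate that
the estimators invert the generative model they assume, at realistic sizes —
not that any particular human dataset would yield the same numbers.

One calibration is worth stating plainly: observers quantize the semantic
image into a handful of discrete labels, so a linear readout cannot invert
the argmax per trial. Per-trial semantic predictions rank the generating
concept near the top of the lexicon (the tests assert median rank within the
top 3 of 40 and first-rank far above chance on a fixed-seed world), and
*concept-level* recovery — which pools across trials — identifies the correct
concept essentially always at 2000 trials. Trial-level top-1 accuracy near 1
is not attainable under this observer model and is not claimed.

## 7. The toy extractor

`make_toy_extractor()` is a frozen random feature extractor: stages of
circular convolution (computed in the Fourier domain) with zero-sum kernels,
a smooth nonlinearity (tanh by default; softplus and linear available), and
channel-mean readout. Zero-sum kernels give no response to constant images,
so features behave as mean-free directions — negating a target direction
negates the reachable features (the map is odd under intensity inversion),
which is what makes the caricature negation property testable. It is a
fixture for exercising the synthesis machinery, not a model of any trained
network; any object implementing `extract_channel_features()` and
`extractor_gradient()` can be plugged in instead.

## 8. Problem sizes and reproducibility

The shipped tests and the acceptance script use: 500 simulated null families
(100 coefficients, 200 permutations) for the family-wise error calibration;
20 replicates of the standard synthetic world at 2000 and 200 trials for
parameter recovery; 32 x 32 images, 16 channels and 300 iterations for the
synthesis checks; and 1500 trials for the leave-concept-out and
binary-embedding agreements. These sizes give stable Monte-Carlo estimates
while keeping a full run in the tens of seconds on one CPU. Every stochastic
routine draws through `with_seed()`, which restores the caller's RNG state,
and derives per-stage streams with `child_seed()`; identical seeds give
byte-identical outputs on one platform.

## 9. Known limitations

- The visual-semantic map is linear; systematic nonlinear structure in the
  feature-to-semantics relation is only captured up to its linear part.
- Serialization uses directories of CSV and JSON (plain text, 17 significant
  digits) rather than a binary array container.
- Spell correction considers single-token candidates only, and
  singular/plural matching is a suffix heuristic.
- The exact t-SNE implementation is quadratic in the number of items.
- The KDE sampler treats whitened channels as independent; only second-order
  structure is restored by coloring.
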
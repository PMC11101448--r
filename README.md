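# reprecon

Reverse correlation in deep feature space: infer and visualize the visual
features associated with verbal concepts from open-ended labeling behavior.

## The problem

Classical reverse correlation shows observers pixel noise and averages the
noise fields associated with their responses, revealing the internal template
behind a judgment. That works for simple, fixed-pixel targets but not for
natural categories, which are defined by abstract features invariant to image
transformations. `reprecon` generalizes the paradigm in both directions:

- **Stimuli** are "feature noise" rather than pixel noise: pseudo-random
  target vectors are drawn in the channel space of a differentiable image
  feature extractor (after standardization, shrinkage covariance estimation
  and ZCA whitening), and images are optimized so that their channel-mean
  activations match those targets.
- **Responses** are open-ended labels (1–3 words per trial) mapped into a
  word-embedding space and averaged into one semantic vector per trial.

The two spaces are linked by the **visual-semantic matrix**

```
B = X' Y / (t - 1)
```

the outer product of the trial-by-visual-PC and trial-by-semantic-PC score
matrices (both PCAs whitened, retaining the smallest number of components
explaining 90% of variance). With whitened scores this equals the
least-squares solution of the multivariate regression of semantic scores on
visual scores, and each coefficient reads as a correlation. Coefficients are
tested with a permutation **max-statistic** procedure (trial labels shuffled,
family-wise error controlled by the null distribution of the maximum |Z|).

Any concept in the embedding vocabulary — including words never produced in
the experiment — can then be projected through `B` to obtain its associated
feature vector, and visualized by maximizing the **caricature objective**

```
p* = argmax_p  <y, phi(p)> * ( <y, phi(p)> / (||y|| ||phi(p)||) )^alpha
```

over a Fourier-parameterized image with transformation robustness (random
small rotations, translations and homothecies each step), using Adam with
decoupled weight decay. Downstream statistics cover semantic-content
prediction (cosine similarity with label-resampling nulls), stimulus
prediction (Dice overlap with permutation nulls), representational similarity
analysis (Spearman correlation of RDM upper triangles with row/column
permutation tests and item bootstraps), split-half uniqueness analysis,
2AFC validation with participant bootstrap and Šidák correction, and
open-label agreement metrics. A seeded synthetic-world simulator makes every
stage testable end to end with no external data.

## Worked example

```r
library(reprecon)

# a synthetic world: 40 concepts, 32 semantic dims, 64 feature channels
world <- synthetic_world(seed = 42)
fm    <- world_feature_model(world, seed = 43)
sim   <- simulate_experiment(world, fm, t = 1000, seed = 44)
#> <simulated_trials: 1000 trials, 64 channels, 10 participants>

cleaned <- clean_responses(sim$responses, world$embedding)
sems    <- embed_trials(cleaned$responses, world$embedding)
ids     <- intersect(rownames(sim$features), sems$trial_id)
map     <- fit_concept_map(sim$features[ids, ], semantic_matrix(sems)[ids, ])
glance(map)
#> # A tibble: 1 x 5
#>   n_trials k_visual k_semantic visual_variance semantic_variance
#> 1     1000       49         17           0.907             0.904
```

49 visual and 17 semantic components each explain just over 90% of their
space's variance. Which coefficients of the 49 x 17 matrix are reliable?

```r
X   <- pca_transform(map$visual_pca, sim$features[ids, ])
Y   <- pca_transform(map$semantic_pca, semantic_matrix(sems)[ids, ])
ens <- build_null_ensemble(X, Y, n_perm = 500, seed = 45)
test_coefficients(map, ens)
#> <coef_test: 23 of 833 coefficients significant
#>  (FWER alpha = 0.05, critical |Z| = 4.14)>
```

23 visual-semantic associations survive the family-wise correction. Recover
a concept's feature vector, check what it means, and compare it with the
simulator's ground truth:

```r
word <- world$lexicon[1]
rep  <- concept_to_features(word, world$embedding, map)
nearest_words(features_to_semantics(rep$features, map),
              world$embedding, world$lexicon, k = 3)
#> # A tibble: 3 x 3
#>   word   similarity  rank
#> 1 bababa      0.551     1    # the concept itself ranks first
#> 2 debaba      0.550     2
#> 3 tibaba      0.404     3

cor((rep$features - fm$mean) / fm$sd, world$true_features[, word])
#> [1] 0.53
```

The recovered vector can be rendered with `reconstruct_image()` against any
differentiable extractor (a small frozen-convolution toy extractor ships for
experimentation; see `make_toy_extractor()`), `autoplot()` methods visualize
maps, tests and optimization traces, and `run_workflow()` /
`inst/cli/reprecon` chain the stages from the command line.

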
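# Parameter-recovery machinery shared by the mapping and acceptance tests.

# Recover standardized feature vectors for every lexicon concept through a
# fitted map, vectorized over concepts.
recover_matrix <- function(map, world, feature_model) {
  S <- pca_transform(map$semantic_pca, world$embedding$vectors)
  Fm <- pca_inverse(map$visual_pca, S %*% t(map$B))
  Fz <- sweep(sweep(Fm, 2, feature_model$mean, "-"), 2, feature_model$sd, "/")
  t(Fz)   # v x m
}

# One synthetic-world recovery replicate: simulate, fit, and compare matched
# recovery correlations against a label-permutation null.
recovery_replicate <- function(t, seed, n_perm = 100, world_args = list()) {
  w <- do.call(synthetic_world, c(list(seed = child_seed(seed, 1)), world_args))
  fm <- world_feature_model(w, seed = child_seed(seed, 2))
  dat <- simulate_and_embed(w, fm, t, seed = child_seed(seed, 3))
  map <- fit_concept_map(dat$features, dat$semantics)
  rec <- recover_matrix(map, w, fm)
  matched <- vapply(seq_len(w$m), function(ci) {
    cor(rec[, ci], w$true_features[, ci])
  }, numeric(1))

  X <- pca_transform(map$visual_pca, dat$features)
  Y <- pca_transform(map$semantic_pca, dat$semantics)
  t_n <- nrow(X)
  S <- pca_transform(map$semantic_pca, w$embedding$vectors)
  null_cors <- with_seed(child_seed(seed, 4), {
    vapply(seq_len(n_perm), function(p) {
      Bp <- crossprod(X, Y[sample.int(t_n), , drop = FALSE]) / (t_n - 1)
      Fp <- pca_inverse(map$visual_pca, S %*% t(Bp))
      Fpz <- sweep(sweep(Fp, 2, fm$mean, "-"), 2, fm$sd, "/")
      vapply(seq_len(w$m), function(ci) {
        cor(Fpz[ci, ], w$true_features[, ci])
      }, numeric(1))
    }, numeric(w$m))
  })
  crit <- apply(null_cors, 1, quantile, probs = 0.95)
  list(matched = matched, beat_null = matched > crit,
       mean_cor = mean(matched))
}
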
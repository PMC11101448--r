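# Shared fixtures, all generated in code.

# Small handcrafted embedding with known geometry for semantics tests.
test_embedding <- function() {
  words <- c("dog", "cat", "grass", "sky", "tree", "water", "polar", "bear",
             "bird", "house")
  set.seed(42)
  vecs <- matrix(rnorm(length(words) * 6), length(words), 6)
  embedding_model(words, vecs)
}

# Standard small synthetic world + feature model for pipeline tests.
test_world <- function(m = 12, d = 8, v = 16, noise_sd = 0.3, seed = 7, ...) {
  synthetic_world(m = m, d = d, v = v, noise_sd = noise_sd,
                  n_clusters = max(2, m %/% 4), seed = seed, ...)
}

# Simulate, embed responses (generator emits in-vocabulary words, so the
# cleaned table is built directly), and align features with trial vectors.
simulate_and_embed <- function(world, feature_model, t, seed) {
  sim <- simulate_experiment(world, feature_model, t, seed = seed)
  long <- tidyr::pivot_longer(sim$responses, dplyr::starts_with("label_"),
                              values_to = "word")
  long <- long[!is.na(long$word), c("trial_id", "participant_id", "word")]
  sems <- embed_trials(long, world$embedding)
  ids <- intersect(rownames(sim$features), sems$trial_id)
  list(
    sim = sim,
    cleaned = long,
    features = sim$features[ids, , drop = FALSE],
    semantics = semantic_matrix(sems)[ids, , drop = FALSE]
  )
}

# Recovered concept vectors for every lexicon word, standardized to the
# feature model's channel scale, as a v x m matrix.
recover_all_concepts <- function(map, world, feature_model) {
  vapply(world$lexicon, function(w) {
    f <- concept_to_features(w, world$embedding, map)$features
    (f - feature_model$mean) / feature_model$sd
  }, numeric(world$v))
}

# Fixed 32x32 toy synthesis fixture shared by synthesis and acceptance tests.
synthesis_fixture <- function() {
  extractor <- make_toy_extractor(16, 32, seed = 5)
  corpus <- t(vapply(1:80, function(i) {
    img <- render_image(init_fourier_params(32, seed = 1000 + i, scale = 0.5))
    extract_channel_features(img, extractor, "conv1")
  }, numeric(16)))
  model <- fit_feature_space(corpus)
  list(extractor = extractor, corpus = corpus, model = model,
       target = sample_target_features(model, 1, seed = 7)[1, ])
}
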
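# PCA, the outer-product visual-semantic matrix, and projections through it.

test_that("PCA retains the minimum components reaching the variance threshold", {
  # collinear points: one component explains everything
  line <- cbind(1:20, 2 * (1:20) + 3)
  p <- fit_pca(line)
  expect_equal(p$k, 1)
  expect_equal(sum(p$explained[1]), 1, tolerance = 1e-12)

  # exact sample variances 9 and 1, uncorrelated: first PC explains exactly 90%
  set.seed(5)
  a <- rnorm(50); b <- rnorm(50)
  a <- resid(lm(a ~ b))                       # force zero correlation
  a <- 3 * a / sd(a); b <- b / sd(b)
  p2 <- fit_pca(cbind(a, b), variance_threshold = 0.9)
  expect_equal(p2$k, 1)
  expect_equal(p2$explained[1], 0.9, tolerance = 1e-10)

  expect_error(fit_pca(matrix(1, 1, 3)), "2 rows")
  expect_error(fit_pca(matrix(1, 5, 3)), "Zero total variance")
})

test_that("PCA components are orthonormal and inverse recovers the retained subspace", {
  set.seed(6)
  x <- matrix(rnorm(300), 50, 6) %*% (diag(6) + 0.5)
  p <- fit_pca(x, variance_threshold = 1)   # keep everything
  expect_lt(max(abs(crossprod(p$rotation) - diag(p$k))), 1e-8)
  expect_lt(max(abs(pca_inverse(p, pca_transform(p, x)) - x)), 1e-8)
  # whitened scores have unit variance on the fitting data
  expect_equal(unname(apply(pca_transform(p, x), 2, var)), rep(1, p$k),
               tolerance = 1e-10)
})

test_that("outer product on whitened scores equals the least-squares solution", {
  set.seed(7)
  t_n <- 120
  xr <- matrix(rnorm(t_n * 8), t_n, 8)
  yr <- xr[, 1:5] %*% matrix(rnorm(20), 5, 4) + matrix(rnorm(t_n * 4), t_n, 4)
  xp <- fit_pca(xr, 1); yp <- fit_pca(yr, 1)
  X <- pca_transform(xp, xr); Y <- pca_transform(yp, yr)
  map <- fit_visual_semantic(X, Y, xp, yp)
  ols <- solve(crossprod(X), crossprod(X, Y))          # normal equations
  expect_lt(max(abs(map$B - ols)), 1e-10)
  expect_error(fit_visual_semantic(X[1, , drop = FALSE], Y[1, , drop = FALSE]),
               "2 aligned trials")
  expect_error(fit_visual_semantic(X, Y[1:10, ]), "differ")
})

test_that("independent scores give coefficients bounded like a null", {
  set.seed(8)
  t_n <- 5000
  X <- scale(matrix(rnorm(t_n * 6), t_n, 6))
  Y <- scale(matrix(rnorm(t_n * 5), t_n, 5))
  B <- fit_visual_semantic(X, Y)$B
  expect_lt(max(abs(B)), 4 / sqrt(t_n))
})

test_that("forward and reverse projections are adjoint through B", {
  set.seed(9)
  w <- test_world()
  fm <- world_feature_model(w, seed = 2)
  dat <- simulate_and_embed(w, fm, 250, seed = 3)
  map <- fit_concept_map(dat$features, dat$semantics)
  for (r in 1:5) {
    s <- rnorm(ncol(map$B)); v <- rnorm(nrow(map$B))
    expect_equal(sum((map$B %*% s) * v), sum(s * (t(map$B) %*% v)),
                 tolerance = 1e-12)
  }
})

test_that("identity-map projections reduce to the identity", {
  d <- 4
  B <- diag(d)
  map <- fit_visual_semantic(diag(d) * sqrt(1), diag(d))  # placeholder scores
  map$B <- B
  vec <- rnorm(d)
  rep <- reprecon:::semantic_vector_to_features(vec, map)
  expect_equal(unname(rep), vec, tolerance = 1e-12)
  expect_equal(unname(features_to_semantics(vec, map)), vec, tolerance = 1e-12)
})

test_that("zero features map to the semantic mean through centered PCAs", {
  set.seed(10)
  f <- matrix(rnorm(400, mean = 2), 50, 8)
  s <- matrix(rnorm(300, mean = -1), 50, 6)
  map <- fit_concept_map(f, s, variance_threshold = 0.9)
  out <- features_to_semantics(colMeans(f), map)   # visual mean -> zero scores
  expect_equal(unname(out), unname(colMeans(s)), tolerance = 1e-10)
})

test_that("concept recovery identifies the generating concept in a noiseless world", {
  # standard 40-concept world with noiseless observers
  w <- synthetic_world(noise_sd = 0, seed = 3)
  fm <- world_feature_model(w, seed = 4)
  dat <- simulate_and_embed(w, fm, 2000, seed = 5)
  map <- fit_concept_map(dat$features, dat$semantics)
  rec <- recover_all_concepts(map, w, fm)          # v x m, standardized
  truth <- w$true_features
  hits <- vapply(seq_len(w$m), function(ci) {
    cors <- cor(rec[, ci], truth)
    which.max(cors) == ci
  }, logical(1))
  expect_gte(mean(hits), 0.9)
  expect_error(concept_to_features("notaword", w$embedding, map), "vocabulary")
})

test_that("recovered trial semantics rank the generating concept highly", {
  # Observers quantize the semantic image into discrete labels, so a linear
  # readout cannot invert the argmax per trial; the generating concept must
  # nevertheless rank near the top of the 40-word lexicon far above chance.
  # Thresholds calibrated once on this fixed-seed fixture.
  w <- synthetic_world(noise_sd = 0, label_probs = c(1, 0, 0),
                       temperature = 0, seed = 3)
  fm <- world_feature_model(w, seed = 4)
  dat <- simulate_and_embed(w, fm, 2000, seed = 5)
  map <- fit_concept_map(dat$features, dat$semantics)
  ids <- rownames(dat$features)[1:100]
  word_of <- setNames(dat$cleaned$word, dat$cleaned$trial_id)
  ranks <- vapply(ids, function(id) {
    sem <- features_to_semantics(dat$features[id, ], map)
    nw <- nearest_words(sem, w$embedding, w$lexicon, k = w$m)
    which(nw$word == word_of[[id]])
  }, numeric(1))
  expect_gte(mean(ranks == 1), 0.3)     # chance is 1/40
  expect_lte(median(ranks), 3)
})
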
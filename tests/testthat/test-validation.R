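# Validation-experiment analyses: 2AFC bootstrap with Sidak correction,
# open-label agreement metrics, real-versus-null comparisons, uniqueness.

test_that("2AFC validation flags perfect concepts and respects the Sidak level", {
  set.seed(24)
  resp <- cbind(
    perfect = rep(1, 40),
    good = rbinom(40, 1, 0.9),
    chance = rbinom(40, 1, 0.5)
  )
  out <- twoafc_validation(resp, n_boot = 2000, n_perm = 200, seed = 9)
  pc <- out$per_concept
  expect_true(pc$significant[pc$concept == "perfect"])
  expect_equal(pc$accuracy[pc$concept == "perfect"], 1)
  expect_false(pc$significant[pc$concept == "chance"])
  expect_equal(out$sidak_level, 0.95^(1 / 3))
  expect_error(twoafc_validation(matrix(2, 3, 3)), "binary")
})

test_that("fair-coin responding stays below the Sidak false-positive budget", {
  set.seed(25)
  n_p <- 50; n_c <- 350
  resp <- matrix(rbinom(n_p * n_c, 1, 0.5), n_p, n_c)
  out <- twoafc_validation(resp, n_boot = 2000, n_perm = 100, seed = 10)
  # expected false positives at alpha 0.05 over the family: about 0.05
  expect_lte(sum(out$per_concept$significant), 2)
  expect_gt(out$mean_p, 0.05)
})

test_that("label agreement metrics match closed forms on hand data", {
  emb <- test_embedding()
  # all responses equal the true label
  all_same <- label_agreement_metrics(rep("dog", 8), "dog", emb)
  expect_true(all_same$most_common_correct)
  expect_equal(all_same$entropy, 0)
  expect_equal(all_same$trace, 0)
  # uniform over k labels: entropy ln k
  k3 <- label_agreement_metrics(c("dog", "cat", "sky"), "dog", emb)
  expect_equal(k3$entropy, log(3), tolerance = 1e-12)
  # plural/singular equivalence
  plural <- label_agreement_metrics(c("dogs", "dogs", "cat"), "dog",
                                    embedding_model(c("dogs", "cat", "dog"),
                                                    matrix(rnorm(9), 3, 3)))
  expect_true(plural$most_common_correct)
  expect_error(label_agreement_metrics("dog", "notaword", emb), "vocabulary")
})

test_that("the distance-frequency slope matches the normal-equations oracle", {
  # hand-built embedding: true label at (1, 0); responses at controlled
  # cosine distances 0.1, 0.5, 0.9 with frequencies 10, 5, 1
  ang <- acos(1 - c(0.1, 0.5, 0.9))
  words <- c("true", "near", "mid", "far")
  vecs <- rbind(c(1, 0), cbind(cos(ang), sin(ang)))
  emb <- embedding_model(words, vecs)
  responses <- rep(c("near", "mid", "far"), c(10, 5, 1))
  out <- suppressWarnings(   # 3 points fit exactly: summary.lm warns
    label_agreement_metrics(responses, "true", emb)
  )
  d <- c(0.1, 0.5, 0.9); f <- c(10, 5, 1)
  slope_oracle <- sum((d - mean(d)) * (f - mean(f))) / sum((d - mean(d))^2)
  expect_equal(out$slope, slope_oracle, tolerance = 1e-8)
  expect_lt(out$slope, 0)
  expect_lt(out$slope_p, 0.05)
})

test_that("real-vs-null comparison sets flags strictly and tests by permutation", {
  emb <- test_embedding()
  concepts <- c("c1", "c2", "c3", "c4")
  labels <- setNames(c("dog", "cat", "sky", "tree"), concepts)
  mk <- function(cc, role, img, words) {
    tibble::tibble(concept = cc, image_role = role, image_id = img,
                   response = words)
  }
  # real reconstructions always labeled correctly; nulls never
  resp <- dplyr::bind_rows(lapply(concepts, function(cc) {
    dplyr::bind_rows(
      mk(cc, "real", "r", rep(labels[[cc]], 5)),
      mk(cc, "null", "n1", sample(c("grass", "water", "house"), 5, TRUE)),
      mk(cc, "null", "n2", sample(c("bird", "bear", "polar"), 5, TRUE))
    )
  }))
  out <- real_vs_null_comparison(resp, labels, emb, n_perm = 100, n_boot = 100,
                                 seed = 11)
  expect_equal(unname(out$counts), rep(4, 4))
  expect_true(all(out$p < 0.2))
  expect_equal(dim(out$ci), c(4L, 2L))

  # identical response distributions: ties fail every flag
  tied <- dplyr::bind_rows(lapply(concepts, function(cc) {
    dplyr::bind_rows(
      mk(cc, "real", "r", c("grass", "water")),
      mk(cc, "null", "n1", c("grass", "water"))
    )
  }))
  out_tied <- real_vs_null_comparison(tied, labels, emb, n_perm = 20,
                                      n_boot = 20, seed = 12)
  expect_equal(unname(out_tied$counts), rep(0, 4))
})

test_that("uniqueness is zero for identical groups and positive for distinct worlds", {
  # identical data in both groups with identical halves: within == between
  w <- synthetic_world(m = 8, d = 6, v = 10, noise_sd = 0, n_clusters = 8,
                       seed = 7)
  fm <- world_feature_model(w, seed = 26)
  dat <- simulate_and_embed(w, fm, 160, seed = 27)
  n <- nrow(dat$features)
  halves <- list(a = list(1:(n / 2), (n / 2 + 1):n),
                 b = list(1:(n / 2), (n / 2 + 1):n))
  u_same <- uniqueness_analysis(dat$features, dat$semantics,
                                dat$features, dat$semantics,
                                reference = w$lexicon,
                                embedding = w$embedding,
                                n_perm = 30, n_boot = 0, seed = 13,
                                halves = halves)
  expect_equal(u_same$within, u_same$between, tolerance = 1e-12)
  expect_equal(u_same$difference, 0, tolerance = 1e-12)

  # two worlds with distinct ground-truth mappings: within > between
  w2 <- synthetic_world(m = 8, d = 6, v = 10, noise_sd = 0, n_clusters = 8,
                        seed = 99)
  w2$embedding <- w$embedding; w2$lexicon <- w$lexicon  # shared lexicon
  w2$true_features <- w2$W %*% t(w$embedding$vectors)
  dat2 <- simulate_and_embed(w2, fm, 160, seed = 28)
  u_diff <- uniqueness_analysis(dat$features, dat$semantics,
                                dat2$features, dat2$semantics,
                                reference = w$lexicon,
                                embedding = w$embedding,
                                n_perm = 60, n_boot = 0, seed = 14)
  expect_gt(u_diff$within, u_diff$between)
  expect_lt(u_diff$p, 0.05)

  # one world, two independent observer samples: no significant difference
  dat3 <- simulate_and_embed(w, fm, 160, seed = 55)
  u_null <- uniqueness_analysis(dat$features, dat$semantics,
                                dat3$features, dat3$semantics,
                                reference = w$lexicon,
                                embedding = w$embedding,
                                n_perm = 60, n_boot = 0, seed = 15)
  expect_gt(u_null$p, 0.05)
})

test_that("pairwise uniqueness averages over group pairs", {
  w <- synthetic_world(m = 8, d = 6, v = 10, noise_sd = 0.1, n_clusters = 8,
                       seed = 8)
  fm <- world_feature_model(w, seed = 29)
  gs <- lapply(1:3, function(i) {
    d <- simulate_and_embed(w, fm, 120, seed = 30 + i)
    list(features = d$features, semantics = d$semantics)
  })
  names(gs) <- c("g1", "g2", "g3")
  out <- uniqueness_pairwise(gs, w$lexicon[1:4], w$embedding, n_perm = 20,
                             seed = 15)
  expect_equal(nrow(out$pairs), 3)
  expect_equal(out$within, mean(out$pairs$within))
})
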
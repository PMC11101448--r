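# Dice overlap, stimulus prediction, RDMs and representational similarity.

test_that("Dice coefficient matches hand counts and set axioms", {
  expect_equal(dice_coefficient(1:3, 1:3), 1)
  expect_equal(dice_coefficient(1:3, 4:6), 0)
  expect_equal(dice_coefficient(1:3, 2:4), 2 * 2 / 6)   # 0.6667
  expect_equal(dice_coefficient(integer(0), integer(0)), 0)
  set.seed(15)
  for (r in 1:10) {
    a <- sample(1:20, sample(1:8, 1))
    b <- sample(1:20, sample(1:8, 1))
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
    expect_gte(dice_coefficient(a, b), 0)
    expect_lte(dice_coefficient(a, b), 1)
    expect_equal(dice_coefficient(a, b) == 1, setequal(a, b))
  }
})

test_that("stimulus prediction scores hand-built cases and nulls correctly", {
  set.seed(16)
  feats <- matrix(rnorm(4 * 6), 4, 6)
  concept <- feats[1, ] + feats[2, ]          # correlates with stimuli 1-2
  truth <- c(TRUE, TRUE, FALSE, FALSE)
  out <- predict_stimuli_for_concept(concept, feats, truth, n_perm = 200,
                                     seed = 1)
  # 2 positives; hand evaluation: 1 hit out of 2 predicted -> Dice 0.5 or 1
  expect_equal(out$dice, dice_coefficient(which(out$predicted), which(truth)))
  # perfect ranking gives Dice 1
  r <- rank(-out$correlations)
  perfect_truth <- r <= 2
  out2 <- predict_stimuli_for_concept(concept, feats, perfect_truth,
                                      n_perm = 100, seed = 1)
  expect_equal(out2$dice, 1)
  expect_error(predict_stimuli_for_concept(concept, feats, rep(FALSE, 4)),
               "positive")
  expect_error(predict_stimuli_for_concept(concept, feats, rep(TRUE, 4)),
               "all-positive")
  # random truth: z near zero on average
  feats_big <- matrix(rnorm(60 * 6), 60, 6)
  zs <- vapply(1:10, function(r) {
    tr <- sample(c(rep(TRUE, 20), rep(FALSE, 40)))
    predict_stimuli_for_concept(concept = rnorm(6), feats_big, tr,
                                n_perm = 200, seed = r)$z
  }, numeric(1))
  expect_true(all(abs(zs) < 3))
})

test_that("a hand-built prediction with 2 positives and 1 hit gives Dice 0.5", {
  feats <- diag(4)[, 1:4] %*% diag(4)   # 4 orthogonal stimuli
  feats <- matrix(c(1, 0, 0, 0,
                    0, 1, 0, 0,
                    0, 0, 1, 0,
                    0, 0, 0, 1), 4, 4, byrow = TRUE) + 0.01 * matrix(rnorm(16), 4)
  concept <- c(1, 0.5, 0, 0)            # ranks stimuli 1, 2 on top
  truth <- c(TRUE, FALSE, TRUE, FALSE)  # positives 1 and 3 -> one hit
  out <- predict_stimuli_for_concept(concept, feats, truth, n_perm = 50,
                                     seed = 2)
  expect_equal(out$dice, 0.5)
})

test_that("family-wise stimulus prediction corrects across concepts", {
  set.seed(17)
  feats <- matrix(rnorm(40 * 8), 40, 8)
  concepts <- list(a = feats[1, ] + feats[2, ], b = rnorm(8))
  truth <- cbind(a = seq_len(40) %in% order(-cor(t(feats), concepts$a))[1:10],
                 b = sample(c(rep(TRUE, 10), rep(FALSE, 30))))
  fam <- predict_stimuli_family(concepts, feats, truth, n_perm = 200, seed = 3)
  expect_equal(nrow(fam), 2)
  expect_lt(fam$p_fwer[1], 0.05)   # planted concept
  expect_equal(fam$dice[1], 1)
})

test_that("RDMs hold correlation distances with the required symmetries", {
  v <- rnorm(10)
  m <- rbind(v, v, -v, rnorm(10))
  rdm <- build_rdm(m, labels = c("a", "b", "c", "d"))
  d <- rdm$distances
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 2)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 2))
  # brute-force oracle on 3 hand vectors
  h <- matrix(c(1, 2, 3, 1, 0, -1, 2, 2, 1), 3, 3, byrow = TRUE)
  r3 <- build_rdm(h)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(r3$distances[i, j], 1 - cor(h[i, ], h[j, ]))
  }
  expect_error(build_rdm(m[1:2, ]), "3 items")
  expect_error(build_rdm(rbind(rep(1, 5), rnorm(5), rnorm(5))), "Constant")
})

test_that("RSA is rank-invariant, self-correlates at 1, and validates labels", {
  set.seed(18)
  m <- matrix(rnorm(8 * 12), 8, 12)
  rownames(m) <- letters[1:8]
  rdm <- build_rdm(m)
  self <- rsa_compare(rdm, rdm, n_perm = 50, n_boot = 50, seed = 4)
  expect_equal(self$rho, 1)
  # monotone transform of distances leaves rho unchanged
  mono <- rdm
  mono$distances <- rdm$distances^3 + 2 * rdm$distances
  other <- build_rdm(matrix(rnorm(8 * 12), 8, 12, byrow = TRUE),
                     labels = letters[1:8])
  expect_equal(rsa_compare(rdm, other, n_perm = 10, n_boot = 10, seed = 5)$rho,
               rsa_compare(mono, other, n_perm = 10, n_boot = 10, seed = 5)$rho)
  bad <- build_rdm(m, labels = LETTERS[1:8])
  expect_error(rsa_compare(rdm, bad), "labels")
})

test_that("RSA permutation p-values are roughly uniform under independence", {
  set.seed(19)
  ps <- vapply(1:60, function(r) {
    a <- build_rdm(matrix(rnorm(10 * 6), 10, 6))
    b <- build_rdm(matrix(rnorm(10 * 6), 10, 6))
    rsa_compare(a, b, n_perm = 99, n_boot = 0, seed = r)$p
  }, numeric(1))
  # permutation p-values take discrete values; jitter within a grid step
  # to apply the continuous KS test
  ps <- ps - runif(length(ps), 0, 1 / 100)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("RSA difference test is centered for identical models", {
  set.seed(20)
  m <- matrix(rnorm(9 * 7), 9, 7)
  a <- build_rdm(m)
  beh <- build_rdm(matrix(rnorm(9 * 7), 9, 7), labels = a$labels)
  d <- rsa_difference(a, a, beh, n_perm = 100, seed = 6)
  expect_equal(d$difference, 0)
  expect_equal(d$p, 1)
})

test_that("rank-averaged RDMs preserve the common ordering", {
  set.seed(21)
  base <- build_rdm(matrix(rnorm(6 * 5), 6, 5))
  warped <- base
  warped$distances <- base$distances^2      # same ranks
  avg <- average_rank_rdms(list(base, warped))
  expect_equal(rank(upper_tri_vec(avg$distances)),
               rank(upper_tri_vec(base$distances)))
})

test_that("semantic-content prediction returns cosine 1 for a perfect map", {
  emb <- test_embedding()
  d <- emb$d
  # identity map: features ARE semantic vectors
  map <- fit_visual_semantic(diag(d), diag(d))
  map$B <- diag(d)
  feats <- emb$vectors[c("dog", "cat", "sky"), ]
  rownames(feats) <- paste0("t", 1:3)
  cleaned <- tibble::tibble(trial_id = paste0("t", 1:3),
                            word = c("dog", "cat", "sky"))
  out <- predict_semantic_content(feats, cleaned, emb, map, n_null = 50,
                                  seed = 7)
  expect_equal(out$per_image$cosine, rep(1, 3), tolerance = 1e-12)
  expect_gt(out$z, 2)
  expect_lt(out$p, 0.05)
})

test_that("semantic-content prediction beats its label-resampling null in a synthetic world", {
  w <- synthetic_world(noise_sd = 0.3, seed = 31)
  fm <- world_feature_model(w, seed = 32)
  dat <- simulate_and_embed(w, fm, 800, seed = 33)
  hold <- 1:5
  map <- fit_concept_map(dat$features[-hold, ], dat$semantics[-hold, ])
  ids <- rownames(dat$features)[hold]
  out <- predict_semantic_content(
    dat$features[hold, , drop = FALSE],
    dat$cleaned[dat$cleaned$trial_id %in% ids, ],
    w$embedding, map, n_null = 200, seed = 8
  )
  expect_gt(out$mean, out$null_mean)
  expect_lt(out$p, 0.05)
})
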
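# Response cleaning, trial embedding, and participant validation.

test_that("cleaning removes stopwords, single characters and numerals", {
  emb <- test_embedding()
  raw <- tibble::tibble(trial_id = "t1",
                        label = c("the", "s", "42", "dog"))
  out <- clean_responses(raw, emb)
  expect_equal(out$responses$word, "dog")
  expect_equal(nrow(out$audit), 4)
  expect_setequal(out$audit$action, c("dropped", "kept"))
  expect_equal(sum(out$audit$action == "kept"), 1)
})

test_that("misspellings are corrected within edit distance 2, others dropped", {
  emb <- test_embedding()
  raw <- tibble::tibble(trial_id = c("t1", "t1", "t2"),
                        label = c("dgo", "xqzvw", "grsas"))
  out <- clean_responses(raw, emb)
  expect_equal(sort(out$responses$word), c("dog", "grass"))
  aud <- out$audit
  expect_equal(aud$action[aud$original == "dgo"], "corrected")
  expect_equal(aud$replacement[aud$original == "dgo"], "dog")
  expect_equal(aud$action[aud$original == "xqzvw"], "dropped")
  expect_equal(aud$reason[aud$original == "xqzvw"], "unrecognized")
})

test_that("correction ties prefer the priority lexicon, then lexicographic order", {
  words <- c("bat", "cat", "hat")
  emb <- embedding_model(words, matrix(rnorm(9), 3, 3))
  raw <- tibble::tibble(trial_id = "t1", label = "rat")
  # all three candidates are 1 edit away; lexicographic picks "bat"
  expect_equal(clean_responses(raw, emb)$responses$word, "bat")
  # a priority lexicon overrides
  expect_equal(clean_responses(raw, emb, priority_lexicon = "hat")$responses$word,
               "hat")
  # corpus frequency breaks residual ties
  expect_equal(clean_responses(raw, emb, frequencies = c(cat = 10, bat = 1))$responses$word,
               "cat")
})

test_that("cleaning is idempotent and the audit covers every word exactly once", {
  emb <- test_embedding()
  raw <- tibble::tibble(
    trial_id = c("t1", "t1", "t2", "t2", "t3"),
    label = c("Dog", "the sky", "polar bear", "42", "grsas")
  )
  out1 <- clean_responses(raw, emb)
  # audit rows = number of tokens examined; every original token appears once
  tokens <- unlist(lapply(tolower(raw$label), function(l) {
    if (l %in% emb$vocab) l else strsplit(l, " ")[[1]]
  }))
  expect_equal(sort(out1$audit$original), sort(tokens))
  # re-cleaning the cleaned words changes nothing
  again <- tibble::tibble(trial_id = out1$responses$trial_id,
                          label = out1$responses$word)
  out2 <- clean_responses(again, emb)
  expect_equal(out2$responses$word, out1$responses$word)
  expect_true(all(out2$audit$action == "kept"))
})

test_that("trial embedding averages word vectors and splits unknown multiwords", {
  emb <- test_embedding()
  expect_equal(embed_trial("dog", emb), emb$vectors["dog", ])
  expect_equal(embed_trial(c("dog", "cat"), emb),
               colMeans(emb$vectors[c("dog", "cat"), ]))
  # "polar bear" is not a vocabulary entry; both parts are
  expect_equal(embed_trial("polar bear", emb),
               colMeans(emb$vectors[c("polar", "bear"), ]))
  # permutation invariance
  expect_equal(embed_trial(c("cat", "dog", "sky"), emb),
               embed_trial(c("sky", "cat", "dog"), emb))
  expect_error(embed_trial(character(0), emb), "at least one")
})

test_that("binary trial vectors indicate vocabulary membership", {
  vocab <- c("a1", "b2", "c3")
  expect_equal(unname(binary_trial_vector(c("x"), vocab)), c(0L, 0L, 0L))
  expect_equal(unname(binary_trial_vector(vocab, vocab)), c(1L, 1L, 1L))
  expect_equal(unname(binary_trial_vector("b2", vocab)), c(0L, 1L, 0L))
  expect_error(binary_trial_vector("x", character(0)), "non-empty")
})

test_that("participant exclusion uses a strict 25% low-concreteness rule", {
  conc <- tibble::tibble(
    word = c("dog", "cat", "sky", "tree", "grass", "water", "bird", "house"),
    rating = c(5, 5, 5, 5, 2, 2, 2, 2)
  )
  mk <- function(words) tibble::tibble(participant_id = "p1", word = words)
  # 0% low-concreteness: keep
  expect_true(validate_participant(mk(c("dog", "cat")), conc)$keep)
  # exactly 25%: keep (rule is strictly more than)
  r <- validate_participant(mk(c("dog", "cat", "sky", "grass")), conc)
  expect_equal(r$frac_low, 0.25)
  expect_true(r$keep)
  # 50%: exclude
  expect_false(validate_participant(mk(c("dog", "grass")), conc)$keep)
  # unrated words are ignored in the fraction
  r2 <- validate_participant(mk(c("dog", "unrated", "grass", "water", "bird")),
                             conc)
  expect_equal(r2$n_rated, 4)
  expect_equal(r2$frac_low, 0.75)
})

test_that("nearest words rank by cosine with deterministic ties", {
  emb <- test_embedding()
  nw <- nearest_words(emb$vectors["dog", ], emb, k = 3)
  expect_equal(nw$word[1], "dog")
  expect_equal(nw$rank, 1:3)
  # k larger than the lexicon returns the full ranking
  full <- nearest_words(emb$vectors["dog", ], emb, lexicon = c("cat", "sky"),
                        k = 10)
  expect_equal(nrow(full), 2)
  # brute-force oracle on a hand-built lexicon
  lex <- c("cat", "grass", "sky", "tree", "water")
  sims <- vapply(lex, function(w) {
    sum(emb$vectors[w, ] * emb$vectors["dog", ]) /
      sqrt(sum(emb$vectors[w, ]^2) * sum(emb$vectors["dog", ]^2))
  }, numeric(1))
  oracle <- lex[order(-sims, lex)]
  expect_equal(nearest_words(emb$vectors["dog", ], emb, lex, k = 5)$word, oracle)
  expect_error(nearest_words(emb$vectors["dog", ], emb, character(0), 1), "empty")
})
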
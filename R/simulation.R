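# Synthetic worlds: ground-truth lexicons, embeddings and visual-semantic
# mappings, plus simulated observers. Everything is seeded and runs in
# feature space by default so full recovery suites stay fast; a pixel mode
# routes stimuli through the image synthesizer with a toy extractor.

# Deterministic pronounceable pseudo-words ("bakodu", ...) that pass the
# response-cleaning filters (letters only, length > 1).
pseudo_words <- function(m) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  ns <- length(syl)
  vapply(seq_len(m) - 1L, function(i) {
    paste0(syl[(i %% ns) + 1], syl[((i %/% ns) %% ns) + 1],
           syl[((i %/% (ns * ns)) %% ns) + 1])
  }, character(1))
}

#' Generate a clustered toy word embedding
#'
#' Cluster centers are placed uniformly on the unit sphere; member words are
#' perturbed copies of their center, re-normalized. Within-cluster cosine
#' similarity exceeds between-cluster similarity on average, emulating the
#' neighborhood structure of real word embeddings.
#'
#' @param m Number of words (`m >= n_clusters`).
#' @param d Embedding dimension.
#' @param n_clusters Number of clusters (`>= 1`).
#' @param spread Perturbation scale within clusters.
#' @param seed RNG seed.
#' @return A list: `embedding` (an [embedding_model()]) and `lexicon`.
#' @export
make_toy_embedding <- function(m, d, n_clusters = max(1, m %/% 5),
                               spread = 0.3, seed = 1) {
  if (m < n_clusters || n_clusters < 1) abort("Require m >= n_clusters >= 1.")
  words <- pseudo_words(m)
  vecs <- with_seed(seed, {
    centers <- matrix(rnorm(n_clusters * d), n_clusters, d)
    centers <- centers / sqrt(rowSums(centers^2))
    assign <- rep_len(seq_len(n_clusters), m)
    v <- centers[assign, , drop = FALSE] +
      matrix(rnorm(m * d, sd = spread), m, d)
    v <- v / sqrt(rowSums(v^2))
    attr(v, "cluster") <- assign
    v
  })
  emb <- embedding_model(words, vecs)
  emb$cluster <- attr(vecs, "cluster")
  list(embedding = emb, lexicon = words)
}

#' Define a synthetic world
#'
#' A synthetic world fixes the ground truth that simulated observers share: a
#' lexicon with a toy embedding, a true visual-semantic mapping `W` (channels
#' by semantic dimensions), per-concept true feature vectors `W e_c`, the
#' observer noise level, and the labels-per-trial distribution. Defaults
#' emulate the standard study conditions: 40 concepts, 32 semantic
#' dimensions, 64 channels, moderate observer noise (sd 0.5 on unit-scale
#' semantic images) and a labels-per-trial distribution over 1-3 with mean
#' 2.17 labels.
#'
#' @param m Lexicon size.
#' @param d Semantic dimension.
#' @param v Number of visual channels.
#' @param noise_sd Observer noise standard deviation (>= 0).
#' @param label_probs Probabilities of emitting 1, 2 or 3 labels per trial.
#' @param temperature Softmax temperature for label choice (smaller =
#'   more deterministic observers).
#' @param n_clusters Clusters in the toy embedding.
#' @param seed RNG seed fixing the world.
#' @return An object of class `synthetic_world`.
#' @export
synthetic_world <- function(m = 40, d = 32, v = 64, noise_sd = 0.5,
                            label_probs = c(0.25, 0.33, 0.42),
                            temperature = 0.1, n_clusters = 8, seed = 1) {
  if (m < 2) abort("`m` must be at least 2.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (length(label_probs) != 3 || any(label_probs < 0)) {
    abort("`label_probs` must be 3 non-negative probabilities.")
  }
  label_probs <- label_probs / sum(label_probs)
  toy <- make_toy_embedding(m, d, n_clusters, seed = child_seed(seed, 1))
  W <- with_seed(child_seed(seed, 2), {
    matrix(rnorm(v * d, sd = 1 / sqrt(v)), v, d)
  })
  true_features <- W %*% t(toy$embedding$vectors)   # v x m, one column/concept
  colnames(true_features) <- toy$lexicon
  structure(
    list(lexicon = toy$lexicon, embedding = toy$embedding, W = W,
         true_features = true_features, noise_sd = noise_sd,
         label_probs = label_probs, temperature = temperature,
         m = m, d = d, v = v, seed = seed),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world: %d concepts, %d semantic dims, %d channels, noise sd %.2f>\n",
              x$m, x$d, x$v, x$noise_sd))
  invisible(x)
}

#' A feature-space model matching a synthetic world
#'
#' Fits [fit_feature_space()] on a Gaussian activation corpus with a random
#' channel covariance, giving the world a realistic (correlated) stimulus
#' distribution to sample from.
#'
#' @param world A [synthetic_world()].
#' @param n_corpus Corpus size for the fit.
#' @param seed RNG seed.
#' @return A `feature_space` model with `v` channels.
#' @export
world_feature_model <- function(world, n_corpus = 500, seed = 1) {
  v <- world$v
  acts <- with_seed(seed, {
    a <- matrix(rnorm(n_corpus * v), n_corpus, v)
    mix <- matrix(rnorm(v * v, sd = 1 / sqrt(v)), v, v)
    a %*% (diag(v) + 0.5 * mix)
  })
  fit_feature_space(acts)
}

#' Simulate a reverse-correlation experiment
#'
#' Draws `t` stimulus feature vectors from the fitted feature-space model,
#' computes each stimulus's noiseless semantic image `s = W' z` (with `z` the
#' standardized features) plus Gaussian observer noise, and emits 1-3 labels
#' per trial by sampling without replacement from a softmax over the cosine
#' similarities between the noisy semantic image and the lexicon vectors.
#'
#' @param world A [synthetic_world()].
#' @param feature_model A [fit_feature_space()] model with `world$v` channels
#'   (see [world_feature_model()]).
#' @param t Number of trials.
#' @param seed RNG seed.
#' @param n_participants Trials are attributed to this many simulated
#'   participants in contiguous blocks.
#' @return A list of class `simulated_trials`: `features` (`t x v`, trial ids
#'   as row names), `responses` (wide tibble: `participant_id`, `trial_id`,
#'   `stimulus_id`, `label_1..3`), and `world`.
#' @export
simulate_experiment <- function(world, feature_model, t, seed = NULL,
                                n_participants = max(1, t %/% 100)) {
  stopifnot(inherits(world, "synthetic_world"))
  if (feature_model$v != world$v) {
    abort("Feature model channel count does not match the world.")
  }
  features <- sample_target_features(feature_model, t, seed = child_seed(seed, 1))
  trial_ids <- sprintf("t%05d", seq_len(t))
  rownames(features) <- trial_ids

  z <- sweep(sweep(features, 2, feature_model$mean, "-"),
             2, feature_model$sd, "/")
  s_clean <- z %*% world$W                     # t x d semantic images
  E <- world$embedding$vectors                 # m x d
  En <- E / sqrt(rowSums(E^2))

  responses <- with_seed(child_seed(seed, 2), {
    s <- s_clean + matrix(rnorm(t * world$d, sd = world$noise_sd), t, world$d)
    sims <- s %*% t(En) / pmax(sqrt(rowSums(s^2)), 1e-12)   # t x m cosines
    n_labels <- sample(1:3, t, replace = TRUE, prob = world$label_probs)
    labs <- matrix(NA_character_, t, 3)
    for (i in seq_len(t)) {
      p <- exp((sims[i, ] - max(sims[i, ])) / world$temperature)
      p <- p / sum(p)
      k <- n_labels[i]
      pick <- if (world$temperature <= 0) {
        order(-sims[i, ])[seq_len(k)]
      } else {
        sample.int(world$m, k, replace = FALSE, prob = p)
      }
      labs[i, seq_len(k)] <- world$lexicon[pick]
    }
    labs
  })

  part <- sprintf("p%03d", ((seq_len(t) - 1) * n_participants) %/% t + 1)
  structure(
    list(
      features = features,
      responses = tibble(
        participant_id = part,
        trial_id = trial_ids,
        stimulus_id = trial_ids,
        label_1 = responses[, 1],
        label_2 = responses[, 2],
        label_3 = responses[, 3]
      ),
      world = world,
      seed = seed
    ),
    class = "simulated_trials"
  )
}

#' @export
print.simulated_trials <- function(x, ...) {
  cat(sprintf("<simulated_trials: %d trials, %d channels, %d participants>\n",
              nrow(x$features), ncol(x$features),
              dplyr::n_distinct(x$responses$participant_id)))
  invisible(x)
}

#' Model-observer responses from a probability-emitting classifier
#'
#' Takes the `top_k` most probable class labels per stimulus as the model's
#' responses. Labels with multiple comma-separated synonyms contribute their
#' first synonym. Labels the embedding does not recognize are passed to the
#' resolver hook (e.g. a hypernym lookup) and dropped, with a log entry, if
#' still unresolved.
#'
#' @param classifier Function mapping an image (or a stimulus id when
#'   `stimuli` is a vector of ids) to a named probability vector over classes.
#' @param stimuli List (or vector) of stimuli to label.
#' @param top_k Number of labels per stimulus (>= 1).
#' @param embedding Optional [embedding_model()] used to screen labels.
#' @param resolver Optional function label -> replacement label (or NA).
#' @return A wide response tibble (as in [simulate_experiment()]) with an
#'   attribute `dropped` listing unresolvable labels.
#' @export
model_observer_responses <- function(classifier, stimuli, top_k = 3,
                                     embedding = NULL, resolver = NULL) {
  if (top_k < 1) abort("`top_k` must be >= 1.")
  dropped <- list()
  rows <- lapply(seq_along(stimuli), function(i) {
    probs <- classifier(stimuli[[i]])
    if (is.null(names(probs))) abort("Classifier must return named probabilities.")
    labels <- names(sort(probs, decreasing = TRUE))[seq_len(min(top_k, length(probs)))]
    labels <- vapply(labels, function(l) trimws(strsplit(l, ",")[[1]][1]),
                     character(1))
    if (!is.null(embedding)) {
      resolved <- vapply(labels, function(l) {
        if (l %in% embedding$vocab) return(l)
        if (!is.null(resolver)) {
          alt <- resolver(l)
          if (!is.na(alt) && alt %in% embedding$vocab) return(alt)
        }
        NA_character_
      }, character(1))
      bad <- labels[is.na(resolved)]
      if (length(bad) > 0) dropped[[length(dropped) + 1]] <<- bad
      labels <- resolved[!is.na(resolved)]
    }
    labs <- rep(NA_character_, 3)
    labs[seq_along(labels[seq_len(min(3, length(labels)))])] <-
      labels[seq_len(min(3, length(labels)))]
    tibble(participant_id = "model", trial_id = sprintf("t%05d", i),
           stimulus_id = sprintf("t%05d", i),
           label_1 = labs[1], label_2 = labs[2], label_3 = labs[3])
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "dropped") <- unname(unlist(dropped))
  out
}
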
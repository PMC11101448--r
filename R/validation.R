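# Analyses for the behavioral validation experiments: 2AFC recognition of
# reconstructions, open-ended label agreement, and real-versus-null
# reconstruction comparisons.

#' Two-alternative forced-choice validation with participant bootstrap
#'
#' Per-concept accuracy is the mean over participants of binary correctness.
#' Significance uses a participant bootstrap: a concept is significant when
#' at least a Sidak-corrected fraction of its bootstrap distribution lies
#' above the 50% chance level (per-concept one-sided level
#' `1 - (1 - alpha)^(1/m)` with `m` the family size). An optional refinement
#' pass reruns concepts whose decision sits near the boundary with more
#' resamples. The mean-level p-value comes from the chance model implied by
#' permuting the response labels of a 2AFC trial: each trial correct with
#' probability one half.
#'
#' @param responses Binary matrix, participants by concepts (0/1 correctness).
#' @param n_boot Bootstrap resamples over participants.
#' @param alpha Family-wise level for the Sidak correction.
#' @param family_size Family size `m` for the correction (defaults to the
#'   number of concepts).
#' @param n_perm Iterations for the mean-level chance null.
#' @param refine Run the refinement pass (10x resamples) for concepts whose
#'   bootstrap fraction above chance falls within `refine_band`.
#' @param refine_band Two-element accuracy band triggering refinement.
#' @param seed RNG seed.
#' @return A list: `per_concept` (tibble: `concept`, `accuracy`,
#'   `frac_above_chance`, `significant`), `sidak_level` (the required
#'   fraction), `mean_accuracy`, `mean_p`.
#' @export
twoafc_validation <- function(responses, n_boot = 50000, alpha = 0.05,
                              family_size = NULL, n_perm = 1000,
                              refine = FALSE, refine_band = c(0.4, 0.6),
                              seed = NULL) {
  responses <- check_matrix(responses, "responses")
  if (!all(responses %in% c(0, 1))) abort("`responses` must be binary (0/1).")
  n_p <- nrow(responses); n_c <- ncol(responses)
  m <- family_size %||% n_c
  required <- (1 - alpha)^(1 / m)  # fraction of bootstrap that must beat 0.5
  acc <- colMeans(responses)
  concepts <- colnames(responses) %||% paste0("concept", seq_len(n_c))

  boot_frac <- function(nb, sd_stream) {
    with_seed(child_seed(seed, sd_stream), {
      idx <- matrix(sample.int(n_p, nb * n_p, replace = TRUE), nrow = nb)
      counts <- Matrix::sparseMatrix(
        i = rep(seq_len(nb), n_p), j = as.integer(idx), x = 1,
        dims = c(nb, n_p)
      )
      means <- as.matrix(counts %*% responses) / n_p
      colMeans(means > 0.5)
    })
  }
  frac <- boot_frac(n_boot, 1)
  if (refine) {
    near <- which(acc >= refine_band[1] & acc <= refine_band[2])
    if (length(near) > 0) {
      frac_ref <- boot_frac(n_boot * 10, 2)
      frac[near] <- frac_ref[near]
    }
  }
  sig <- frac >= required

  mean_acc <- mean(acc)
  null_means <- with_seed(child_seed(seed, 3), {
    vapply(seq_len(n_perm), function(p) {
      mean(matrix(rbinom(n_p * n_c, 1, 0.5), n_p, n_c))
    }, numeric(1))
  })
  list(
    per_concept = tibble(concept = concepts, accuracy = unname(acc),
                         frac_above_chance = unname(frac),
                         significant = unname(sig)),
    sidak_level = required,
    mean_accuracy = mean_acc,
    mean_p = perm_pvalue(mean_acc, null_means, "greater")
  )
}

#' Agreement metrics for open-ended labels of one reconstruction
#'
#' Computes: whether the most common response equals the true label (with
#' singular/plural equivalence); the least-squares slope of response
#' frequency on semantic distance to the true label, with its t statistic and
#' one-tailed p-value for a negative slope (callers apply any multiple-test
#' correction); the entropy of the empirical response distribution (natural
#' log); and the trace of the covariance matrix of the response embeddings
#' (unbiased `n - 1` estimator; a single response gives trace 0 with a
#' warning).
#'
#' @param responses Character vector of (cleaned) responses, one per answer.
#' @param true_label The concept's label (in the embedding vocabulary).
#' @param embedding An [embedding_model()].
#' @return A list of class `agreement_metrics`: `most_common_correct`,
#'   `slope`, `slope_t`, `slope_p`, `entropy`, `trace`, `n_unique`.
#' @export
label_agreement_metrics <- function(responses, true_label, embedding) {
  if (length(responses) == 0) abort("At least one response is required.")
  if (!true_label %in% embedding$vocab) {
    abort(sprintf("True label '%s' not in vocabulary.", true_label))
  }
  counts <- sort(table(responses), decreasing = TRUE)
  words <- names(counts)
  top <- words[counts == max(counts)]
  most_common_correct <- any(plural_equivalent(top, true_label))

  probs <- as.numeric(counts) / sum(counts)
  entropy <- -sum(probs * log(probs))

  known <- words[in_vocabulary(embedding, words)]
  tv <- embedding$vectors[true_label, ]
  slope <- slope_t <- slope_p <- NA_real_
  if (length(known) >= 3) {
    dist <- vapply(known, function(w) {
      1 - cosine_similarity(embedding$vectors[w, ], tv)
    }, numeric(1))
    freq <- as.numeric(counts[known])
    fit <- stats::lm(freq ~ dist)
    slope <- unname(stats::coef(fit)[2])
    # t statistic only when the fit leaves residual variance (a perfectly
    # collinear or constant-frequency instance has no sampling error to test)
    rss <- sum(stats::resid(fit)^2)
    if (is.finite(slope) && rss > 1e-12 && fit$df.residual > 0) {
      se <- sqrt(rss / fit$df.residual / sum((dist - mean(dist))^2))
      slope_t <- slope / se
      slope_p <- pt(slope_t, df = fit$df.residual)  # one-tailed, negative slope
    }
  }

  resp_known <- responses[in_vocabulary(embedding, responses)]
  tr <- if (length(resp_known) >= 2) {
    sum(diag(stats::cov(embedding$vectors[resp_known, , drop = FALSE])))
  } else {
    warn("Fewer than 2 embeddable responses: covariance trace set to 0.")
    0
  }
  structure(
    list(most_common_correct = most_common_correct, slope = slope,
         slope_t = slope_t, slope_p = slope_p, entropy = entropy,
         trace = tr, n_unique = length(words)),
    class = "agreement_metrics"
  )
}

# Per-image summary metrics used by the real-vs-null comparison.
image_label_metrics <- function(responses, true_label, embedding) {
  correct <- mean(plural_equivalent(responses, true_label))
  counts <- table(responses)
  probs <- as.numeric(counts) / sum(counts)
  entropy <- -sum(probs * log(probs))
  known <- responses[in_vocabulary(embedding, responses)]
  tv <- embedding$vectors[true_label, ]
  dist <- if (length(known) > 0) {
    mean(vapply(known, function(w) 1 - cosine_similarity(embedding$vectors[w, ], tv),
                numeric(1)))
  } else {
    NA_real_
  }
  tr <- if (length(known) >= 2) {
    sum(diag(stats::cov(embedding$vectors[known, , drop = FALSE])))
  } else {
    0
  }
  c(correct = correct, distance = dist, entropy = entropy, trace = tr)
}

#' Compare labeling of real versus null reconstructions
#'
#' For each concept, computes four per-concept success flags: the correct
#' label is given more often, the mean semantic distance to the true label is
#' lower, the response entropy is lower, and the response-embedding
#' covariance trace is smaller, for the real reconstruction than for its null
#' reconstructions on average. Comparisons are strict (ties count as
#' failures). Success counts are tested by permutation: the label-dependent
#' metrics (correct-label frequency, semantic distance) permute the true
#' labels across concepts; the label-free metrics (entropy, trace) permute
#' all responses across images. Confidence intervals resample the
#' per-concept flag vectors.
#'
#' @param responses Tibble with columns `concept`, `image_role` (`"real"` or
#'   `"null"`), `image_id`, `response` (one row per answer).
#' @param true_labels Named character vector mapping concept to its label.
#' @param embedding An [embedding_model()].
#' @param n_perm Permutations for the significance tests.
#' @param n_boot Bootstrap resamples for the CIs.
#' @param seed RNG seed.
#' @return A list: `flags` (tibble, one row per concept, logical columns
#'   `correct`, `distance`, `entropy`, `trace`), `counts`, `p` (per metric),
#'   `ci` (per metric, 2-column matrix).
#' @export
real_vs_null_comparison <- function(responses, true_labels, embedding,
                                    n_perm = 1000, n_boot = 1000, seed = NULL) {
  stopifnot(all(c("concept", "image_role", "image_id", "response") %in%
                  names(responses)))
  concepts <- unique(responses$concept)
  if (!all(concepts %in% names(true_labels))) {
    abort("`true_labels` must cover every concept.")
  }
  metric_names <- c("correct", "distance", "entropy", "trace")

  concept_flags <- function(resp_tbl, labels) {
    f <- t(vapply(concepts, function(cc) {
      sub <- resp_tbl[resp_tbl$concept == cc, ]
      real <- sub[sub$image_role == "real", ]
      nulls <- split(sub[sub$image_role == "null", ],
                     sub$image_id[sub$image_role == "null"])
      if (nrow(real) == 0 || length(nulls) == 0) {
        abort(sprintf("Concept '%s' lacks real or null responses.", cc))
      }
      mr <- image_label_metrics(real$response, labels[[cc]], embedding)
      mn <- rowMeans(vapply(nulls, function(nn) {
        image_label_metrics(nn$response, labels[[cc]], embedding)
      }, numeric(4)), na.rm = TRUE)
      c(correct = isTRUE(mr["correct"] > mn["correct"]),
        distance = isTRUE(mr["distance"] < mn["distance"]),
        entropy = isTRUE(mr["entropy"] < mn["entropy"]),
        trace = isTRUE(mr["trace"] < mn["trace"]))
    }, logical(4)))
    colnames(f) <- metric_names
    f
  }

  flags <- concept_flags(responses, true_labels)
  counts <- colSums(flags)

  null_counts <- with_seed(child_seed(seed, 1), {
    t(vapply(seq_len(n_perm), function(p) {
      lab_perm <- setNames(true_labels[sample(concepts)], concepts)
      resp_perm <- responses
      resp_perm$response <- sample(responses$response)
      f_lab <- concept_flags(responses, lab_perm)
      f_resp <- concept_flags(resp_perm, true_labels)
      c(correct = sum(f_lab[, "correct"]),
        distance = sum(f_lab[, "distance"]),
        entropy = sum(f_resp[, "entropy"]),
        trace = sum(f_resp[, "trace"]))
    }, numeric(4)))
  })
  colnames(null_counts) <- metric_names
  p <- vapply(metric_names, function(mm) {
    perm_pvalue(counts[mm], null_counts[, mm], "greater")
  }, numeric(1))

  ci <- with_seed(child_seed(seed, 2), {
    boots <- t(vapply(seq_len(n_boot), function(b) {
      colSums(flags[sample.int(nrow(flags), nrow(flags), replace = TRUE), ,
                    drop = FALSE])
    }, numeric(4)))
    apply(boots, 2, quantile, probs = c(0.025, 0.975))
  })

  list(
    flags = dplyr::bind_cols(tibble(concept = concepts),
                             as_tibble(flags)),
    counts = counts,
    n_concepts = length(concepts),
    p = p,
    ci = t(ci)
  )
}
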
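# Permutation max-statistic inference for the visual-semantic matrix,
# bootstrap confidence intervals, and the leave-concept-out robustness fit.

#' Build a permutation null ensemble of visual-semantic matrices
#'
#' Each permutation shuffles the semantic score rows across trials (breaking
#' the stimulus-response alignment) and refits the outer-product matrix. The
#' ensemble stores every null matrix plus per-coefficient null means and
#' standard deviations.
#'
#' @inheritParams fit_visual_semantic
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed for the permutations.
#' @return An object of class `null_ensemble`: `matrices` (array
#'   `k_v x k_s x n_perm`), `mean`, `sd`, `n_perm`, `seed`.
#' @export
build_null_ensemble <- function(visual_scores, semantic_scores,
                                n_perm = 1000, seed = NULL) {
  x <- check_matrix(visual_scores, "visual_scores")
  y <- check_matrix(semantic_scores, "semantic_scores")
  if (nrow(x) != nrow(y)) abort("Row counts differ.")
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  t_n <- nrow(x)
  mats <- with_seed(seed, {
    a <- array(0, dim = c(ncol(x), ncol(y), n_perm))
    for (p in seq_len(n_perm)) {
      a[, , p] <- crossprod(x, y[sample.int(t_n), , drop = FALSE]) / (t_n - 1)
    }
    a
  })
  structure(
    list(matrices = mats,
         mean = apply(mats, c(1, 2), mean),
         sd = apply(mats, c(1, 2), sd),
         n_perm = n_perm, seed = seed),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble: %d permutations of a %d x %d matrix>\n",
              x$n_perm, dim(x$matrices)[1], dim(x$matrices)[2]))
  invisible(x)
}

#' Max-statistic test of visual-semantic coefficients
#'
#' Z-scores every coefficient against its permutation null
#' (`Z = (B - null mean) / null sd`) and applies the two-tailed max-statistic
#' correction: each observed `|Z|` is compared with the null distribution of
#' per-permutation maxima of `|Z|`, controlling the family-wise error rate
#' across all coefficients. P-values are floored at `1/(n_perm + 1)`. Cells
#' with zero null standard deviation are flagged untestable (`NA`).
#'
#' @param map A `visual_semantic_map` (or a bare coefficient matrix).
#' @param ensemble A matching [build_null_ensemble()].
#' @param alpha Family-wise significance level.
#' @return An object of class `coef_test`: `z` matrix, `p` matrix (FWER-
#'   corrected), logical `significant` mask, `critical` (the `1 - alpha`
#'   quantile of null max `|Z|`), and `null_max` (the null maxima).
#' @export
test_coefficients <- function(map, ensemble, alpha = 0.05) {
  B <- if (inherits(map, "visual_semantic_map")) map$B else check_matrix(map, "map")
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (!all(dim(B) == dim(ensemble$mean))) {
    abort("`ensemble` shape does not match the coefficient matrix.")
  }
  sd0 <- ensemble$sd
  testable <- sd0 > 0
  z <- (B - ensemble$mean) / ifelse(testable, sd0, NA_real_)
  n_perm <- ensemble$n_perm
  # null matrices are z-scored against leave-one-out moments so that each
  # permutation is treated exactly like the observed matrix (which is not
  # part of its own null); self-inclusion would deflate the null maxima and
  # make the test anti-conservative
  mats <- ensemble$matrices
  s1 <- ensemble$mean * n_perm                    # per-cell sums
  s2 <- (n_perm - 1) * sd0^2 + ensemble$mean^2 * n_perm
  null_z <- mats
  for (p in seq_len(n_perm)) {
    x <- mats[, , p]
    m_loo <- (s1 - x) / (n_perm - 1)
    v_loo <- pmax((s2 - x^2 - (n_perm - 1) * m_loo^2) / (n_perm - 2), 0)
    null_z[, , p] <- ifelse(testable & v_loo > 0,
                            (x - m_loo) / sqrt(v_loo), NA_real_)
  }
  null_max <- apply(abs(null_z), 3, max, na.rm = TRUE)
  # +1 convention: the observed family counts as one more permutation
  k_crit <- min(ceiling((n_perm + 1) * (1 - alpha)), n_perm)
  critical <- sort(null_max)[k_crit]
  p <- matrix(NA_real_, nrow(B), ncol(B))
  absz <- abs(z)
  for (i in seq_len(nrow(B))) {
    for (j in seq_len(ncol(B))) {
      if (testable[i, j]) {
        p[i, j] <- (sum(null_max >= absz[i, j]) + 1) / (n_perm + 1)
      }
    }
  }
  structure(
    list(z = z, p = pmin(p, 1), significant = !is.na(p) & absz > critical,
         critical = critical, null_max = null_max, alpha = alpha,
         untestable = !testable),
    class = "coef_test"
  )
}

#' @export
print.coef_test <- function(x, ...) {
  cat(sprintf("<coef_test: %d of %d coefficients significant (FWER alpha = %g, critical |Z| = %.2f)>\n",
              sum(x$significant), length(x$significant), x$alpha, x$critical))
  invisible(x)
}

#' Bootstrap confidence intervals for a concept's feature vector
#'
#' Resamples trials with replacement, refits the full pipeline per resample
#' (PCAs included, unless `refit_pca = FALSE` for the fast fixed-PCA mode),
#' and returns elementwise 2.5th/97.5th percentile bounds around the observed
#' feature vector. Degenerate resamples (a constant feature or semantic
#' column) are redrawn and counted.
#'
#' @inheritParams fit_concept_map
#' @param word Concept label (in the embedding vocabulary).
#' @param embedding An [embedding_model()].
#' @param n_boot Number of bootstrap resamples.
#' @param seed RNG seed.
#' @param refit_pca Refit the PCAs per resample (default) or keep the
#'   original PCAs fixed and refit only the coefficient matrix.
#' @param level Confidence level (default 0.95).
#' @return A `concept_representation` with `ci_lower`/`ci_upper` and a
#'   `provenance` entry recording redrawn resamples.
#' @export
bootstrap_concept_ci <- function(features, semantics, word, embedding,
                                 variance_threshold = 0.9, n_boot = 1000,
                                 seed = NULL, refit_pca = TRUE, level = 0.95) {
  features <- check_matrix(features, "features")
  semantics <- check_matrix(semantics, "semantics")
  t_n <- nrow(features)
  if (t_n < 2) abort("At least 2 trials are required.")
  full_map <- fit_concept_map(features, semantics, variance_threshold)
  observed <- concept_to_features(word, embedding, full_map)
  sem_vec <- embedding$vectors[word, ]

  redraws <- 0L
  draws <- with_seed(seed, {
    out <- matrix(0, nrow = n_boot, ncol = ncol(features))
    for (b in seq_len(n_boot)) {
      repeat {
        idx <- sample.int(t_n, t_n, replace = TRUE)
        f <- features[idx, , drop = FALSE]
        s <- semantics[idx, , drop = FALSE]
        ok <- all(apply(f, 2, sd) > 0) && any(apply(s, 2, sd) > 0)
        if (ok) break
        redraws <- redraws + 1L
      }
      m <- if (refit_pca) {
        fit_concept_map(f, s, variance_threshold)
      } else {
        fit_visual_semantic(pca_transform(full_map$visual_pca, f),
                            pca_transform(full_map$semantic_pca, s),
                            visual_pca = full_map$visual_pca,
                            semantic_pca = full_map$semantic_pca)
      }
      out[b, ] <- semantic_vector_to_features(sem_vec, m)
    }
    out
  })
  lo <- (1 - level) / 2
  new_concept_representation(
    word, observed$features,
    ci_lower = apply(draws, 2, quantile, probs = lo),
    ci_upper = apply(draws, 2, quantile, probs = 1 - lo),
    provenance = list(n_boot = n_boot, seed = seed, refit_pca = refit_pca,
                      redrawn_resamples = redraws)
  )
}

#' Refit the visual-semantic map without a concept's responses
#'
#' Removes every response word equal to the concept's name (or its
#' singular/plural variant), recomputes trial semantic vectors from the
#' remaining words, drops trials left with no valid response, and refits the
#' whole pipeline. Quantifies how much a concept's recovered representation
#' depends on its own label.
#'
#' @param cleaned Cleaned response table (`trial_id`, `word`).
#' @param features `t x v` feature matrix with trial ids as row names
#'   matching `cleaned$trial_id`.
#' @param word Concept label to hold out.
#' @param embedding An [embedding_model()].
#' @param variance_threshold PCA retention threshold.
#' @return A `visual_semantic_map` fitted on the reduced data; its
#'   `provenance` records removed responses and dropped trials.
#' @export
leave_concept_out_map <- function(cleaned, features, word, embedding,
                                  variance_threshold = 0.9) {
  features <- check_matrix(features, "features")
  if (is.null(rownames(features))) {
    abort("`features` must carry trial ids as row names.")
  }
  variants <- word_variants(tolower(word))
  keep <- !(tolower(cleaned$word) %in% variants)
  reduced <- cleaned[keep, , drop = FALSE]
  if (nrow(reduced) == 0) abort("No usable responses remain after removal.")
  sems <- embed_trials(reduced, embedding)
  usable <- intersect(rownames(features), sems$trial_id)
  if (length(usable) < 2) abort("Fewer than 2 usable trials remain.")
  sem_m <- semantic_matrix(sems)[usable, , drop = FALSE]
  feat_m <- features[usable, , drop = FALSE]
  fit_concept_map(
    feat_m, sem_m, variance_threshold,
    provenance = list(held_out = word,
                      removed_responses = sum(!keep),
                      dropped_trials = nrow(features) - length(usable))
  )
}
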
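# Downstream prediction statistics: semantic-content prediction, stimulus
# prediction with Dice overlap, RDMs and representational similarity
# analysis.

#' Predict the semantic content of held-out stimuli
#'
#' Projects each stimulus's visual feature vector through the fitted map to a
#' predicted semantic vector and scores it against the trial's true semantic
#' vector (the mean embedding of its response words) with cosine similarity.
#' A label-resampling null recomputes the true vectors with labels drawn with
#' replacement from the pooled labels of all tested stimuli; the mean-level
#' p-value is the percentile of the observed mean cosine in the null of
#' means.
#'
#' @param features `n x v` matrix of held-out stimulus feature vectors, with
#'   trial ids as row names.
#' @param cleaned Cleaned responses for those stimuli (`trial_id`, `word`).
#' @param embedding An [embedding_model()].
#' @param map A fitted `visual_semantic_map`.
#' @param n_null Number of label-resampling null iterations.
#' @param seed RNG seed.
#' @return A list with `per_image` (tibble: `trial_id`, `cosine`), `mean`
#'   (observed mean cosine), `null_mean`, `null_sd`, `z`, `p`.
#' @export
predict_semantic_content <- function(features, cleaned, embedding, map,
                                     n_null = 1000, seed = NULL) {
  features <- check_matrix(features, "features")
  ids <- rownames(features)
  if (is.null(ids)) abort("`features` must carry trial ids as row names.")
  sems <- embed_trials(cleaned, embedding)
  if (!all(ids %in% sems$trial_id)) {
    abort("Every feature row needs at least one valid response word.")
  }
  true_m <- semantic_matrix(sems)[ids, , drop = FALSE]
  pred <- t(apply(features, 1, features_to_semantics, map = map))
  cosines <- vapply(seq_along(ids), function(i) {
    cosine_similarity(pred[i, ], true_m[i, ])
  }, numeric(1))

  counts <- sems$n_words[match(ids, sems$trial_id)]
  pool <- cleaned$word[cleaned$trial_id %in% ids]
  null_means <- with_seed(seed, {
    vapply(seq_len(n_null), function(b) {
      mean(vapply(seq_along(ids), function(i) {
        words <- sample(pool, counts[i], replace = TRUE)
        cosine_similarity(pred[i, ], embed_trial(words, embedding))
      }, numeric(1)))
    }, numeric(1))
  })
  obs <- mean(cosines)
  list(
    per_image = tibble(trial_id = ids, cosine = cosines),
    mean = obs,
    null_mean = mean(null_means),
    null_sd = sd(null_means),
    z = (obs - mean(null_means)) / sd(null_means),
    p = perm_pvalue(obs, null_means, "greater")
  )
}

#' Dice coefficient between two sets
#'
#' `2 |A intersect B| / (|A| + |B|)`; two empty sets give 0 by convention.
#' Symmetric, in `[0, 1]`, and 1 exactly when the sets are equal (and
#' non-empty).
#'
#' @param a,b Vectors treated as sets (duplicates ignored).
#' @return A scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(0)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Predict which stimuli contain a concept
#'
#' Correlates every stimulus's feature vector with the concept's recovered
#' feature vector, predicts as positive the top `m` stimuli (where `m` is the
#' number of truly positive stimuli; ties broken by stimulus index), and
#' scores the overlap with the truth by the Dice coefficient. The null
#' permutes the stimulus order of the truth vector.
#'
#' @param concept A `concept_representation` (or bare feature vector).
#' @param features `t x v` stimulus feature matrix.
#' @param truth Logical or 0/1 vector: which stimuli truly contain the
#'   concept (at least one positive, not all positive).
#' @param n_perm Number of permutations.
#' @param seed RNG seed.
#' @return A list of class `prediction_outcome`: `dice`, `correlations`,
#'   `predicted` (logical), `null_dice`, `z`, `p` (uncorrected, one-tailed).
#' @export
predict_stimuli_for_concept <- function(concept, features, truth,
                                        n_perm = 1000, seed = NULL) {
  feats <- if (inherits(concept, "concept_representation")) concept$features else concept
  features <- check_matrix(features, "features")
  truth <- as.logical(truth)
  if (!any(truth)) abort("`truth` must contain at least one positive stimulus.")
  if (all(truth)) abort("`truth` must not be all-positive.")
  r <- as.numeric(cor(t(features), feats))
  m <- sum(truth)
  ord <- order(-r, seq_along(r))
  predicted <- seq_along(r) %in% ord[seq_len(m)]
  pos_set <- which(truth); pred_set <- which(predicted)
  dice <- dice_coefficient(pred_set, pos_set)
  null_dice <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      dice_coefficient(pred_set, which(truth[sample.int(length(truth))]))
    }, numeric(1))
  })
  z <- if (sd(null_dice) > 0) (dice - mean(null_dice)) / sd(null_dice) else NA_real_
  structure(
    list(dice = dice, correlations = r, predicted = predicted,
         null_dice = null_dice, z = z,
         p = perm_pvalue(dice, null_dice, "greater")),
    class = "prediction_outcome"
  )
}

#' Family-wise stimulus prediction across several concepts
#'
#' Runs [predict_stimuli_for_concept()] per concept and applies the
#' max-statistic correction across the family: each concept's z-scored Dice
#' is compared with the null distribution of per-permutation maxima of the
#' z-scored null Dice values across concepts.
#'
#' @param concepts Named list of `concept_representation`s (or feature
#'   vectors).
#' @param features `t x v` stimulus feature matrix.
#' @param truth_matrix Logical matrix, stimuli by concepts.
#' @param n_perm,seed As in [predict_stimuli_for_concept()].
#' @return A tibble: `concept`, `dice`, `z`, `p_fwer`.
#' @export
predict_stimuli_family <- function(concepts, features, truth_matrix,
                                   n_perm = 1000, seed = NULL) {
  stopifnot(length(concepts) == ncol(truth_matrix))
  outs <- lapply(seq_along(concepts), function(i) {
    predict_stimuli_for_concept(concepts[[i]], features, truth_matrix[, i],
                                n_perm = n_perm,
                                seed = child_seed(seed, i))
  })
  null_z <- vapply(outs, function(o) {
    mu <- mean(o$null_dice); s <- sd(o$null_dice)
    if (s > 0) (o$null_dice - mu) / s else rep(0, length(o$null_dice))
  }, numeric(n_perm))
  null_max <- apply(null_z, 1, max)
  z_obs <- vapply(outs, `[[`, numeric(1), "z")
  tibble(
    concept = names(concepts) %||% as.character(seq_along(concepts)),
    dice = vapply(outs, `[[`, numeric(1), "dice"),
    z = z_obs,
    p_fwer = vapply(z_obs, function(z) perm_pvalue(z, null_max, "greater"),
                    numeric(1))
  )
}

#' Build a representational dissimilarity matrix
#'
#' Pairwise correlation distances (1 - Pearson r) between row vectors.
#'
#' @param vectors `n x d` matrix (`n >= 3`, no constant row).
#' @param labels Item labels (defaults to row names).
#' @return An object of class `rdm`: symmetric distance matrix with zero
#'   diagonal, entries in `[0, 2]`.
#' @export
build_rdm <- function(vectors, labels = rownames(vectors)) {
  vectors <- check_matrix(vectors, "vectors")
  if (nrow(vectors) < 3) abort("At least 3 items are required for an RDM.")
  if (any(apply(vectors, 1, sd) == 0)) abort("Constant vector(s): correlation undefined.")
  labels <- labels %||% paste0("item", seq_len(nrow(vectors)))
  d <- 1 - cor(t(vectors))
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  structure(list(distances = d, labels = labels), class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm: %d items, correlation distance>\n", length(x$labels)))
  invisible(x)
}

as_rdm_matrix <- function(x) {
  if (inherits(x, "rdm")) return(x$distances)
  check_matrix(x, "rdm")
}

#' Representational similarity analysis between two RDMs
#'
#' Spearman correlation between the vectorized upper triangles. Statistical
#' significance comes from jointly shuffling rows and columns of the
#' behavioral RDM; the confidence interval from resampling items with
#' replacement (dropping the off-diagonal zero entries created by duplicated
#' items). Rank-based, hence invariant to monotone transforms of either
#' distance matrix.
#'
#' @param rdm_model,rdm_behavior [build_rdm()] objects (or bare matrices)
#'   with matching labels/order.
#' @param n_perm Permutations for the p-value.
#' @param n_boot Bootstrap resamples for the CI.
#' @param seed RNG seed.
#' @param level CI level.
#' @return A list: `rho`, `p`, `ci` (2-vector), `null` (permutation rhos).
#' @export
rsa_compare <- function(rdm_model, rdm_behavior, n_perm = 1000, n_boot = 1000,
                        seed = NULL, level = 0.95) {
  dm <- as_rdm_matrix(rdm_model)
  db <- as_rdm_matrix(rdm_behavior)
  if (!all(dim(dm) == dim(db))) abort("RDM dimensions differ.")
  if (inherits(rdm_model, "rdm") && inherits(rdm_behavior, "rdm") &&
      !identical(rdm_model$labels, rdm_behavior$labels)) {
    abort("RDM labels do not match.")
  }
  n <- nrow(dm)
  rho <- cor(upper_tri_vec(dm), upper_tri_vec(db), method = "spearman")
  null <- with_seed(child_seed(seed, 1), {
    vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(n)
      cor(upper_tri_vec(dm), upper_tri_vec(db[idx, idx]), method = "spearman")
    }, numeric(1))
  })
  boots <- with_seed(child_seed(seed, 2), {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      a <- upper_tri_vec(dm[idx, idx]); bb <- upper_tri_vec(db[idx, idx])
      dup <- outer(idx, idx, "==")
      keep <- !upper_tri_vec(dup)
      if (sum(keep) < 3) return(NA_real_)
      cor(a[keep], bb[keep], method = "spearman")
    }, numeric(1))
  })
  lo <- (1 - level) / 2
  list(
    rho = rho,
    p = perm_pvalue(rho, null, "greater"),
    ci = as.numeric(quantile(boots, c(lo, 1 - lo), na.rm = TRUE)),
    null = null
  )
}

#' Paired difference between two model RDMs against one behavioral RDM
#'
#' Tests `rho(model A, behavior) - rho(model B, behavior)` with the same
#' joint row/column permutation of the behavioral RDM applied to both terms
#' (two-tailed).
#'
#' @param rdm_a,rdm_b Model RDMs.
#' @param rdm_behavior Behavioral RDM.
#' @inheritParams rsa_compare
#' @return A list: `rho_a`, `rho_b`, `difference`, `p`, `null`.
#' @export
rsa_difference <- function(rdm_a, rdm_b, rdm_behavior, n_perm = 1000,
                           seed = NULL) {
  da <- as_rdm_matrix(rdm_a); db2 <- as_rdm_matrix(rdm_b)
  db <- as_rdm_matrix(rdm_behavior)
  va <- upper_tri_vec(da); vb <- upper_tri_vec(db2)
  rho_a <- cor(va, upper_tri_vec(db), method = "spearman")
  rho_b <- cor(vb, upper_tri_vec(db), method = "spearman")
  obs <- rho_a - rho_b
  n <- nrow(db)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(p) {
      idx <- sample.int(n)
      vv <- upper_tri_vec(db[idx, idx])
      cor(va, vv, method = "spearman") - cor(vb, vv, method = "spearman")
    }, numeric(1))
  })
  list(rho_a = rho_a, rho_b = rho_b, difference = obs,
       p = perm_pvalue(obs, null, "two"), null = null)
}

#' Average rank-transformed RDMs across participants
#'
#' @param rdms List of `rdm` objects (or matrices) with identical labels.
#' @return An `rdm` of the mean rank-transformed distances.
#' @export
average_rank_rdms <- function(rdms) {
  mats <- lapply(rdms, as_rdm_matrix)
  labels <- if (inherits(rdms[[1]], "rdm")) rdms[[1]]$labels else rownames(mats[[1]])
  ranked <- lapply(mats, function(m) {
    v <- rank(upper_tri_vec(m))
    out <- matrix(0, nrow(m), ncol(m))
    out[upper.tri(out)] <- v
    out + t(out)
  })
  avg <- Reduce(`+`, ranked) / length(ranked)
  dimnames(avg) <- list(labels, labels)
  structure(list(distances = avg, labels = labels), class = "rdm")
}
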
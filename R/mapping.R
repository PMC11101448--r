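# The visual-semantic matrix: an outer product of whitened trial score
# matrices linking visual principal components to semantic principal
# components, plus the projections through it in both directions.

#' Fit the visual-semantic matrix from trial score matrices
#'
#' Computes `B = X' Y / (t - 1)` between aligned visual and semantic score
#' matrices. With whitened scores this equals the least-squares coefficient
#' matrix of the multivariate regression of `Y` on `X` (up to the positive
#' `1/(t-1)` scale, which is irrelevant to significance ranks and to
#' direction-only reconstruction), and each coefficient reads as a
#' correlation.
#'
#' @param visual_scores `t x k_v` matrix of visual PC scores.
#' @param semantic_scores `t x k_s` matrix of semantic PC scores, row-aligned
#'   with `visual_scores`.
#' @param visual_pca,semantic_pca Optional fitted [fit_pca()] models used to
#'   project between the original spaces and the scores; identity models are
#'   substituted when omitted, in which case the "scores" are taken to live
#'   in the original spaces.
#' @param provenance Optional free-form provenance list (dataset id, seed).
#' @return An object of class `visual_semantic_map` with elements `B`
#'   (`k_v x k_s`), the two PCA models, and `t`.
#' @export
fit_visual_semantic <- function(visual_scores, semantic_scores,
                                visual_pca = NULL, semantic_pca = NULL,
                                provenance = list()) {
  x <- check_matrix(visual_scores, "visual_scores")
  y <- check_matrix(semantic_scores, "semantic_scores")
  if (nrow(x) != nrow(y)) abort("Row counts of the two score matrices differ.")
  if (nrow(x) < 2) abort("At least 2 aligned trials are required.")
  t_n <- nrow(x)
  B <- crossprod(x, y) / (t_n - 1)
  structure(
    list(B = B,
         visual_pca = visual_pca %||% identity_pca(ncol(x)),
         semantic_pca = semantic_pca %||% identity_pca(ncol(y)),
         t = t_n, provenance = provenance),
    class = "visual_semantic_map"
  )
}

#' Fit the full concept-mapping pipeline from raw trial data
#'
#' Fits whitened PCAs (retaining the minimum number of components explaining
#' `variance_threshold` of the variance) to the visual feature matrix and to
#' the semantic trial vectors, then the outer-product visual-semantic matrix
#' on the scores. Rows of the two inputs must describe the same trials in the
#' same order; when both carry row names, alignment is checked.
#'
#' @param features `t x v` matrix of per-trial visual feature values.
#' @param semantics `t x d` matrix of per-trial semantic vectors.
#' @param variance_threshold PCA retention threshold for both spaces.
#' @param whiten Whiten the PC scores (default TRUE).
#' @param provenance Optional provenance list.
#' @return A `visual_semantic_map`.
#' @export
fit_concept_map <- function(features, semantics, variance_threshold = 0.9,
                            whiten = TRUE, provenance = list()) {
  features <- check_matrix(features, "features")
  semantics <- check_matrix(semantics, "semantics")
  if (nrow(features) != nrow(semantics)) {
    abort("`features` and `semantics` must have the same number of trials.")
  }
  rf <- rownames(features); rs <- rownames(semantics)
  if (!is.null(rf) && !is.null(rs) && !identical(rf, rs)) {
    if (!setequal(rf, rs)) abort("Trial ids of `features` and `semantics` differ.")
    features <- features[rs, , drop = FALSE]
  }
  vp <- fit_pca(features, variance_threshold, whiten = whiten)
  sp <- fit_pca(semantics, variance_threshold, whiten = whiten)
  fit_visual_semantic(pca_transform(vp, features),
                      pca_transform(sp, semantics),
                      visual_pca = vp, semantic_pca = sp,
                      provenance = provenance)
}

#' @export
print.visual_semantic_map <- function(x, ...) {
  cat(sprintf("<visual_semantic_map: %d visual x %d semantic PCs, %d trials>\n",
              nrow(x$B), ncol(x$B), x$t))
  invisible(x)
}

#' Concept label to visual feature values
#'
#' Embeds the word, projects through the semantic PCA, multiplies by the
#' visual-semantic matrix (visual PC values = `B %*%` semantic PC values) and
#' inverts the visual PCA, yielding the channel-space feature vector
#' associated with the concept.
#'
#' @param word A word in the embedding vocabulary.
#' @param embedding An [embedding_model()].
#' @param map A fitted `visual_semantic_map`.
#' @return An object of class `concept_representation` (label, `features`,
#'   optional CI bounds).
#' @export
concept_to_features <- function(word, embedding, map) {
  stopifnot(inherits(map, "visual_semantic_map"))
  if (!word %in% embedding$vocab) {
    abort(sprintf("'%s' is not in the embedding vocabulary.", word))
  }
  sem <- embedding$vectors[word, ]
  feats <- semantic_vector_to_features(sem, map)
  new_concept_representation(word, feats)
}

# Semantic-space vector (length d) -> channel-space feature vector.
semantic_vector_to_features <- function(sem, map) {
  s_scores <- pca_transform(map$semantic_pca, sem)
  v_scores <- s_scores %*% t(map$B)
  drop(pca_inverse(map$visual_pca, v_scores))
}

#' Visual feature values to a semantic vector
#'
#' The reverse projection: visual PCA forward, multiply by the transpose of
#' the visual-semantic matrix, semantic PCA inverse. Adjoint to
#' [concept_to_features()] through `B`/`B'`.
#'
#' @param features Channel-space feature vector (length `v`).
#' @param map A fitted `visual_semantic_map`.
#' @return Numeric semantic vector of length `d`.
#' @export
features_to_semantics <- function(features, map) {
  stopifnot(inherits(map, "visual_semantic_map"))
  v_scores <- pca_transform(map$visual_pca, features)
  s_scores <- v_scores %*% map$B
  drop(pca_inverse(map$semantic_pca, s_scores))
}

new_concept_representation <- function(label, features,
                                       ci_lower = NULL, ci_upper = NULL,
                                       provenance = list()) {
  if (!is.null(ci_lower) && !is.null(ci_upper) &&
      any(ci_lower > ci_upper)) {
    abort("Confidence bounds are inverted (lower > upper).")
  }
  structure(
    list(label = label, features = features,
         ci_lower = ci_lower, ci_upper = ci_upper, provenance = provenance),
    class = "concept_representation"
  )
}

#' @export
print.concept_representation <- function(x, ...) {
  cat(sprintf("<concept_representation '%s': %d features%s>\n",
              x$label, length(x$features),
              if (!is.null(x$ci_lower)) ", with 95%% CI" else ""))
  invisible(x)
}
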
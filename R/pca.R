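#' Fit a whitened principal component analysis
#'
#' Centered PCA retaining the minimum number of components whose cumulative
#' explained variance reaches `variance_threshold` of the total. With
#' `whiten = TRUE` (the default throughout the toolkit), forward-transformed
#' scores have unit variance on the fitting data, which makes the
#' outer-product visual-semantic coefficients read as correlations.
#'
#' @param x Numeric matrix or data frame (`t` rows, `t >= 2`).
#' @param variance_threshold Fraction of total variance to retain (0, 1].
#' @param whiten Scale scores to unit variance.
#' @return An object of class `pca_model` with `mean`, `rotation`
#'   (orthonormal columns, retained components only), `sdev`, `k`,
#'   `explained` (per-component variance fractions), and `whiten`.
#' @export
fit_pca <- function(x, variance_threshold = 0.9, whiten = TRUE) {
  x <- check_matrix(x, "x")
  if (nrow(x) < 2) abort("PCA requires at least 2 rows.")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  tot <- sum(p$sdev^2)
  if (tot == 0) abort("Zero total variance: PCA undefined.")
  explained <- p$sdev^2 / tot
  k <- which(cumsum(explained) >= variance_threshold - 1e-12)[1]
  structure(
    list(mean = p$center,
         rotation = p$rotation[, seq_len(k), drop = FALSE],
         sdev = p$sdev[seq_len(k)],
         k = k,
         explained = explained,
         variance_threshold = variance_threshold,
         whiten = whiten,
         d = ncol(x)),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model: %d of %d dimensions retained (%.1f%% variance%s)>\n",
              x$k, x$d, 100 * sum(x$explained[seq_len(x$k)]),
              if (x$whiten) ", whitened" else ""))
  invisible(x)
}

#' Transform data to (whitened) principal component scores
#'
#' @param model A [fit_pca()] model.
#' @param x Matrix (rows are observations) or a single vector of length `d`.
#' @return Score matrix, `nrow(x)` by `k`.
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- check_matrix(x, "x")
  if (ncol(x) != model$d) {
    abort(sprintf("Expected %d columns, got %d.", model$d, ncol(x)))
  }
  scores <- sweep(x, 2, model$mean, "-") %*% model$rotation
  if (model$whiten) scores <- sweep(scores, 2, model$sdev, "/")
  scores
}

#' Inverse-transform scores back to the original space
#'
#' Exact inverse of [pca_transform()] on the retained subspace.
#'
#' @param model A [fit_pca()] model.
#' @param scores Score matrix (`k` columns) or a vector of length `k`.
#' @return Matrix in the original `d`-dimensional space.
#' @export
pca_inverse <- function(model, scores) {
  stopifnot(inherits(model, "pca_model"))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  scores <- check_matrix(scores, "scores")
  if (ncol(scores) != model$k) {
    abort(sprintf("Expected %d score columns, got %d.", model$k, ncol(scores)))
  }
  if (model$whiten) scores <- sweep(scores, 2, model$sdev, "*")
  sweep(scores %*% t(model$rotation), 2, model$mean, "+")
}

# Identity PCA over a d-dimensional space: transform/inverse are the
# identity map. Used for fitting maps directly on already-reduced scores and
# in delegation tests.
identity_pca <- function(d) {
  structure(
    list(mean = rep(0, d), rotation = diag(d), sdev = rep(1, d), k = d,
         explained = rep(1 / d, d), variance_threshold = 1,
         whiten = FALSE, d = d),
    class = "pca_model"
  )
}
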
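# 2-D visualization of recovered representations: a compact exact t-SNE
# (suitable for the small concept sets this toolkit handles, up to a few
# hundred items) plus orthogonal Procrustes alignment between layouts.

# Conditional probabilities with per-point precision calibrated to the
# target perplexity by bisection.
tsne_input_probs <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (iter in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 2; next }
      p <- w / sw
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - target) < 1e-6) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi) && hi < 1e19) (lo + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' Project representations to two dimensions
#'
#' Embeds items in the plane with a compact exact t-SNE using correlation
#' distance (1 - Pearson r between feature vectors), then optionally aligns
#' the layout to a reference with an orthogonal Procrustes transform so that
#' two embeddings can be compared position by position. Deterministic given
#' the seed.
#'
#' @param vectors `n x v` matrix of representations (`n >= 3`), item labels
#'   as row names.
#' @param perplexity t-SNE perplexity (effective neighborhood size).
#' @param seed RNG seed for the initial layout.
#' @param reference Optional reference layout (`n x 2` matrix or the tibble
#'   returned by this function, same items in the same order) to align to.
#' @param n_iter Optimization iterations.
#' @return A tibble: `label`, `x`, `y`.
#' @export
embed_2d <- function(vectors, perplexity = 15, seed = NULL, reference = NULL,
                     n_iter = 500) {
  vectors <- check_matrix(vectors, "vectors")
  n <- nrow(vectors)
  if (n < 3) abort("At least 3 items are required.")
  if (perplexity >= n) perplexity <- max((n - 1) / 3, 1)
  d <- 1 - cor(t(vectors))
  diag(d) <- 0
  P <- tsne_input_probs(d^2, perplexity)

  y <- with_seed(seed, matrix(rnorm(n * 2, sd = 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  eta <- 100
  for (it in seq_len(n_iter)) {
    ex <- if (it <= 100) 4 else 1      # early exaggeration
    mom <- if (it <= 250) 0.5 else 0.8
    sumy <- rowSums(y^2)
    num <- 1 / (1 + outer(sumy, sumy, "+") - 2 * tcrossprod(y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% y
    inc <- mom * inc - eta * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  if (!is.null(reference)) {
    ref <- if (is.data.frame(reference)) as.matrix(reference[, c("x", "y")]) else reference
    y <- procrustes_align(y, ref)
  }
  tibble(label = rownames(vectors) %||% paste0("item", seq_len(n)),
         x = y[, 1], y = y[, 2])
}

#' Orthogonal Procrustes alignment
#'
#' Finds the translation, scaling and orthogonal rotation/reflection of `x`
#' minimizing the squared distance to `ref` and returns the aligned
#' coordinates.
#'
#' @param x,ref Numeric matrices of the same shape (items by coordinates).
#' @return The aligned version of `x`.
#' @export
procrustes_align <- function(x, ref) {
  x <- check_matrix(x, "x"); ref <- check_matrix(ref, "ref")
  if (!all(dim(x) == dim(ref))) abort("`x` and `ref` must have the same shape.")
  cx <- colMeans(x); cr <- colMeans(ref)
  xc <- sweep(x, 2, cx); rc <- sweep(ref, 2, cr)
  s <- svd(crossprod(rc, xc))
  rot <- s$v %*% t(s$u)
  scale <- sum(s$d) / sum(xc^2)
  sweep(scale * xc %*% rot, 2, cr, "+")
}
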
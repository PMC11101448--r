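#' Fit a statistical model of a feature extractor's channel space
#'
#' Given a corpus of channel-mean activations (one row per image, one column
#' per channel), this standardizes each channel, estimates the channel
#' covariance with analytic shrinkage toward its diagonal, derives the
#' symmetric ZCA whitening transform and its inverse (the coloring
#' transform), and fits a Gaussian kernel density to each channel in the
#' whitened space. The fitted model supports drawing pseudo-random target
#' feature vectors whose joint second-order structure matches the corpus.
#'
#' The shrinkage intensity is the Schaefer-Strimmer analytic estimate for a
#' diagonal target (computed on the standardized data); it can be overridden.
#' Kernel bandwidths default to Scott's rule, `sd * n^(-1/5)`, per whitened
#' channel.
#'
#' @param activations Numeric matrix or data frame, `t` images by `v`
#'   channels; `t >= 2` and no constant column.
#' @param shrinkage Optional shrinkage intensity in `[0, 1]`; `NULL` uses the
#'   analytic estimate.
#' @param bandwidth Optional kernel bandwidth(s): a single value or one per
#'   channel; `NULL` uses Scott's rule.
#' @return An object of class `feature_space` with elements `mean`, `sd`,
#'   `sigma` (shrunk covariance of the standardized channels), `lambda`
#'   (shrinkage intensity), `whiten` / `color` (mutually inverse transforms),
#'   and `kde` (per-channel sample points and bandwidth).
#' @export
fit_feature_space <- function(activations, shrinkage = NULL, bandwidth = NULL) {
  x <- check_matrix(activations, "activations")
  t_n <- nrow(x); v <- ncol(x)
  if (t_n < 2) abort("At least 2 rows of activations are required.")
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  if (any(s == 0)) {
    abort(sprintf("Constant activation column(s): %s",
                  paste(head(which(s == 0), 5), collapse = ", ")))
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, s, "/")
  r <- crossprod(z) / (t_n - 1)   # correlation matrix of the channels

  lambda <- shrinkage %||% shrinkage_intensity(z, r)
  lambda <- min(max(lambda, 0), 1)
  sigma <- (1 - lambda) * r
  diag(sigma) <- diag(r)          # diagonal target: shrink off-diagonals only

  eig <- eigen(sigma, symmetric = TRUE)
  if (any(eig$values <= 0)) abort("Shrunk covariance is not positive definite.")
  W <- eig$vectors %*% (t(eig$vectors) / sqrt(eig$values))
  C <- eig$vectors %*% (t(eig$vectors) * sqrt(eig$values))

  zw <- z %*% W
  n_eff <- t_n
  bw <- if (is.null(bandwidth)) {
    apply(zw, 2, sd) * n_eff^(-1 / 5)
  } else {
    rep_len(bandwidth, v)
  }
  kde <- lapply(seq_len(v), function(j) list(points = zw[, j], bw = bw[j]))

  structure(
    list(mean = mu, sd = s, sigma = sigma, lambda = lambda,
         whiten = W, color = C, kde = kde, n = t_n, v = v,
         channels = colnames(x) %||% paste0("ch", seq_len(v))),
    class = "feature_space"
  )
}

# Schaefer-Strimmer analytic shrinkage intensity toward the diagonal target:
# lambda = sum of estimated variances of the off-diagonal correlations over
# the sum of their squares.
shrinkage_intensity <- function(z, r) {
  n <- nrow(z)
  wbar <- r * (n - 1) / n                 # mean of w_kij = z_ki z_kj
  sq <- crossprod(z^2)                    # sum_k z_ki^2 z_kj^2
  var_w <- (sq - n * wbar^2) * n / ((n - 1)^3)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  if (denom == 0) return(1)
  min(1, max(0, sum(var_w[off]) / denom))
}

#' @export
print.feature_space <- function(x, ...) {
  cat(sprintf("<feature_space: %d channels fitted on %d images>\n", x$v, x$n))
  cat(sprintf("  shrinkage intensity: %.4f\n", x$lambda))
  invisible(x)
}

#' Draw pseudo-random target feature vectors
#'
#' Independent draws from each whitened channel's kernel density (a uniformly
#' chosen sample point plus Gaussian noise at the bandwidth scale, exact for
#' Gaussian kernels) are colored back through the inverse whitening transform
#' and unstandardized, yielding target vectors in the original channel space.
#'
#' @param model A fitted [fit_feature_space()] model.
#' @param n Number of vectors to draw (`n >= 0`).
#' @param seed Optional seed for reproducible draws.
#' @return An `n` by `v` matrix of target feature vectors.
#' @export
sample_target_features <- function(model, n, seed = NULL) {
  if (!inherits(model, "feature_space")) abort("`model` must be a fitted feature_space.")
  if (n < 0) abort("`n` must be non-negative.")
  v <- model$v
  draws <- with_seed(seed, {
    m <- matrix(0, nrow = n, ncol = v)
    if (n > 0) {
      for (j in seq_len(v)) {
        k <- model$kde[[j]]
        idx <- sample.int(length(k$points), n, replace = TRUE)
        m[, j] <- k$points[idx] + rnorm(n, sd = k$bw)
      }
    }
    m
  })
  out <- draws %*% model$color
  out <- sweep(sweep(out, 2, model$sd, "*"), 2, model$mean, "+")
  colnames(out) <- model$channels
  out
}

# Numeric CDF of a fitted per-channel kernel density (Gaussian kernels).
kde_cdf <- function(kde, q) {
  vapply(q, function(qq) mean(pnorm((qq - kde$points) / max(kde$bw, .Machine$double.eps))),
         numeric(1))
}

#' Whiten or color feature vectors under a fitted feature-space model
#'
#' `feature_whiten()` standardizes rows and applies the ZCA transform;
#' `feature_color()` is its exact inverse.
#'
#' @param model A fitted [fit_feature_space()] model.
#' @param x Matrix of feature vectors (rows) in the original channel space
#'   (for whitening) or whitened space (for coloring).
#' @return A matrix of the same shape.
#' @export
feature_whiten <- function(model, x) {
  x <- check_matrix(x, "x")
  z <- sweep(sweep(x, 2, model$mean, "-"), 2, model$sd, "/")
  z %*% model$whiten
}

#' @rdname feature_whiten
#' @export
feature_color <- function(model, x) {
  x <- check_matrix(x, "x")
  out <- x %*% model$color
  sweep(sweep(out, 2, model$sd, "*"), 2, model$mean, "+")
}
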
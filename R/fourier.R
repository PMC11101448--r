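# Fourier parameterization of optimizable images.
#
# Images are stored as complex 2-D Fourier coefficients per color channel.
# Rendering applies 1/f frequency scaling, an inverse FFT, a color
# decorrelation matrix, and a smooth sigmoid map into the display range.
# Every step is linear or smooth, so gradients flow back to the coefficients
# exactly.

#' Initialize random Fourier image parameters
#'
#' Real and imaginary parts of every coefficient are drawn from a Gaussian
#' with the given standard deviation (default 0.01), seeded for
#' reproducibility.
#'
#' @param size Image side length in pixels (`size > 0`).
#' @param seed Optional RNG seed.
#' @param scale Standard deviation of the initial coefficients.
#' @param channels Number of color channels (3 for RGB).
#' @return An object of class `fourier_params`.
#' @export
init_fourier_params <- function(size, seed = NULL, scale = 0.01, channels = 3) {
  if (size <= 0) abort("`size` must be positive.")
  coef <- with_seed(seed, {
    array(complex(real = rnorm(size * size * channels, sd = scale),
                  imaginary = rnorm(size * size * channels, sd = scale)),
          dim = c(size, size, channels))
  })
  structure(list(coef = coef, size = size, scale = scale, channels = channels),
            class = "fourier_params")
}

# Per-coefficient 1/f scaling. The DC bin (frequency zero) uses the minimum
# nonzero frequency's scale to avoid division by zero.
freq_scale <- function(size) {
  f1 <- c(seq(0, floor(size / 2)), seq(-ceiling(size / 2) + 1, -1)) / size
  f <- sqrt(outer(f1^2, f1^2, "+"))
  fmin <- 1 / size
  1 / pmax(f, fmin)
}

# Mildly correlated RGB covariance Cholesky factor, for use as a default
# color-decorrelation matrix on realistic renders. Toy fixtures use identity.
#' Default color decorrelation matrix
#'
#' A fixed Cholesky factor of a mildly correlated RGB covariance, standing in
#' for a matrix estimated from a natural-image corpus. Supply your own
#' 3x3 matrix (e.g. `chol(cov(rgb_corpus))`) for corpus-faithful rendering.
#' @return A 3x3 numeric matrix.
#' @export
default_color_matrix <- function() {
  cov_rgb <- matrix(c(1.00, 0.80, 0.60,
                      0.80, 1.00, 0.80,
                      0.60, 0.80, 1.00), 3, 3)
  t(chol(cov_rgb))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Render an image from Fourier parameters
#'
#' Pipeline: per-frequency 1/f normalization (scaled by `sqrt(h * w)`, the
#' usual spectrum gain for Fourier-parameterized images), inverse Fourier
#' transform,
#' color decorrelation (a 3x3 mixing matrix applied to each pixel's channel
#' vector), and a smooth sigmoid squashing into the (0, 1) display range.
#' Zero coefficients therefore render to a constant mid-range (0.5) image.
#' The map is differentiable end to end; set `range_map = FALSE` to obtain
#' the pre-sigmoid image (linear in the coefficients).
#'
#' @param params A [init_fourier_params()] object.
#' @param color_matrix 3x3 color mixing matrix (identity by default; see
#'   [default_color_matrix()]).
#' @param range_map Apply the sigmoid display-range map (default TRUE).
#' @return Numeric array `size x size x channels`.
#' @export
render_image <- function(params, color_matrix = NULL, range_map = TRUE) {
  stopifnot(inherits(params, "fourier_params"))
  n <- params$size
  ch <- params$channels
  cm <- color_matrix %||% diag(ch)
  if (!is.matrix(cm) || any(dim(cm) != ch)) {
    abort(sprintf("`color_matrix` must be %d x %d.", ch, ch))
  }
  fs <- freq_scale(n)
  x <- array(0, dim = c(n, n, ch))
  for (c in seq_len(ch)) {
    z <- fft(params$coef[, , c] * fs, inverse = TRUE) / n
    if (max(abs(Im(z))) > 1e-6 * (1 + max(abs(Re(z))))) {
      # informative, not an error: coefficients need not be conjugate
      # symmetric; only the real part is used
    }
    x[, , c] <- Re(z)
  }
  xm <- matrix(x, ncol = ch) %*% t(cm)
  x <- array(xm, dim = c(n, n, ch))
  if (range_map) x <- sigmoid(x)
  x
}

# Gradient of a scalar loss w.r.t. the complex Fourier coefficients, given
# the gradient w.r.t. the rendered image. Returns a complex array whose real
# and imaginary parts are the partial derivatives w.r.t. the coefficient real
# and imaginary parts.
render_gradient <- function(params, g_img, color_matrix = NULL,
                            range_map = TRUE, image_pre = NULL) {
  n <- params$size
  ch <- params$channels
  cm <- color_matrix %||% diag(ch)
  if (range_map) {
    if (is.null(image_pre)) abort("`image_pre` required when range_map = TRUE.")
    s <- sigmoid(image_pre)
    g_img <- g_img * s * (1 - s)
  }
  gm <- matrix(g_img, ncol = ch) %*% cm   # adjoint of x %*% t(cm)
  g_x <- array(gm, dim = c(n, n, ch))
  fs <- freq_scale(n)
  grad <- array(complex(real = 0), dim = c(n, n, ch))
  for (c in seq_len(ch)) {
    grad[, , c] <- (fft(g_x[, , c]) / n) * fs
  }
  grad
}

# Pre-sigmoid render, kept for gradient computation.
render_pre <- function(params, color_matrix = NULL) {
  render_image(params, color_matrix = color_matrix, range_map = FALSE)
}
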
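# Differentiable image-feature extractors.
#
# An extractor is any object of class `feature_extractor` providing:
#   - $layers: named list; each entry has a $channels count
#   - extractor_forward(extractor, image): per-layer activation maps
#   - extractor_gradient(extractor, image, layer, g): gradient of
#     sum(g * channel_means(layer)) with respect to the image pixels
# The toy extractor implements this contract with frozen random circular
# convolutions (computed in the Fourier domain) followed by a smooth
# nonlinearity, stacked into one or more stages; features are spatial means
# per channel. It is deterministic given its seed and exactly differentiable.

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}
softplus_prime <- function(x) 1 / (1 + exp(-x))

#' Create a small frozen differentiable feature extractor
#'
#' Builds a fixed-parameter image-to-channel map: one or more stages of
#' random circular convolution (applied via FFT) followed by a softplus
#' nonlinearity, with features defined as the spatial mean of each channel's
#' activation map. The extractor is deterministic given its seed and supports
#' exact analytic gradients of any scalar function of its features with
#' respect to the input pixels, which is what the image-synthesis optimizers
#' require.
#'
#' @param channels Integer vector of per-stage channel counts; each stage
#'   becomes a named layer (`conv1`, `conv2`, ...).
#' @param size Image side length in pixels (images are `size x size x 3`).
#' @param seed Seed fixing the frozen convolution kernels.
#' @param kernel_size Side length of the convolution kernels.
#' @param activation `"tanh"` (default; smooth and signed), `"softplus"`, or
#'   `"linear"`.
#' @return An object of class `c("toy_extractor", "feature_extractor")`.
#' @export
make_toy_extractor <- function(channels, size, seed = 1,
                               kernel_size = 3,
                               activation = c("tanh", "softplus", "linear")) {
  activation <- match.arg(activation)
  if (any(channels < 1)) abort("`channels` entries must be >= 1.")
  if (size < kernel_size) abort("`size` must be at least `kernel_size`.")
  n_in <- c(3L, channels[-length(channels)])
  layers <- with_seed(seed, {
    lapply(seq_along(channels), function(l) {
      c_in <- n_in[l]; c_out <- channels[l]
      kf <- array(complex(real = 0), dim = c(size, size, c_in, c_out))
      for (j in seq_len(c_out)) {
        for (i in seq_len(c_in)) {
          k <- matrix(0, size, size)
          # zero-sum kernels: no response to constant inputs, so features
          # are mean-free directions rather than offsets
          kk <- rnorm(kernel_size^2, sd = 1 / sqrt(c_in * kernel_size^2))
          k[seq_len(kernel_size), seq_len(kernel_size)] <- kk - mean(kk)
          kf[, , i, j] <- fft(k)
        }
      }
      list(kernel_fft = kf, channels = c_out)
    })
  })
  names(layers) <- paste0("conv", seq_along(layers))
  structure(
    list(layers = layers, size = size, activation = activation,
         input_channels = 3L, seed = seed),
    class = c("toy_extractor", "feature_extractor")
  )
}

#' @export
print.toy_extractor <- function(x, ...) {
  cat(sprintf("<toy_extractor: %dx%d input, layers %s (%s)>\n",
              x$size, x$size,
              paste(sprintf("%s=%d", names(x$layers),
                            vapply(x$layers, `[[`, integer(1), "channels")),
                    collapse = ", "),
              x$activation))
  invisible(x)
}

# circular convolution of a stack of maps (h x w x c_in) with precomputed
# kernel FFTs (h x w x c_in x c_out); returns h x w x c_out
circ_conv_stack <- function(maps, kernel_fft, conjugate = FALSE) {
  d <- dim(kernel_fft)
  h <- d[1]; c_in <- d[3]; c_out <- d[4]
  in_fft <- lapply(seq_len(c_in), function(i) fft(maps[, , i]))
  out <- array(0, dim = c(h, h, c_out))
  for (j in seq_len(c_out)) {
    acc <- matrix(complex(real = 0), h, h)
    for (i in seq_len(c_in)) {
      kf <- kernel_fft[, , i, j]
      if (conjugate) kf <- Conj(kf)
      acc <- acc + in_fft[[i]] * kf
    }
    out[, , j] <- Re(fft(acc, inverse = TRUE)) / (h * h)
  }
  out
}

# Full forward pass keeping pre-activations (needed for backprop).
toy_forward_pass <- function(extractor, image) {
  stages <- vector("list", length(extractor$layers))
  maps <- image
  for (l in seq_along(extractor$layers)) {
    pre <- circ_conv_stack(maps, extractor$layers[[l]]$kernel_fft)
    act <- switch(extractor$activation,
                  tanh = tanh(pre),
                  softplus = softplus(pre),
                  linear = pre)
    stages[[l]] <- list(pre = pre, maps = act)
    maps <- act
  }
  names(stages) <- names(extractor$layers)
  stages
}

#' Spatial mean of an activation map
#'
#' Reduces an `h x w x c` activation map to one scalar per channel by
#' averaging over spatial positions (location is deliberately ignored).
#'
#' @param map Numeric array `h x w x c` (or a matrix, treated as one channel).
#' @return Numeric vector of length `c`.
#' @export
channel_means <- function(map) {
  if (is.matrix(map)) map <- array(map, dim = c(dim(map), 1L))
  apply(map, 3, mean)
}

#' Extract channel-mean feature values from an image
#'
#' Runs the extractor and spatially averages each requested layer's
#' activation maps, concatenating layers in the requested order. These
#' channel means are the "feature values" that the whole toolkit operates on.
#'
#' @param image Numeric array `size x size x 3`, finite values.
#' @param extractor A `feature_extractor`.
#' @param layers Character vector of layer names; defaults to all layers in
#'   declared order.
#' @return Named numeric feature vector (one value per channel per layer).
#' @export
extract_channel_features <- function(image, extractor,
                                     layers = names(extractor$layers)) {
  UseMethod("extract_channel_features", extractor)
}

#' @export
extract_channel_features.toy_extractor <- function(image, extractor,
                                                   layers = names(extractor$layers)) {
  check_image(image, extractor)
  unknown <- setdiff(layers, names(extractor$layers))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown layer id(s): %s", paste(unknown, collapse = ", ")))
  }
  stages <- toy_forward_pass(extractor, image)
  feats <- unlist(lapply(layers, function(l) {
    f <- channel_means(stages[[l]]$maps)
    names(f) <- paste0(l, ".", seq_along(f))
    f
  }))
  if (!all(is.finite(feats))) abort("Non-finite activations encountered.")
  feats
}

check_image <- function(image, extractor) {
  if (!is.array(image) || length(dim(image)) != 3) {
    abort("`image` must be a 3-d array (height x width x 3).")
  }
  d <- dim(image)
  if (d[1] != extractor$size || d[2] != extractor$size || d[3] != 3) {
    abort(sprintf("`image` must be %d x %d x 3.", extractor$size, extractor$size))
  }
  if (!all(is.finite(image))) abort("`image` contains non-finite values.")
  invisible(TRUE)
}

#' Gradient of a weighted feature sum with respect to the image
#'
#' Returns `d sum(g * features(layer)) / d image`, the backbone of the
#' synthesis optimizers. Exact (analytic) for the toy extractor.
#'
#' @param extractor A `feature_extractor`.
#' @param image Input image array.
#' @param layer Layer name whose features are weighted.
#' @param g Numeric weight vector, one per channel of `layer`.
#' @return Gradient array with the same shape as `image`.
#' @export
extractor_gradient <- function(extractor, image, layer, g) {
  UseMethod("extractor_gradient")
}

#' @export
extractor_gradient.toy_extractor <- function(extractor, image, layer, g) {
  check_image(image, extractor)
  l_target <- match(layer, names(extractor$layers))
  if (is.na(l_target)) abort(sprintf("Unknown layer id: %s", layer))
  if (length(g) != extractor$layers[[l_target]]$channels) {
    abort("`g` length must match the layer's channel count.")
  }
  stages <- toy_forward_pass(extractor, image)
  n_pix <- extractor$size^2
  # seed gradient: d(sum g * mean(map)) / d map = g / n_pix broadcast
  g_maps <- array(rep(g / n_pix, each = n_pix),
                  dim = c(extractor$size, extractor$size, length(g)))
  for (l in seq(l_target, 1)) {
    g_pre <- switch(extractor$activation,
                    tanh = g_maps * (1 - stages[[l]]$maps^2),
                    softplus = g_maps * softplus_prime(stages[[l]]$pre),
                    linear = g_maps)
    # adjoint of circular convolution: correlate with conjugate kernel FFTs
    kf <- extractor$layers[[l]]$kernel_fft
    kf_t <- aperm(kf, c(1, 2, 4, 3))
    g_maps <- circ_conv_stack(g_pre, kf_t, conjugate = TRUE)
  }
  g_maps
}
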
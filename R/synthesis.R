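# Image synthesis by first-order optimization of Fourier coefficients.

#' Synthesis configuration
#'
#' Collects the optimizer and objective settings for stimulus synthesis and
#' caricature reconstruction. Defaults follow the standard recipe: Adam with
#' decoupled weight decay (weight decay 0.1, learning rate 0.05, beta1 0.9,
#' beta2 0.999), 1500 iterations for MSE stimulus synthesis; caricature
#' reconstructions conventionally use 2000 iterations and exponent
#' `alpha = 4` (see [reconstruction_config()]).
#'
#' Robustness-transform ranges apply only to the caricature objective: at
#' each iteration the rendered image receives a random rotation (degrees),
#' translation (pixels) and homothecy (scale factor) before feature
#' extraction, which suppresses high-frequency adversarial artifacts.
#'
#' @param iterations Number of optimization steps (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param weight_decay Decoupled weight-decay coefficient.
#' @param beta1,beta2 Adam moment decay rates.
#' @param adam_epsilon Adam denominator stabilizer. The default is small so
#'   that optimization remains scale-invariant for feature spaces whose
#'   activations (hence gradients) are orders of magnitude below 1.
#' @param alpha Caricature exponent (>= 0).
#' @param objective `"mse"` or `"caricature"`.
#' @param rotation Max absolute rotation in degrees (uniform).
#' @param translation Max absolute translation in pixels (uniform).
#' @param scale_range Two-element homothecy range (uniform).
#' @param transform_robustness Apply the random transforms (caricature only).
#' @param init_scale Standard deviation of the initial Fourier coefficients.
#' @param layer Extractor layer to optimize against (default: first layer).
#' @param color_matrix Optional 3x3 color decorrelation matrix.
#' @param seed RNG seed covering initialization and the random transforms.
#' @return A list of class `synthesis_config`.
#' @export
synthesis_config <- function(iterations = 1500, learning_rate = 0.05,
                             weight_decay = 0.1, beta1 = 0.9, beta2 = 0.999,
                             adam_epsilon = 1e-12,
                             alpha = 4, objective = c("mse", "caricature"),
                             rotation = 5, translation = 4,
                             scale_range = c(0.95, 1.05),
                             transform_robustness = NULL,
                             init_scale = 0.01, layer = NULL,
                             color_matrix = NULL, seed = NULL) {
  objective <- match.arg(objective)
  if (iterations < 1) abort("`iterations` must be >= 1.")
  if (learning_rate <= 0) abort("`learning_rate` must be > 0.")
  if (alpha < 0) abort("`alpha` must be >= 0.")
  structure(
    list(iterations = iterations, learning_rate = learning_rate,
         weight_decay = weight_decay, beta1 = beta1, beta2 = beta2,
         adam_epsilon = adam_epsilon,
         alpha = alpha, objective = objective, rotation = rotation,
         translation = translation, scale_range = scale_range,
         transform_robustness = transform_robustness %||% (objective == "caricature"),
         init_scale = init_scale, layer = layer,
         color_matrix = color_matrix, seed = seed),
    class = "synthesis_config"
  )
}

#' @rdname synthesis_config
#' @export
reconstruction_config <- function(iterations = 2000, alpha = 4, ...) {
  synthesis_config(iterations = iterations, alpha = alpha,
                   objective = "caricature", ...)
}

#' Caricature objective
#'
#' The inner product of a target direction `y` with achieved features `phi`,
#' multiplied by their cosine similarity raised to the exponent `alpha`:
#' `<y, phi> * (<y, phi> / (||y|| ||phi||))^alpha`. Maximizing it pushes
#' features along the target direction while the cosine term keeps the
#' angular deviation small; the magnitude of `y` is arbitrary (the objective
#' is 1-homogeneous in each argument).
#'
#' @param y Target feature direction (nonzero).
#' @param phi Achieved feature vector (nonzero, same length).
#' @param alpha Non-negative exponent (integer recommended; even integers are
#'   well defined for negative cosines).
#' @return A scalar objective value.
#' @export
caricature_objective <- function(y, phi, alpha = 4) {
  if (length(y) != length(phi)) abort("`y` and `phi` must have equal length.")
  ny <- sqrt(sum(y^2)); np <- sqrt(sum(phi^2))
  if (ny == 0 || np == 0) abort("Zero-norm input to the caricature objective.")
  d <- sum(y * phi)
  d * (d / (ny * np))^alpha
}

# Gradient of the caricature objective with respect to phi.
caricature_gradient <- function(y, phi, alpha) {
  ny <- sqrt(sum(y^2)); np <- sqrt(sum(phi^2))
  d <- sum(y * phi)
  cosv <- d / (ny * np)
  if (alpha == 0) return(y)
  cosv^alpha * y + d * alpha * cosv^(alpha - 1) *
    (y / (ny * np) - d * phi / (ny * np^3))
}

# Sparse bilinear resampling operator for a small rotation/translation/
# homothecy, with edge padding (clamped coordinates). Output pixel centers
# are inversely mapped into the input image. Returns an n^2 x n^2
# dgCMatrix applied to each vectorized channel.
transform_operator <- function(n, angle_deg, tx, ty, scale) {
  ctr <- (n + 1) / 2
  th <- -angle_deg * pi / 180   # inverse rotation
  co <- cos(th); si <- sin(th)
  grid <- expand.grid(row = seq_len(n), col = seq_len(n))
  xo <- grid$col - ctr - tx
  yo <- grid$row - ctr - ty
  xi <- (co * xo - si * yo) / scale + ctr
  yi <- (si * xo + co * yo) / scale + ctr
  xi <- pmin(pmax(xi, 1), n)
  yi <- pmin(pmax(yi, 1), n)
  x0 <- pmin(floor(xi), n - 1); y0 <- pmin(floor(yi), n - 1)
  fx <- xi - x0; fy <- yi - y0
  out_idx <- seq_len(n * n)
  idx <- function(r, c) (c - 1) * n + r
  Matrix::sparseMatrix(
    i = rep(out_idx, 4),
    j = c(idx(y0, x0), idx(y0, x0 + 1), idx(y0 + 1, x0), idx(y0 + 1, x0 + 1)),
    x = c((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy),
    dims = c(n * n, n * n)
  )
}

apply_operator <- function(op, image) {
  d <- dim(image)
  out <- image
  for (c in seq_len(d[3])) {
    out[, , c] <- matrix(as.numeric(op %*% as.numeric(image[, , c])), d[1], d[2])
  }
  out
}

run_synthesis <- function(target, extractor, config) {
  layer <- config$layer %||% names(extractor$layers)[1]
  if (!layer %in% names(extractor$layers)) {
    abort(sprintf("Unknown layer id: %s", layer))
  }
  v <- extractor$layers[[layer]]$channels
  if (length(target) != v) {
    abort(sprintf("`target` length %d does not match layer '%s' channel count %d.",
                  length(target), layer, v))
  }
  n <- extractor$size
  cm <- config$color_matrix %||% diag(3)
  maximize <- config$objective == "caricature"

  with_seed(config$seed, {
    params <- init_fourier_params(n, seed = NULL, scale = config$init_scale)
    cr <- Re(params$coef); ci <- Im(params$coef)
    m_r <- v_r <- m_i <- v_i <- array(0, dim = dim(cr))
    trace <- numeric(config$iterations)
    lr <- config$learning_rate; wd <- config$weight_decay
    b1 <- config$beta1; b2 <- config$beta2
    eps <- config$adam_epsilon %||% 1e-12

    for (it in seq_len(config$iterations)) {
      params$coef <- array(complex(real = cr, imaginary = ci), dim = dim(cr))
      img_pre <- render_pre(params, cm)
      img <- sigmoid(img_pre)

      op <- NULL
      img_in <- img
      if (maximize && isTRUE(config$transform_robustness)) {
        op <- transform_operator(
          n,
          angle_deg = runif(1, -config$rotation, config$rotation),
          tx = runif(1, -config$translation, config$translation),
          ty = runif(1, -config$translation, config$translation),
          scale = runif(1, config$scale_range[1], config$scale_range[2])
        )
        img_in <- apply_operator(op, img)
      }

      feats <- extract_channel_features(img_in, extractor, layer)
      if (maximize) {
        obj <- caricature_objective(target, feats, config$alpha)
        gfeat <- -caricature_gradient(target, feats, config$alpha) # minimize -obj
      } else {
        obj <- mean((feats - target)^2)
        gfeat <- 2 * (feats - target) / v
      }
      if (!is.finite(obj)) {
        abort(sprintf("Objective diverged (non-finite) at iteration %d.", it))
      }
      trace[it] <- obj

      g_img <- extractor_gradient(extractor, img_in, layer, gfeat)
      if (!is.null(op)) g_img <- apply_operator(Matrix::t(op), g_img)
      gc_cplx <- render_gradient(params, g_img, cm, range_map = TRUE,
                                 image_pre = img_pre)
      gr <- Re(gc_cplx); gi <- Im(gc_cplx)

      # Adam with decoupled weight decay
      m_r <- b1 * m_r + (1 - b1) * gr; v_r <- b2 * v_r + (1 - b2) * gr^2
      m_i <- b1 * m_i + (1 - b1) * gi; v_i <- b2 * v_i + (1 - b2) * gi^2
      bc1 <- 1 - b1^it; bc2 <- 1 - b2^it
      cr <- cr - lr * ((m_r / bc1) / (sqrt(v_r / bc2) + eps) + wd * cr)
      ci <- ci - lr * ((m_i / bc1) / (sqrt(v_i / bc2) + eps) + wd * ci)
    }

    params$coef <- array(complex(real = cr, imaginary = ci), dim = dim(cr))
    final <- render_image(params, cm)
    achieved <- extract_channel_features(final, extractor, layer)
    sse <- sum((achieved - target)^2)
    sst <- sum((target - mean(target))^2)
    r2 <- if (sst > 0) 1 - sse / sst else NA_real_
    structure(
      list(image = final, achieved = achieved, target = target,
           trace = trace, r_squared = r2, objective = config$objective,
           layer = layer, config = config, params = params),
      class = "synthesis_result"
    )
  })
}

#' Synthesize a feature-noise stimulus
#'
#' Optimizes a Fourier-parameterized image so that its channel-mean
#' activations in the chosen extractor layer match the target feature values,
#' minimizing mean squared error with Adam (decoupled weight decay). The
#' result is a "feature-noise" image: pseudo-random in feature space rather
#' than pixel space.
#'
#' @param target Target feature vector for the optimized layer.
#' @param extractor A differentiable `feature_extractor`.
#' @param config A [synthesis_config()].
#' @return A `synthesis_result` with the final image, achieved features, the
#'   per-iteration objective trace, and the reconstruction R^2 (1 - SSE/SStot
#'   between achieved and target).
#' @export
synthesize_stimulus <- function(target, extractor, config = synthesis_config()) {
  config$objective <- "mse"
  run_synthesis(target, extractor, config)
}

#' Reconstruct a caricature image for a feature direction
#'
#' Maximizes the [caricature_objective()] for the given feature direction,
#' applying a small random rotation, translation and homothecy to the
#' rendered image at each iteration before feature extraction (transformation
#' robustness).
#'
#' @param direction Target feature direction (its magnitude is arbitrary).
#' @inheritParams synthesize_stimulus
#' @return A `synthesis_result` (trace holds the objective value, maximized).
#' @export
reconstruct_image <- function(direction, extractor,
                              config = reconstruction_config()) {
  config$objective <- "caricature"
  run_synthesis(direction, extractor, config)
}

#' Visualize a principal component of the feature space
#'
#' Maps the component's loading vector back to channel space and delegates to
#' [reconstruct_image()], caricaturing the feature direction that the
#' component spans.
#'
#' @param pc_index Component index (1-based, within the retained components).
#' @param pca A fitted [fit_pca()] model over channel-space features.
#' @inheritParams synthesize_stimulus
#' @export
visualize_pc <- function(pc_index, pca, extractor,
                         config = reconstruction_config()) {
  stopifnot(inherits(pca, "pca_model"))
  if (pc_index < 1 || pc_index > pca$k) {
    abort(sprintf("`pc_index` must be in 1..%d.", pca$k))
  }
  direction <- pca$rotation[, pc_index]
  reconstruct_image(direction, extractor, config)
}

#' @export
print.synthesis_result <- function(x, ...) {
  cat(sprintf("<synthesis_result: %s objective, %d iterations>\n",
              x$objective, length(x$trace)))
  cat(sprintf("  final objective: %.6g | R^2 vs target: %.4f\n",
              x$trace[length(x$trace)], x$r_squared))
  invisible(x)
}
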
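# Fourier parameterization, rendering, and the synthesis optimizers.

test_that("Fourier initialization is seeded, scaled, and Gaussian", {
  expect_identical(init_fourier_params(8, seed = 3)$coef,
                   init_fourier_params(8, seed = 3)$coef)
  expect_true(all(init_fourier_params(8, seed = 3, scale = 0)$coef == 0))
  p <- init_fourier_params(60, seed = 5, scale = 0.01)  # > 10^4 coefficients
  expect_gt(sd(Re(p$coef)), 0.009)
  expect_lt(sd(Re(p$coef)), 0.011)
  expect_error(init_fourier_params(0), "positive")
})

test_that("rendering maps zero coefficients to constant mid-range and is linear pre-range", {
  p0 <- init_fourier_params(8, scale = 0)
  img <- render_image(p0)
  expect_true(all(img == 0.5))
  p <- init_fourier_params(8, seed = 2, scale = 0.1)
  pre <- render_image(p, range_map = FALSE)
  p2 <- p; p2$coef <- 2 * p2$coef
  expect_equal(render_image(p2, range_map = FALSE), 2 * pre, tolerance = 1e-12)
  expect_true(all(is.finite(render_image(p))))  # real output, no residue
  expect_error(render_image(p, color_matrix = diag(2)), "3 x 3")
})

test_that("render gradients are exact", {
  p <- init_fourier_params(8, seed = 1)
  g <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
  pre <- render_image(p, range_map = FALSE)
  gc <- reprecon:::render_gradient(p, g, range_map = TRUE, image_pre = pre)
  l0 <- sum(g * render_image(p))
  eps <- 1e-6
  pp <- p; pp$coef[2, 3, 1] <- pp$coef[2, 3, 1] + eps
  expect_equal(Re(gc[2, 3, 1]), (sum(g * render_image(pp)) - l0) / eps,
               tolerance = 1e-4)
  pp <- p; pp$coef[2, 3, 1] <- pp$coef[2, 3, 1] + complex(imaginary = eps)
  expect_equal(Im(gc[2, 3, 1]), (sum(g * render_image(pp)) - l0) / eps,
               tolerance = 1e-4)
})

test_that("caricature objective matches its closed form and homogeneity laws", {
  y <- c(3, -1, 2)
  expect_equal(caricature_objective(y, y, 4), sum(y^2))
  expect_equal(caricature_objective(c(1, 0), c(0, 1), 4), 0)
  expect_equal(caricature_objective(c(1, 0), c(1, 1), 4), 0.25)
  expect_equal(caricature_objective(y, 2 * y, 0), 2 * sum(y^2))  # alpha 0 = dot
  set.seed(3)
  for (r in 1:10) {
    a <- rnorm(5); b <- rnorm(5); cpos <- runif(1, 0.1, 5)
    expect_equal(caricature_objective(cpos * a, b, 3),
                 cpos * caricature_objective(a, b, 3), tolerance = 1e-10)
    expect_equal(caricature_objective(a, cpos * b, 3),
                 cpos * caricature_objective(a, b, 3), tolerance = 1e-10)
  }
  expect_error(caricature_objective(c(0, 0), c(1, 1)), "Zero-norm")
  expect_error(caricature_objective(1:2, 1:3), "equal length")
})

test_that("synthesis config validates inputs and carries standard defaults", {
  cfg <- synthesis_config()
  expect_equal(cfg$iterations, 1500)
  expect_equal(cfg$learning_rate, 0.05)
  expect_equal(cfg$weight_decay, 0.1)
  expect_equal(cfg$beta1, 0.9)
  expect_equal(cfg$beta2, 0.999)
  rcfg <- reconstruction_config()
  expect_equal(rcfg$iterations, 2000)
  expect_equal(rcfg$alpha, 4)
  expect_true(rcfg$transform_robustness)
  expect_error(synthesis_config(iterations = 0), "iterations")
  expect_error(synthesis_config(learning_rate = 0), "learning_rate")
  expect_error(synthesis_config(alpha = -1), "alpha")
})

test_that("MSE synthesis converges on the toy fixture and is bit-deterministic", {
  fx <- synthesis_fixture()
  cfg <- synthesis_config(iterations = 120, seed = 11)
  r1 <- synthesize_stimulus(fx$target, fx$extractor, cfg)
  r2 <- synthesize_stimulus(fx$target, fx$extractor, cfg)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(is.finite(r1$trace)))
  expect_lt(r1$trace[120], r1$trace[1])
  expect_lte(r1$r_squared, 1)
  expect_error(synthesize_stimulus(fx$target[1:3], fx$extractor, cfg),
               "does not match")
})

test_that("caricature reconstruction aligns with the direction; negation flips it", {
  fx <- synthesis_fixture()
  y <- fx$target
  rec <- reconstruct_image(y, fx$extractor,
                           reconstruction_config(iterations = 150, seed = 12))
  expect_true(all(is.finite(rec$trace)))
  expect_gt(rec$trace[150], rec$trace[1])   # maximized
  cs <- sum(rec$achieved * y) / sqrt(sum(rec$achieved^2) * sum(y^2))
  expect_gt(cs, 0.5)
  neg <- reconstruct_image(-y, fx$extractor,
                           reconstruction_config(iterations = 150, seed = 12))
  cs_neg <- sum(neg$achieved * y) / sqrt(sum(neg$achieved^2) * sum(y^2))
  expect_lt(cs_neg, 0)
})

test_that("PC visualization delegates to caricature reconstruction", {
  fx <- synthesis_fixture()
  pca <- reprecon:::identity_pca(16)
  cfg <- reconstruction_config(iterations = 40, seed = 9)
  via_pc <- visualize_pc(1, pca, fx$extractor, cfg)
  direct <- reconstruct_image(c(1, rep(0, 15)), fx$extractor, cfg)
  expect_identical(via_pc$trace, direct$trace)
  expect_equal(via_pc$achieved, direct$achieved)
  expect_error(visualize_pc(17, pca, fx$extractor, cfg), "pc_index")
})

test_that("robustness transform operator is exact for the identity and adjoint-consistent", {
  op <- reprecon:::transform_operator(8, 0, 0, 0, 1)
  expect_equal(as.matrix(op), diag(64), ignore_attr = TRUE)
  op2 <- reprecon:::transform_operator(8, 4, 1.5, -1, 1.03)
  x <- rnorm(64); y <- rnorm(64)
  expect_equal(sum(y * as.numeric(op2 %*% x)),
               sum(x * as.numeric(Matrix::t(op2) %*% y)), tolerance = 1e-10)
})
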
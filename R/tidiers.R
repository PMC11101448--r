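# broom-style tidiers for the fitted object classes.

#' @export
tidy.visual_semantic_map <- function(x, ...) {
  B <- x$B
  grid <- tidyr::expand_grid(visual_pc = seq_len(nrow(B)),
                             semantic_pc = seq_len(ncol(B)))
  grid$coefficient <- B[cbind(grid$visual_pc, grid$semantic_pc)]
  grid
}

#' @export
glance.visual_semantic_map <- function(x, ...) {
  tibble(
    n_trials = x$t,
    k_visual = nrow(x$B),
    k_semantic = ncol(x$B),
    visual_variance = sum(x$visual_pca$explained[seq_len(x$visual_pca$k)]),
    semantic_variance = sum(x$semantic_pca$explained[seq_len(x$semantic_pca$k)])
  )
}

#' @export
tidy.coef_test <- function(x, ...) {
  grid <- tidyr::expand_grid(visual_pc = seq_len(nrow(x$z)),
                             semantic_pc = seq_len(ncol(x$z)))
  idx <- cbind(grid$visual_pc, grid$semantic_pc)
  grid$z <- x$z[idx]
  grid$p <- x$p[idx]
  grid$significant <- x$significant[idx]
  grid
}

#' @export
glance.coef_test <- function(x, ...) {
  tibble(
    n_coefficients = length(x$z),
    n_significant = sum(x$significant),
    critical_z = x$critical,
    alpha = x$alpha
  )
}

#' @export
tidy.feature_space <- function(x, ...) {
  tibble(
    channel = x$channels,
    mean = unname(x$mean),
    sd = unname(x$sd),
    bandwidth = vapply(x$kde, `[[`, numeric(1), "bw")
  )
}

#' @export
glance.feature_space <- function(x, ...) {
  tibble(n_images = x$n, n_channels = x$v, shrinkage = x$lambda)
}

#' @export
tidy.pca_model <- function(x, ...) {
  tibble(
    component = seq_along(x$explained),
    variance_fraction = x$explained,
    cumulative = cumsum(x$explained),
    retained = seq_along(x$explained) <= x$k
  )
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble(k = x$k, d = x$d,
         variance_retained = sum(x$explained[seq_len(x$k)]),
         whitened = x$whiten)
}

#' @export
tidy.concept_representation <- function(x, ...) {
  out <- tibble(
    channel = names(x$features) %||% paste0("ch", seq_along(x$features)),
    value = unname(x$features)
  )
  if (!is.null(x$ci_lower)) {
    out$ci_lower <- unname(x$ci_lower)
    out$ci_upper <- unname(x$ci_upper)
  }
  out
}

#' @export
tidy.synthesis_result <- function(x, ...) {
  tibble(iteration = seq_along(x$trace), objective = x$trace)
}

#' @export
glance.synthesis_result <- function(x, ...) {
  tibble(
    objective = x$objective,
    iterations = length(x$trace),
    final_value = x$trace[length(x$trace)],
    r_squared = x$r_squared
  )
}

#' @export
tidy.rdm <- function(x, ...) {
  m <- x$distances
  idx <- which(upper.tri(m), arr.ind = TRUE)
  tibble(
    item_a = x$labels[idx[, 1]],
    item_b = x$labels[idx[, 2]],
    distance = m[idx]
  )
}
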
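# Helpers shared across modules.

#' Evaluate an expression under a local RNG seed
#'
#' Runs `expr` with the RNG seeded to `seed`, restoring the caller's RNG
#' state afterwards so seeded routines never disturb the surrounding stream.
#' `seed = NULL` leaves the current stream untouched. All stochastic routines
#' in the package draw through this scope, which is what makes them
#' seed-deterministic.
#'
#' @param seed A single number, or NULL.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a stream-specific child seed from a master seed
#'
#' Deterministic, stays within the 32-bit integer range, and gives distinct
#' streams to independent stochastic steps driven by one master seed.
#'
#' @param seed Master seed (or NULL, returned as is).
#' @param stream Integer stream index.
#' @return A numeric seed below 2^31.
#' @export
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream * 16807) %% 2147483647
}

check_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix or data frame.", arg))
  }
  if (!all(is.finite(x))) abort(sprintf("`%s` contains non-finite values.", arg))
  x
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) abort("cosine similarity undefined for a zero vector.")
  sum(a * b) / (na * nb)
}

# Permutation p-value with the +1 floor: percentile of `observed` in `null`.
perm_pvalue <- function(observed, null, tail = c("greater", "less", "two")) {
  tail <- match.arg(tail)
  n <- length(null)
  p <- switch(tail,
    greater = (sum(null >= observed) + 1) / (n + 1),
    less    = (sum(null <= observed) + 1) / (n + 1),
    two     = (sum(abs(null) >= abs(observed)) + 1) / (n + 1)
  )
  min(p, 1)
}

upper_tri_vec <- function(m) m[upper.tri(m)]
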
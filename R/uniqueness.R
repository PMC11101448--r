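# Split-half uniqueness analysis: are two groups' recovered representations
# different beyond noise?

# Fit a map on a trial subset and flatten the recovered feature vectors of
# the reference concepts into one long vector. The per-channel mean across
# reference concepts is removed before flattening: every map recovers a
# similar global offset (the fitted feature mean), and without centering that
# shared component saturates both within- and between-group correlations.
half_representation <- function(features, semantics, idx, reference,
                                embedding, variance_threshold) {
  m <- fit_concept_map(features[idx, , drop = FALSE],
                       semantics[idx, , drop = FALSE], variance_threshold)
  reps <- vapply(reference, function(w) {
    concept_to_features(w, embedding, m)$features
  }, numeric(ncol(features)))
  as.numeric(reps - rowMeans(reps))
}

# Same, but with semantic rows permuted within the half (null model).
half_representation_null <- function(features, semantics, idx, reference,
                                     embedding, variance_threshold) {
  idx_perm <- idx[sample.int(length(idx))]
  sem_perm <- semantics[idx_perm, , drop = FALSE]
  # keep the original trial ids: the permutation must break the alignment,
  # not be undone by fit_concept_map's rowname-based realignment
  rownames(sem_perm) <- rownames(semantics)[idx]
  m <- fit_concept_map(features[idx, , drop = FALSE],
                       sem_perm, variance_threshold)
  reps <- vapply(reference, function(w) {
    concept_to_features(w, embedding, m)$features
  }, numeric(ncol(features)))
  as.numeric(reps - rowMeans(reps))
}

#' Split-half uniqueness of two groups' representations
#'
#' Splits each group's trials into random halves, fits a visual-semantic map
#' per half, recovers the feature vectors of a reference concept list through
#' each map, and flattens them into one representation vector per half.
#' The within-group correlation is the mean of corr(A1, A2) and corr(B1, B2);
#' the between-group correlation the mean of corr(A1, B2) and corr(A2, B1).
#' Their difference measures how unique the two groups' representations are.
#' Significance repeats the analysis with trial-permuted (null) maps;
#' confidence intervals resample trials with replacement within each half.
#'
#' @param features_a,semantics_a Group A trial data (aligned rows).
#' @param features_b,semantics_b Group B trial data.
#' @param reference Character vector of reference concepts (the independent
#'   semantic space both groups are projected into).
#' @param embedding An [embedding_model()].
#' @param variance_threshold PCA retention threshold for the per-half fits.
#' @param n_perm Null permutations.
#' @param n_boot Bootstrap resamples (0 to skip the CI).
#' @param seed RNG seed.
#' @param halves Optional explicit split: a list with elements `a` and `b`,
#'   each a list of two index vectors into the group's trials. Random halves
#'   are drawn when omitted.
#' @return A list: `within`, `between`, `difference`, `p` (two-tailed),
#'   `ci_within`, `ci_between`, `detail` (the four half correlations).
#' @export
uniqueness_analysis <- function(features_a, semantics_a,
                                features_b, semantics_b,
                                reference, embedding,
                                variance_threshold = 0.9,
                                n_perm = 200, n_boot = 200, seed = NULL,
                                halves = NULL) {
  fa <- check_matrix(features_a); sa <- check_matrix(semantics_a)
  fb <- check_matrix(features_b); sb <- check_matrix(semantics_b)
  if (nrow(fa) != nrow(sa) || nrow(fb) != nrow(sb)) abort("Row counts differ.")
  if (nrow(fa) < 4 || nrow(fb) < 4) {
    abort("Each group needs at least 4 trials to split into halves.")
  }

  halves <- halves %||% with_seed(child_seed(seed, 1), {
    list(a = split_halves(nrow(fa)), b = split_halves(nrow(fb)))
  })

  reps <- function(fn) {
    list(
      a1 = fn(fa, sa, halves$a[[1]]), a2 = fn(fa, sa, halves$a[[2]]),
      b1 = fn(fb, sb, halves$b[[1]]), b2 = fn(fb, sb, halves$b[[2]])
    )
  }
  make <- function(f, s, idx) {
    half_representation(f, s, idx, reference, embedding, variance_threshold)
  }
  r <- reps(make)
  stats_from <- function(r) {
    within <- mean(c(cor(r$a1, r$a2), cor(r$b1, r$b2)))
    between <- mean(c(cor(r$a1, r$b2), cor(r$a2, r$b1)))
    c(within = within, between = between, diff = within - between)
  }
  obs <- stats_from(r)

  null_diffs <- with_seed(child_seed(seed, 2), {
    vapply(seq_len(n_perm), function(p) {
      rn <- reps(function(f, s, idx) {
        half_representation_null(f, s, idx, reference, embedding,
                                 variance_threshold)
      })
      stats_from(rn)[["diff"]]
    }, numeric(1))
  })

  ci_w <- ci_b <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- with_seed(child_seed(seed, 3), {
      t(vapply(seq_len(n_boot), function(b) {
        rb <- reps(function(f, s, idx) {
          make(f, s, sample(idx, length(idx), replace = TRUE))
        })
        stats_from(rb)[c("within", "between")]
      }, numeric(2)))
    })
    ci_w <- as.numeric(quantile(boots[, 1], c(0.025, 0.975)))
    ci_b <- as.numeric(quantile(boots[, 2], c(0.025, 0.975)))
  }

  list(
    within = obs[["within"]], between = obs[["between"]],
    difference = obs[["diff"]],
    p = perm_pvalue(obs[["diff"]], null_diffs, "two"),
    ci_within = ci_w, ci_between = ci_b,
    detail = c(r_a = cor(r$a1, r$a2), r_b = cor(r$b1, r$b2),
               r_ab1 = cor(r$a1, r$b2), r_ab2 = cor(r$a2, r$b1)),
    null = null_diffs
  )
}

split_halves <- function(n) {
  idx <- sample.int(n)
  list(sort(idx[seq_len(floor(n / 2))]), sort(idx[(floor(n / 2) + 1):n]))
}

#' Pairwise-averaged uniqueness across more than two groups
#'
#' Runs [uniqueness_analysis()] for every pair of groups and averages the
#' within/between correlations and differences.
#'
#' @param groups Named list; each element a list with `features` and
#'   `semantics`.
#' @inheritParams uniqueness_analysis
#' @return A list: `pairs` (tibble of per-pair results), `within`, `between`,
#'   `difference` (pairwise means).
#' @export
uniqueness_pairwise <- function(groups, reference, embedding,
                                variance_threshold = 0.9, n_perm = 100,
                                seed = NULL) {
  if (length(groups) < 2) abort("At least two groups are required.")
  nm <- names(groups) %||% as.character(seq_along(groups))
  combs <- utils::combn(seq_along(groups), 2)
  rows <- lapply(seq_len(ncol(combs)), function(ci) {
    i <- combs[1, ci]; j <- combs[2, ci]
    u <- uniqueness_analysis(groups[[i]]$features, groups[[i]]$semantics,
                             groups[[j]]$features, groups[[j]]$semantics,
                             reference, embedding, variance_threshold,
                             n_perm = n_perm, n_boot = 0,
                             seed = child_seed(seed, ci))
    tibble(group_a = nm[i], group_b = nm[j], within = u$within,
           between = u$between, difference = u$difference, p = u$p)
  })
  pairs <- dplyr::bind_rows(rows)
  list(pairs = pairs, within = mean(pairs$within),
       between = mean(pairs$between), difference = mean(pairs$difference))
}
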